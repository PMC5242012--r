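TAXON_GROUPS <- c("spider", "scorpion", "snake", "centipede", "cone_snail",
                  "other")

# Default taxon composition of the library (library-wide proportions of the
# source animal groups).
DEFAULT_TAXON_MIX <- c(spider = 0.43, scorpion = 0.31, snake = 0.10,
                       centipede = 0.07, cone_snail = 0.06, other = 0.03)

# Cysteine frameworks commonly seen in venom peptide collections: the
# three-bridge knottin (ICK), three-finger and extended three-finger folds,
# the Csalpha/beta scaffolds, the four-cysteine helical hairpin and the
# minimal two-cysteine loop.
NAMED_FRAMEWORKS <- c(
  "C-C-CC-C-C",
  "C-C-C-C-C-CC-C",
  "C-C-C-C-C-C-C-CC-C",
  "C-C-C-C-C-C",
  "C-C-C-C-C-C-C-C",
  "C-C-C-C",
  "C-C"
)

new_peptide_record <- function(id, sequence, taxon_group = "other") {
  assert_peptide(sequence, id)
  taxon_group <- match.arg(taxon_group, TAXON_GROUPS)
  n_cys <- lengths(regmatches(sequence, gregexpr("C", sequence, fixed = TRUE)))
  data.frame(
    id = id,
    sequence = sequence,
    taxon_group = taxon_group,
    length = nchar(sequence),
    n_cys = as.integer(n_cys),
    pattern = cysteine_pattern(sequence),
    n_bridges_max = bridge_count(n_cys),
    odd_cysteines = n_cys %% 2L == 1L,
    stringsAsFactors = FALSE
  )
}

#' Read peptide records from a FASTA file
#'
#' Each entry becomes one record. The description line may carry
#' whitespace-separated `key=value` tokens; `taxon=` sets the taxon group
#' (defaulting to `other`), unknown keys are ignored with a warning.
#'
#' @param path Path to a protein FASTA file (wrapped or single-line).
#' @return A `peptide_library` data frame with one row per entry, in file
#'   order: columns `id`, `sequence`, `taxon_group`, `length`, `n_cys`,
#'   `pattern`, `n_bridges_max`, `odd_cysteines`.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no FASTA records in ", path)
  recs <- lapply(seq_along(aas), function(i) {
    header <- names(aas)[i]
    toks <- strsplit(header, "\\s+")[[1]]
    id <- toks[1L]
    taxon <- "other"
    for (tok in toks[-1L]) {
      if (!grepl("=", tok, fixed = TRUE)) next
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (kv[1L] == "taxon") {
        if (!kv[2L] %in% TAXON_GROUPS) {
          warning("record '", id, "': unknown taxon '", kv[2L],
                  "', using 'other'", call. = FALSE)
        } else {
          taxon <- kv[2L]
        }
      } else {
        warning("record '", id, "': ignoring unknown metadata key '",
                kv[1L], "'", call. = FALSE)
      }
    }
    new_peptide_record(id, as.character(aas[[i]]), taxon)
  })
  lib <- do.call(rbind, recs)
  class(lib) <- c("peptide_library", class(lib))
  lib
}

#' Write a peptide library as a CSV table
#'
#' @param library A `peptide_library` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(library, path) {
  write.csv(library[, c("id", "taxon_group", "length", "n_cys", "pattern",
                        "n_bridges_max")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cysteine framework of a peptide
#'
#' Projects the sequence onto its cysteines: cysteines at consecutive residue
#' positions are concatenated (`"CC"`), otherwise separated by dashes. The
#' empty string is returned when the sequence has no cysteine. Runs of three
#' or more consecutive cysteines are rendered as that many concatenated C's.
#'
#' @param sequence Amino-acid sequence.
#' @return Framework string, e.g. `"C-C-CC-C-C"` for the knottin (ICK) motif.
#' @examples
#' cysteine_pattern("ACACCA")  # "C-CC"
#' @export
cysteine_pattern <- function(sequence) {
  assert_peptide(sequence)
  pos <- which(strsplit(sequence, "")[[1]] == "C")
  if (length(pos) == 0L) return("")
  sep <- ifelse(diff(pos) == 1L, "", "-")
  paste0(paste0(c("", sep), "C"), collapse = "")
}

#' Maximum number of disulphide bridges for a cysteine count
#'
#' @param n_cys Non-negative cysteine count.
#' @return `floor(n_cys / 2)` as an integer. Peptides with an odd cysteine
#'   count carry one unpaired thiol; see the `odd_cysteines` flag on records.
#' @export
bridge_count <- function(n_cys) {
  if (any(n_cys < 0)) stop("n_cys must be non-negative")
  as.integer(n_cys %/% 2L)
}

## Place cysteines in a window of `length` residues realizing `pattern`
## (blocks of adjacent C separated by >= 2-residue gaps). Returns positions or
## NULL when infeasible for this length.
place_framework <- function(pattern, length) {
  if (pattern == "") return(integer(0))
  blocks <- nchar(strsplit(pattern, "-", fixed = TRUE)[[1]])
  n_blocks <- length(blocks)
  # minimal footprint: block widths plus >= 1 spacer residue between blocks
  min_span <- sum(blocks) + (n_blocks - 1L)
  if (min_span > length) return(NULL)
  slack <- length - min_span
  # distribute the slack at random over the n_blocks + 1 gaps
  extra <- if (slack > 0) {
    tabulate(sample.int(n_blocks + 1L, slack, replace = TRUE), n_blocks + 1L)
  } else rep(0L, n_blocks + 1L)
  pos <- integer(0)
  cursor <- extra[1L]
  for (b in seq_len(n_blocks)) {
    pos <- c(pos, cursor + seq_len(blocks[b]))
    cursor <- cursor + blocks[b] + if (b < n_blocks) 1L + extra[b + 1L] else 0L
  }
  pos
}

random_framework <- function(n_cys) {
  if (n_cys == 0L) return("")
  # mostly isolated cysteines, occasionally an adjacent pair, as in natural
  # venom scaffolds
  blocks <- integer(0)
  remaining <- n_cys
  while (remaining > 0L) {
    b <- if (remaining >= 2L && runif(1) < 0.15) 2L else 1L
    blocks <- c(blocks, b)
    remaining <- remaining - b
  }
  paste(vapply(blocks, function(b) strrep("C", b), character(1)),
        collapse = "-")
}

#' Generate a synthetic venom-like peptide library
#'
#' Emulates the composition of a large disulphide-rich peptide collection:
#' uniform lengths, a taxon mix matching the library-wide proportions of the
#' source animal groups, bridge counts uniform over `bridge_range`, a small
#' fraction of peptides with an odd cysteine count, and cysteine positions
#' realizing either a named natural framework or a random one. Non-cysteine
#' residues are drawn from `residue_probs` (uniform over the 19 non-Cys
#' letters by default).
#'
#' @param n Number of peptides.
#' @param seed Integer seed; the output is bit-for-bit reproducible.
#' @param length_range Length range in residues, default 35--120.
#' @param bridge_range Disulphide-bridge range, default 1--9.
#' @param taxon_mix Named proportions over the taxon groups, summing to 1.
#' @param odd_cys_prob Probability of an extra unpaired cysteine (default
#'   0.02, i.e. about 2\% of records).
#' @param residue_probs Optional named probabilities over non-Cys residues.
#' @return A `peptide_library` data frame (see [read_peptides()]).
#' @export
generate_synthetic_library <- function(n, seed,
                                       length_range = c(35L, 120L),
                                       bridge_range = c(1L, 9L),
                                       taxon_mix = DEFAULT_TAXON_MIX,
                                       odd_cys_prob = 0.02,
                                       residue_probs = NULL) {
  stopifnot(n >= 1L, length(length_range) == 2L, length(bridge_range) == 2L)
  if (abs(sum(taxon_mix) - 1) > 1e-9) {
    stop("taxon_mix proportions must sum to 1")
  }
  if (!all(names(taxon_mix) %in% TAXON_GROUPS)) {
    stop("unknown taxon group in taxon_mix")
  }
  non_cys <- setdiff(AA_LETTERS, "C")
  if (is.null(residue_probs)) {
    residue_probs <- setNames(rep(1 / length(non_cys), length(non_cys)),
                              non_cys)
  }
  stopifnot(all(names(residue_probs) %in% non_cys))

  withr::with_seed(seed, {
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      taxon <- sample(names(taxon_mix), 1L, prob = taxon_mix)
      len <- sample(length_range[1L]:length_range[2L], 1L)
      bridges <- sample(bridge_range[1L]:bridge_range[2L], 1L)
      n_cys <- 2L * bridges + (runif(1) < odd_cys_prob)
      pos <- NULL
      for (try in 1:25) {
        named <- NAMED_FRAMEWORKS[nchar(gsub("-", "", NAMED_FRAMEWORKS)) == n_cys]
        pattern <- if (length(named) > 0L && runif(1) < 0.6) {
          sample(named, 1L)
        } else {
          random_framework(n_cys)
        }
        pos <- place_framework(pattern, len)
        if (!is.null(pos)) break
      }
      if (is.null(pos)) {
        stop("could not place ", n_cys, " cysteines in a ", len,
             "-residue peptide after 25 attempts")
      }
      aa <- sample(non_cys, len, replace = TRUE, prob = residue_probs)
      aa[pos] <- "C"
      recs[[i]] <- new_peptide_record(sprintf("syn%04d", i),
                                      paste(aa, collapse = ""), taxon)
    }
    lib <- do.call(rbind, recs)
    class(lib) <- c("peptide_library", class(lib))
    lib
  })
}

# Default length classes for reporting by size.
DEFAULT_LENGTH_BREAKS <- c(35, 50, 65, 80, 100, 121)

length_class <- function(length, breaks = DEFAULT_LENGTH_BREAKS) {
  labs <- paste0(head(breaks, -1), "-", breaks[-1] - 1)
  as.character(cut(length, breaks = breaks, labels = labs, right = FALSE))
}
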