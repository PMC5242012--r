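# DNA encoding the TEV protease recognition site ENLYFQ, placed immediately
# upstream of the peptide so that cleavage after Q releases the native
# peptide, and the duplicated TAA stop used for every gene.
TEV_PREFIX_DNA <- "GAGAACCTGTACTTCCAA"
STOP_SUFFIX    <- "TAATAA"
TEV_SITE_AA    <- "ENLYFQ"

#' Gene-design constraint set
#'
#' The rule set applied to every synthesized gene: global GC content within a
#' band, a minimum Codon Adaptation Index, limits on homopolymer and G/C-only
#' runs, exclusion of rare codons and of regulatory motifs on either strand,
#' and balanced use of the two cysteine codons.
#'
#' @param gc_min,gc_max GC-content band in percent (default 40--60, applied
#'   to the whole synthesized gene including the TEV prefix and stops).
#' @param cai_min Minimum CAI (default 0.8).
#' @param max_gc_run Longest allowed run over \{G,C\} (default 6 nt).
#' @param max_homopolymer Longest allowed single-base run (default 5 nt).
#' @param balance_cys_codons Require |#TGC - #TGT| <= 1 per gene.
#' @param rare_codon_w_floor Codons with relative adaptiveness below this are
#'   treated as rare and excluded (default 0.1).
#' @param forbidden_motifs DNA motifs that must not appear on either strand;
#'   defaults to the sigma-70 -10 box consensus and a strong Shine-Dalgarno.
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(gc_min = 40, gc_max = 60, cai_min = 0.8,
                               max_gc_run = 6L, max_homopolymer = 5L,
                               balance_cys_codons = TRUE,
                               rare_codon_w_floor = 0.1,
                               forbidden_motifs = c("TATAAT", "AGGAGG")) {
  stopifnot(0 <= gc_min, gc_min < gc_max, gc_max <= 100,
            cai_min > 0, cai_min <= 1, max_gc_run >= 1L, max_homopolymer >= 1L)
  structure(list(gc_min = gc_min, gc_max = gc_max, cai_min = cai_min,
                 max_gc_run = as.integer(max_gc_run),
                 max_homopolymer = as.integer(max_homopolymer),
                 balance_cys_codons = isTRUE(balance_cys_codons),
                 rare_codon_w_floor = rare_codon_w_floor,
                 forbidden_motifs = forbidden_motifs,
                 tev_prefix_dna = TEV_PREFIX_DNA,
                 stop_suffix = STOP_SUFFIX),
            class = "design_constraints")
}

#' Codon Adaptation Index of a coding sequence
#'
#' Geometric mean of the relative adaptiveness `w` of the scored codons.
#' Following the usual convention, codons for Met and Trp (single-codon
#' families, always `w = 1`) and stop codons are excluded from scoring;
#' set `exclude = character(0)` to score Met/Trp as well.
#'
#' @param dna Coding DNA, length a multiple of 3. A trailing run of stop
#'   codons is allowed; an internal stop is an error.
#' @param table A `codon_table`.
#' @param exclude Amino acids excluded from scoring.
#' @return CAI in (0, 1].
#' @export
cai <- function(dna, table, exclude = c("M", "W")) {
  assert_dna(dna)
  codons <- split_codons(dna)
  aa <- Biostrings::GENETIC_CODE[codons]
  is_stop <- aa == "*"
  if (any(is_stop)) {
    # only a terminal run of stops is tolerated
    first_stop <- which(is_stop)[1L]
    if (!all(is_stop[first_stop:length(aa)])) {
      stop("in-frame stop codon at codon ", first_stop,
           " is not part of the terminal stop suffix")
    }
  }
  scored <- !is_stop & !(aa %in% exclude)
  if (!any(scored)) stop("no scorable codons in sequence")
  w <- table$w[match(codons[scored], table$codon)]
  if (anyNA(w)) stop("codon absent from table: ",
                     paste(unique(codons[scored][is.na(w)]), collapse = ", "))
  exp(mean(log(w)))
}

#' GC content in percent
#'
#' @param dna Non-empty DNA string.
#' @return `100 * (G + C) / length`.
#' @export
gc_content <- function(dna) {
  assert_dna(dna)
  b <- strsplit(dna, "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' Longest run in a DNA sequence
#'
#' @param dna Non-empty DNA string.
#' @param mode `"homopolymer"` (longest run of one identical base) or
#'   `"gc_run"` (longest run over the alphabet \{G, C\}).
#' @return Integer run length.
#' @export
max_run <- function(dna, mode = c("homopolymer", "gc_run")) {
  mode <- match.arg(mode)
  assert_dna(dna)
  b <- strsplit(dna, "")[[1]]
  r <- if (mode == "homopolymer") rle(b) else rle(b %in% c("G", "C"))
  if (mode == "gc_run") {
    lens <- r$lengths[r$values]
    if (length(lens) == 0L) return(0L)
    return(max(lens))
  }
  max(r$lengths)
}

## run descriptors (start, length) exceeding a limit, 1-based nt coordinates
runs_over <- function(dna, mode, limit) {
  b <- strsplit(dna, "")[[1]]
  r <- if (mode == "homopolymer") rle(b) else rle(b %in% c("G", "C"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths > limit & (if (mode == "gc_run") r$values else TRUE)
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Screen a sequence for forbidden motifs
#'
#' Exact matches on the given strand and its reverse complement, with 0-based
#' start positions in top-strand coordinates.
#'
#' @param dna DNA string.
#' @param motifs Character vector of DNA motifs.
#' @return Data frame with columns `motif`, `position`, `strand`.
#' @export
screen_motifs <- function(dna, motifs) {
  assert_dna(dna)
  out <- list()
  for (m in motifs) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") m else revcomp(m)
      hits <- gregexpr(pat, dna, fixed = TRUE)[[1]]
      if (hits[1L] != -1L) {
        out[[length(out) + 1L]] <- data.frame(
          motif = m, position = as.integer(hits) - 1L, strand = strand)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(0), position = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, out)
}

#' Initial back-translation of a peptide
#'
#' Every residue receives its most adapted codon (`w = 1`), except cysteines,
#' which alternate between TGC and TGT -- starting with the more frequent of
#' the two -- so that each gene uses the two cysteine codons in equal
#' proportion (|#TGC - #TGT| <= 1).
#'
#' @param peptide Amino-acid sequence.
#' @param table A `codon_table`.
#' @return Coding DNA for the peptide (no prefix or stop).
#' @export
back_translate_initial <- function(peptide, table) {
  assert_peptide(peptide)
  aa <- strsplit(peptide, "")[[1]]
  best <- vapply(unique(aa), function(a) synonymous_codons(table, a)$codon[1L],
                 character(1))
  codons <- best[aa]
  cys_fam <- synonymous_codons(table, "C")
  cys_cycle <- cys_fam$codon[1:2]
  idx <- which(aa == "C")
  if (length(idx) > 0L) {
    codons[idx] <- cys_cycle[((seq_along(idx) - 1L) %% 2L) + 1L]
  }
  paste(codons, collapse = "")
}

## ---- constraint evaluation ------------------------------------------------

## Violation summary for a full synthesized gene. Returns a list with a count
## of violated constraints, a continuous severity, and per-kind details.
eval_violations <- function(cds, table, cons) {
  codons <- split_codons(cds)
  gc <- gc_content(cds)
  hp <- runs_over(cds, "homopolymer", cons$max_homopolymer)
  gr <- runs_over(cds, "gc_run", cons$max_gc_run)
  hits <- screen_motifs(cds, cons$forbidden_motifs)
  w <- table$w[match(codons, table$codon)]           # NA for stop codons
  rare <- which(!is.na(w) & w < cons$rare_codon_w_floor)
  n_tgc <- sum(codons == "TGC")
  n_tgt <- sum(codons == "TGT")
  imbal <- if (cons$balance_cys_codons) max(0L, abs(n_tgc - n_tgt) - 1L) else 0L

  gc_dev <- max(0, cons$gc_min - gc) + max(0, gc - cons$gc_max)
  count <- (gc_dev > 0) + (nrow(hp) > 0) + (nrow(gr) > 0) +
    (nrow(hits) > 0) + (length(rare) > 0) + (imbal > 0)
  severity <- gc_dev +
    sum(hp$length - cons$max_homopolymer) +
    sum(gr$length - cons$max_gc_run) +
    nrow(hits) + length(rare) + imbal
  list(count = count, severity = severity, gc = gc, gc_dev = gc_dev,
       homopolymer = hp, gc_runs = gr, motif_hits = hits, rare = rare,
       n_tgc = n_tgc, n_tgt = n_tgt, imbalance = imbal)
}

## codon indices (1-based) overlapping a nucleotide interval [start, start+len)
codons_touching <- function(start, len) {
  seq.int((start - 1L) %/% 3L + 1L, (start + len - 2L) %/% 3L + 1L)
}

#' Optimize a codon design for one peptide
#'
#' Builds the full synthesized gene (TEV-site prefix, peptide codons,
#' duplicated TAA stop; prefix and suffix are immutable) starting from
#' [back_translate_initial()], then iteratively repairs constraint violations
#' by single-codon synonymous substitutions. Repair candidates must not
#' increase the number of violated constraints; among acceptable candidates
#' the substitution with the highest relative adaptiveness wins, tie-broken
#' by higher codon frequency, then alphabetical codon order, with the seeded
#' RNG deciding only among exact ties and the order in which violations are
#' visited. The optimizer stops when all constraints pass or after
#' `max_iterations` (default `10 * peptide length`), in which case the
#' unmet constraints are reported as failed flags rather than an error.
#'
#' @param peptide Amino-acid sequence (or a single-row `peptide_library`).
#' @param table A `codon_table`.
#' @param constraints A [design_constraints()] list.
#' @param seed Integer seed; identical inputs give identical designs.
#' @param max_iterations Repair-step budget.
#' @param peptide_id Identifier carried into the design.
#' @return A `gene_design` list: `cds`, `cai`, `gc_percent`,
#'   `max_homopolymer_observed`, `max_gc_run_observed`, `motif_hits`,
#'   `n_tgc`/`n_tgt`, per-rule `flags`, `all_pass`, `seed`, `iterations`.
#' @export
optimize_gene <- function(peptide, table, constraints = design_constraints(),
                          seed = 1L, max_iterations = NULL,
                          peptide_id = "peptide") {
  if (is.data.frame(peptide)) {
    stopifnot(nrow(peptide) == 1L)
    peptide_id <- peptide$id
    peptide <- peptide$sequence
  }
  assert_peptide(peptide)
  cons <- constraints
  n_pep <- nchar(peptide)
  if (is.null(max_iterations)) max_iterations <- 10L * n_pep

  prefix_codons <- split_codons(cons$tev_prefix_dna)
  suffix_codons <- split_codons(cons$stop_suffix)
  codons <- c(prefix_codons, split_codons(back_translate_initial(peptide, table)),
              suffix_codons)
  mutable <- seq.int(length(prefix_codons) + 1L,
                     length(prefix_codons) + n_pep)
  aa_of <- Biostrings::GENETIC_CODE[codons]

  syn_cache <- new.env(parent = emptyenv())
  syns <- function(a) {
    if (is.null(syn_cache[[a]])) {
      fam <- synonymous_codons(table, a)
      syn_cache[[a]] <- fam[fam$w >= cons$rare_codon_w_floor, , drop = FALSE]
    }
    syn_cache[[a]]
  }

  iterations <- 0L
  withr::with_seed(seed, {
    repeat {
      cds <- paste(codons, collapse = "")
      v <- eval_violations(cds, table, cons)
      if (v$count == 0L || iterations >= max_iterations) break
      iterations <- iterations + 1L

      # collect repair items: each names the codon positions it can touch
      items <- list()
      if (nrow(v$homopolymer) > 0L) {
        for (k in seq_len(nrow(v$homopolymer))) {
          items[[length(items) + 1L]] <- list(
            kind = "run",
            pos = codons_touching(v$homopolymer$start[k], v$homopolymer$length[k]))
        }
      }
      if (nrow(v$gc_runs) > 0L) {
        for (k in seq_len(nrow(v$gc_runs))) {
          items[[length(items) + 1L]] <- list(
            kind = "run",
            pos = codons_touching(v$gc_runs$start[k], v$gc_runs$length[k]))
        }
      }
      if (nrow(v$motif_hits) > 0L) {
        for (k in seq_len(nrow(v$motif_hits))) {
          items[[length(items) + 1L]] <- list(
            kind = "motif",
            pos = codons_touching(v$motif_hits$position[k] + 1L,
                                  nchar(v$motif_hits$motif[k])))
        }
      }
      if (length(v$rare) > 0L) {
        items[[length(items) + 1L]] <- list(kind = "rare", pos = v$rare)
      }
      if (v$gc_dev > 0) {
        items[[length(items) + 1L]] <- list(kind = "gc", pos = mutable)
      }
      if (v$imbalance > 0L) {
        items[[length(items) + 1L]] <- list(kind = "cys",
                                            pos = mutable[aa_of[mutable] == "C"])
      }

      # RNG chooses the visit order over violation items
      items <- items[sample.int(length(items))]
      applied <- FALSE
      for (item in items) {
        pos <- intersect(item$pos, mutable)
        if (length(pos) == 0L) next
        cand <- list()
        for (p in pos) {
          fam <- syns(aa_of[p])
          for (r in seq_len(nrow(fam))) {
            alt <- fam$codon[r]
            if (alt == codons[p]) next
            new_codons <- codons
            new_codons[p] <- alt
            nv <- eval_violations(paste(new_codons, collapse = ""), table, cons)
            if (nv$count > v$count) next
            if (nv$count == v$count && nv$severity >= v$severity - 1e-12) next
            cand[[length(cand) + 1L]] <- list(p = p, codon = alt,
                                              w = fam$w[r], freq = fam$freq[r])
          }
        }
        if (length(cand) == 0L) next
        w <- vapply(cand, `[[`, numeric(1), "w")
        fr <- vapply(cand, `[[`, numeric(1), "freq")
        cd <- vapply(cand, `[[`, character(1), "codon")
        ord <- order(-w, -fr, cd)
        best <- ord[w[ord] == w[ord[1L]] & fr[ord] == fr[ord[1L]] &
                      cd[ord] == cd[ord[1L]]]
        pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else ord[1L]
        codons[cand[[pick]]$p] <- cand[[pick]]$codon
        applied <- TRUE
        break
      }
      if (!applied) break   # no admissible repair; report flags as-is
    }
  })

  cds <- paste(codons, collapse = "")
  v <- eval_violations(cds, table, cons)
  cai_val <- cai(cds, table)
  flags <- c(
    cai = cai_val >= cons$cai_min,
    gc = v$gc_dev == 0,
    homopolymer = nrow(v$homopolymer) == 0L,
    gc_run = nrow(v$gc_runs) == 0L,
    motifs = nrow(v$motif_hits) == 0L,
    rare_codons = length(v$rare) == 0L,
    cys_balance = v$imbalance == 0L
  )
  structure(list(
    peptide_id = peptide_id,
    peptide = peptide,
    cds = cds,
    cai = cai_val,
    gc_percent = v$gc,
    max_homopolymer_observed = max_run(cds, "homopolymer"),
    max_gc_run_observed = max_run(cds, "gc_run"),
    motif_hits = v$motif_hits,
    n_tgc = v$n_tgc,
    n_tgt = v$n_tgt,
    flags = flags,
    all_pass = all(flags),
    seed = seed,
    iterations = iterations
  ), class = "gene_design")
}

#' @export
print.gene_design <- function(x, ...) {
  cat("Gene design for", x$peptide_id, "\n",
      " cds length:", nchar(x$cds), "nt  CAI:", round(x$cai, 3),
      " GC:", round(x$gc_percent, 1), "%\n",
      " constraints:", if (x$all_pass) "all pass" else
        paste("FAILED:", paste(names(x$flags)[!x$flags], collapse = ", ")),
      "\n")
  invisible(x)
}

#' Design genes for a whole peptide library
#'
#' @param library A `peptide_library` data frame.
#' @param table A `codon_table` (default: packaged E. coli table).
#' @param constraints A [design_constraints()] list.
#' @param seed Master seed; per-gene seeds are drawn from it, so the whole
#'   run is reproducible.
#' @return A list of `gene_design` objects, one per record.
#' @export
design_genes <- function(library, table = read_codon_table(),
                         constraints = design_constraints(), seed = 1L) {
  n <- nrow(library)
  gene_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    optimize_gene(library$sequence[i], table, constraints,
                  seed = gene_seeds[i], peptide_id = library$id[i])
  })
}

#' Summarize gene designs as a data frame
#'
#' @param designs List of `gene_design` objects.
#' @return Data frame of per-gene metrics and pass flags.
#' @export
design_metrics <- function(designs) {
  do.call(rbind, lapply(designs, function(d) {
    data.frame(peptide_id = d$peptide_id, length_nt = nchar(d$cds),
               cai = d$cai, gc_percent = d$gc_percent,
               max_homopolymer = d$max_homopolymer_observed,
               max_gc_run = d$max_gc_run_observed,
               n_motif_hits = nrow(d$motif_hits),
               n_tgc = d$n_tgc, n_tgt = d$n_tgt,
               all_pass = d$all_pass, stringsAsFactors = FALSE)
  }))
}

#' Write gene designs as nucleotide FASTA
#'
#' @param designs List of `gene_design` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(designs, path) {
  seqs <- Biostrings::DNAStringSet(vapply(designs, `[[`, character(1), "cds"))
  names(seqs) <- vapply(designs, `[[`, character(1), "peptide_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
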