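# PCR-assembly oligonucleotide tiling. The geometry is fixed by three
# numbers: a maximum oligo length (60 nt), a 20 nt overlap between
# opposite-strand neighbours and a 20 nt gap between same-strand neighbours.
# Tiling is anchored at position 0 of the top strand: with period
# P = max_len + gap, top oligos start at multiples of P and internal bottom
# oligos are offset by max_len - overlap, so every junction overlap is
# exactly `overlap` nt and every same-strand gap exactly `gap` nt.

MIN_OLIGO_LEN <- 15L

#' Number of assembly oligonucleotides for a gene length
#'
#' Closed form for the tiling produced by [design_oligos()] with the same
#' geometry: `n_top + (n_top - 1)` plus one terminal bottom oligo when the
#' gene extends past the last internal bottom start.
#'
#' @param L Gene length in nt (>= 40).
#' @param max_len,overlap,gap Tiling geometry in nt.
#' @return Integer oligo count.
#' @examples
#' oligo_count(220)  # 6
#' oligo_count(137)  # 4
#' @export
oligo_count <- function(L, max_len = 60L, overlap = 20L, gap = 20L) {
  stopifnot(L >= 40L)
  P <- max_len + gap
  off <- max_len - overlap
  n_top <- as.integer(ceiling(L / P))
  n_top + (n_top - 1L) + as.integer(L > P * (n_top - 1L) + off)
}

#' Tile a gene into PCR-assembly oligonucleotides
#'
#' Top oligos `i = 0..n_top-1` span `[P*i, min(P*i + max_len, L))` with
#' `P = max_len + gap`; internal bottom oligos `j = 0..n_top-2` span
#' `[P*j + off, P*j + off + max_len)` with `off = max_len - overlap`; a
#' terminal bottom oligo spans `[P*(n_top-1) + off, L)` when the gene
#' extends past its start. Any oligo shorter than 15 nt is extended leftward
#' into the duplex to 15 nt (the oligo count is unchanged). Bottom oligos are
#' written 5'->3' on their own strand (reverse complement of the top-strand
#' slice). The two outermost oligos double as the amplification primers.
#'
#' @param gene DNA string (>= 40 nt for a multi-oligo plan; shorter genes
#'   yield a single-oligo plan with a warning flag).
#' @param gene_id Identifier carried into the plan.
#' @param max_len,overlap,gap Tiling geometry in nt.
#' @return An `oligo_plan`: list with `gene_id`, `gene_length`, `n_oligos`,
#'   an `oligos` data frame (`index`, `strand`, `start`, `end`, `length`,
#'   `sequence`; 0-based half-open top-strand coordinates) and `warnings`.
#' @export
design_oligos <- function(gene, gene_id = "gene", max_len = 60L,
                          overlap = 20L, gap = 20L) {
  assert_dna(gene)
  L <- nchar(gene)
  warnings <- character(0)
  if (L < 40L) {
    warnings <- "gene shorter than 40 nt: single-oligo plan"
    oligos <- data.frame(index = 1L, strand = "top", start = 0L, end = L,
                         length = L, sequence = gene,
                         stringsAsFactors = FALSE)
    plan <- list(gene_id = gene_id, gene_length = L, n_oligos = 1L,
                 oligos = oligos, warnings = warnings)
    class(plan) <- "oligo_plan"
    return(plan)
  }
  P <- max_len + gap
  off <- max_len - overlap
  n_top <- as.integer(ceiling(L / P))

  starts <- integer(0); ends <- integer(0); strands <- character(0)
  for (i in seq_len(n_top) - 1L) {
    starts <- c(starts, P * i)
    ends <- c(ends, min(P * i + max_len, L))
    strands <- c(strands, "top")
  }
  if (n_top >= 2L) {
    for (j in seq_len(n_top - 1L) - 1L) {
      starts <- c(starts, P * j + off)
      ends <- c(ends, min(P * j + off + max_len, L))
      strands <- c(strands, "bottom")
    }
  }
  term_start <- P * (n_top - 1L) + off
  if (L > term_start) {
    starts <- c(starts, term_start)
    ends <- c(ends, L)
    strands <- c(strands, "bottom")
  }
  # short terminal pieces are extended leftward into the duplex
  short <- ends - starts < MIN_OLIGO_LEN
  starts[short] <- ends[short] - MIN_OLIGO_LEN

  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]; strands <- strands[ord]
  seqs <- vapply(seq_along(starts), function(k) {
    s <- substr(gene, starts[k] + 1L, ends[k])
    if (strands[k] == "bottom") revcomp(s) else s
  }, character(1))
  oligos <- data.frame(index = seq_along(starts), strand = strands,
                       start = starts, end = ends, length = ends - starts,
                       sequence = seqs, stringsAsFactors = FALSE)
  plan <- list(gene_id = gene_id, gene_length = L,
               n_oligos = nrow(oligos), oligos = oligos, warnings = warnings)
  class(plan) <- "oligo_plan"
  plan
}

#' @export
print.oligo_plan <- function(x, ...) {
  cat("Oligo plan for", x$gene_id, "-", x$gene_length, "nt,",
      x$n_oligos, "oligos\n")
  print(x$oligos[, c("index", "strand", "start", "end", "length")],
        row.names = FALSE)
  invisible(x)
}

#' Verify in silico that an oligo plan reassembles its gene
#'
#' Checks that every pair of consecutive oligos alternates strands and shares
#' an exact reverse-complement overlap of the design width (terminal overlaps
#' may be shorter but at least 15 nt), stitches the top-strand consensus from
#' the oligo sequences and compares it with the gene, and flags junction
#' overlap k-mers that occur more than once in the gene (potential
#' mispriming during assembly PCR).
#'
#' @param plan An `oligo_plan`.
#' @param gene The DNA the plan was designed from.
#' @param overlap Expected internal overlap width (nt).
#' @return List with `ok`, `identical`, `first_divergence` (0-based, or NA),
#'   `junctions` data frame and `mispriming_warnings`.
#' @export
simulate_assembly <- function(plan, gene, overlap = 20L) {
  assert_dna(gene)
  ol <- plan$oligos
  # top-strand view of every oligo
  top_view <- ifelse(ol$strand == "top", ol$sequence,
                     vapply(ol$sequence, revcomp, character(1)))
  # stitch consensus, verifying junction overlaps
  junctions <- list()
  consensus <- strrep("N", nchar(gene))
  cons <- rep(NA_character_, nchar(gene))
  ok <- TRUE
  for (k in seq_len(nrow(ol))) {
    span <- seq.int(ol$start[k] + 1L, ol$end[k])
    piece <- strsplit(top_view[k], "")[[1]]
    clash <- !is.na(cons[span]) & cons[span] != piece
    if (any(clash)) ok <- FALSE
    cons[span] <- piece
  }
  for (k in seq_len(nrow(ol) - 1L)) {
    if (ol$strand[k] == ol$strand[k + 1L]) ok <- FALSE
    ov_start <- ol$start[k + 1L]
    ov_end <- min(ol$end[k], ol$end[k + 1L])
    width <- ov_end - ov_start
    a <- substr(top_view[k], ov_start - ol$start[k] + 1L,
                ov_end - ol$start[k])
    b <- substr(top_view[k + 1L], 1L, width)
    terminal <- k == nrow(ol) - 1L || k == 1L
    width_ok <- width == overlap || (terminal && width >= MIN_OLIGO_LEN)
    junctions[[k]] <- data.frame(junction = k, start = ov_start,
                                 width = width, match = identical(a, b),
                                 width_ok = width_ok)
    if (!identical(a, b) || !width_ok) ok <- FALSE
  }
  junctions <- if (length(junctions)) do.call(rbind, junctions) else
    data.frame(junction = integer(0), start = integer(0), width = integer(0),
               match = logical(0), width_ok = logical(0))
  built <- paste(ifelse(is.na(cons), "N", cons), collapse = "")
  identical_seq <- identical(built, gene)
  first_div <- NA_integer_
  if (!identical_seq) {
    g <- strsplit(gene, "")[[1]]
    bb <- strsplit(built, "")[[1]]
    n <- min(length(g), length(bb))
    d <- which(g[seq_len(n)] != bb[seq_len(n)])
    first_div <- if (length(d)) d[1L] - 1L else n  # 0-based
  }
  # mispriming: junction overlap k-mers occurring more than once in the gene
  warn <- character(0)
  for (k in seq_len(nrow(junctions))) {
    kmer <- substr(gene, junctions$start[k] + 1L,
                   junctions$start[k] + junctions$width[k])
    n_occ <- length(gregexpr(kmer, gene, fixed = TRUE)[[1]])
    if (gregexpr(kmer, gene, fixed = TRUE)[[1]][1] == -1L) n_occ <- 0L
    if (n_occ > 1L) {
      warn <- c(warn, sprintf(
        "junction %d overlap %d-mer occurs %d times in gene", k,
        junctions$width[k], n_occ))
    }
  }
  list(ok = ok && identical_seq, identical = identical_seq,
       first_divergence = first_div, junctions = junctions,
       mispriming_warnings = warn)
}

#' Oligo plans for a set of designed genes
#'
#' @param designs List of `gene_design` objects (or named character vector of
#'   DNA sequences).
#' @param ... Passed to [design_oligos()].
#' @return List of `oligo_plan` objects.
#' @export
design_oligos_library <- function(designs, ...) {
  if (is.character(designs)) {
    ids <- names(designs)
    if (is.null(ids)) ids <- sprintf("gene%04d", seq_along(designs))
    return(lapply(seq_along(designs),
                  function(i) design_oligos(designs[[i]], ids[i], ...)))
  }
  lapply(designs, function(d) design_oligos(d$cds, d$peptide_id, ...))
}

#' Flatten oligo plans to a CSV-ready table
#'
#' @param plans List of `oligo_plan` objects.
#' @return Data frame: `gene_id`, `index`, `strand`, `start`, `end`,
#'   `length`, `sequence`.
#' @export
oligo_table <- function(plans) {
  do.call(rbind, lapply(plans, function(p) {
    cbind(gene_id = p$gene_id, p$oligos, stringsAsFactors = FALSE)
  }))
}
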