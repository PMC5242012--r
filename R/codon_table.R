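#' Read a codon-usage table
#'
#' Accepts a tab- or comma-delimited file with three columns: codon (DNA
#' triplet), amino acid (one-letter code, `*` for stop) and frequency (per
#' thousand or fractions; only ratios within a synonymous family matter).
#' Stop codons are accepted but never scored.
#'
#' @param path Path to the delimited file. Defaults to the packaged
#'   Escherichia coli usage table.
#' @return A `codon_table` object: data frame with columns `codon`, `aa`,
#'   `freq` and the relative adaptiveness `w`.
#' @export
read_codon_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ecoli_codon_usage.tsv",
                        package = "venomlib", mustWork = TRUE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("codon table needs 3 columns: codon, aa, frequency")
  names(raw)[1:3] <- c("codon", "aa", "freq")
  raw$codon <- toupper(gsub("U", "T", raw$codon))
  raw$aa <- toupper(raw$aa)
  as_codon_table(raw[, c("codon", "aa", "freq")])
}

as_codon_table <- function(df) {
  sense <- df[df$aa != "*", , drop = FALSE]
  if (any(duplicated(sense$codon))) stop("duplicated codons in table")
  if (any(sense$freq < 0)) stop("negative codon frequencies")
  gc_map <- Biostrings::GENETIC_CODE
  expected <- names(gc_map)[gc_map != "*"]
  missing <- setdiff(expected, sense$codon)
  if (length(missing) > 0L) {
    stop("codon table is missing ", length(missing), " sense codon(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  wrong <- sense$codon[gc_map[sense$codon] != sense$aa]
  if (length(wrong) > 0L) {
    stop("codon(s) assigned to the wrong amino acid: ",
         paste(head(wrong, 5), collapse = ", "))
  }
  sense$w <- relative_adaptiveness(sense)
  class(sense) <- c("codon_table", "data.frame")
  sense
}

#' Relative adaptiveness of each codon
#'
#' Within every synonymous family, `w = f / max(f)`; the most frequent codon
#' of each amino acid gets `w = 1`.
#'
#' @param table Data frame with columns `codon`, `aa`, `freq`.
#' @return Numeric vector of `w` values aligned with the table rows.
#' @export
relative_adaptiveness <- function(table) {
  fam_max <- tapply(table$freq, table$aa, max)
  if (any(fam_max == 0)) {
    stop("amino acid(s) with all-zero codon frequencies: ",
         paste(names(fam_max)[fam_max == 0], collapse = ", "))
  }
  as.numeric(table$freq / fam_max[table$aa])
}

## codons of one amino acid, ordered by w desc, then freq desc, then codon
synonymous_codons <- function(table, aa) {
  fam <- table[table$aa == aa, , drop = FALSE]
  fam[order(-fam$w, -fam$freq, fam$codon), , drop = FALSE]
}
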