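#' @importFrom stats rpois runif setNames
#' @importFrom utils head read.delim write.csv
NULL

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param dna Character scalar over A/C/G/T.
#' @return Character scalar, the reverse complement.
#' @export
revcomp <- function(dna) {
  intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", dna))))
}

#' Translate a coding DNA string
#'
#' @param dna Character scalar; length must be a multiple of 3.
#' @return Character scalar amino-acid sequence (stops rendered as `*`).
#' @export
translate_dna <- function(dna) {
  if (nchar(dna) %% 3L != 0L) {
    stop("coding sequence length must be a multiple of 3, got ", nchar(dna))
  }
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

## Split a DNA string into codon triplets.
split_codons <- function(dna) {
  n <- nchar(dna)
  substring(dna, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

assert_peptide <- function(sequence, id = NULL) {
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_LETTERS)
  if (length(bad) > 0L) {
    where <- if (is.null(id)) "" else paste0(" in record '", id, "'")
    stop("invalid amino-acid character(s) ", paste(sQuote(bad), collapse = ", "),
         where, "; only the 20 canonical residues are allowed", call. = FALSE)
  }
  invisible(sequence)
}

assert_dna <- function(dna) {
  bad <- setdiff(strsplit(dna, "")[[1]], DNA_BASES)
  if (length(bad) > 0L) {
    stop("invalid DNA character(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  invisible(dna)
}

## round-half-away-from-zero, the convention used for report percentages
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
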