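# Elemental data (IUPAC/NIST): isotope masses and natural abundances for the
# five elements found in unmodified peptides. Average atomic weights are the
# abundance-weighted means, so residue average masses are self-consistent with
# the isotope engine.

ELEMENT_ISOTOPES <- list(
  C = data.frame(offset = c(0L, 1L),       mass = c(12.0000000, 13.0033548),
                 abundance = c(0.9893, 0.0107)),
  H = data.frame(offset = c(0L, 1L),       mass = c(1.0078250, 2.0141018),
                 abundance = c(0.999885, 0.000115)),
  N = data.frame(offset = c(0L, 1L),       mass = c(14.0030740, 15.0001089),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(offset = c(0L, 1L, 2L),   mass = c(15.9949146, 16.9991317, 17.9991596),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(offset = c(0L, 1L, 2L, 4L), mass = c(31.9720707, 32.9714589, 33.9678670, 35.9670808),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

ELEMENT_MONO <- vapply(ELEMENT_ISOTOPES, function(d) d$mass[1L], numeric(1))
ELEMENT_AVG  <- vapply(ELEMENT_ISOTOPES,
                       function(d) sum(d$mass * d$abundance) / sum(d$abundance),
                       numeric(1))

# Residue (i.e. dehydrated monomer) elemental compositions, columns C,H,N,O,S.
RESIDUE_FORMULA <- rbind(
  A = c(3,  5, 1, 1, 0),
  R = c(6, 12, 4, 1, 0),
  N = c(4,  6, 2, 2, 0),
  D = c(4,  5, 1, 3, 0),
  C = c(3,  5, 1, 1, 1),
  E = c(5,  7, 1, 3, 0),
  Q = c(5,  8, 2, 2, 0),
  G = c(2,  3, 1, 1, 0),
  H = c(6,  7, 3, 1, 0),
  I = c(6, 11, 1, 1, 0),
  L = c(6, 11, 1, 1, 0),
  K = c(6, 12, 2, 1, 0),
  M = c(5,  9, 1, 1, 1),
  F = c(9,  9, 1, 1, 0),
  P = c(5,  7, 1, 1, 0),
  S = c(3,  5, 1, 2, 0),
  T = c(4,  7, 1, 2, 0),
  W = c(11, 10, 2, 1, 0),
  Y = c(9,  9, 1, 2, 0),
  V = c(5,  9, 1, 1, 0)
)
colnames(RESIDUE_FORMULA) <- c("C", "H", "N", "O", "S")

WATER_FORMULA <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

# Mass removed per disulphide bridge: two hydrogens.
MH_MONO <- 1.007825
MH_AVG  <- 1.00794

#' Elemental composition of a peptide
#'
#' Counts of C, H, N, O and S atoms in the intact (reduced, free-thiol)
#' peptide, i.e. the sum of residue formulas plus one water.
#'
#' @param sequence Amino-acid sequence (20 canonical letters).
#' @param n_bridges Number of disulphide bridges to subtract (2 H each).
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
elemental_composition <- function(sequence, n_bridges = 0L) {
  assert_peptide(sequence)
  stopifnot(n_bridges >= 0L)
  aa <- strsplit(sequence, "")[[1]]
  comp <- colSums(RESIDUE_FORMULA[aa, , drop = FALSE]) + WATER_FORMULA
  comp["H"] <- comp["H"] - 2L * n_bridges
  if (comp["H"] < 0) stop("more bridges than available hydrogens")
  comp
}

#' Peptide mass
#'
#' Monoisotopic or average mass of the reduced (free-thiol) peptide: sum of
#' standard residue masses plus water.
#'
#' @param sequence Amino-acid sequence.
#' @param mode `"mono"` or `"average"`.
#' @return Mass in Da.
#' @examples
#' peptide_mass("G")            # 75.032
#' peptide_mass("GG", "average")
#' @export
peptide_mass <- function(sequence, mode = c("mono", "average")) {
  mode <- match.arg(mode)
  comp <- elemental_composition(sequence)
  masses <- if (mode == "mono") ELEMENT_MONO else ELEMENT_AVG
  sum(comp * masses[names(comp)])
}
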