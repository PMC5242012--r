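# Mass-level quality control: a peptide with n_max = floor(n_cys/2) possible
# disulphide bridges gives a ladder of species, each bridge removing two
# hydrogens (2 x 1.007825 Da mono, 2 x 1.00794 Da average). An observed
# deconvoluted mass is called by nearest-species matching on that ladder.

#' Mass profile of a peptide
#'
#' Reduced (free-thiol) monoisotopic and average masses, the per-bridge
#' oxidized species ladder, the A280 extinction coefficient and the
#' elemental composition.
#'
#' @param peptide A single-row `peptide_library` data frame or a sequence.
#' @return A `mass_profile` list.
#' @export
mass_profile <- function(peptide) {
  if (is.data.frame(peptide)) {
    stopifnot(nrow(peptide) == 1L)
    id <- peptide$id
    seq <- peptide$sequence
  } else {
    id <- "peptide"
    seq <- peptide
  }
  assert_peptide(seq)
  n_cys <- sum(strsplit(seq, "")[[1]] == "C")
  n_max <- bridge_count(n_cys)
  mono0 <- peptide_mass(seq, "mono")
  avg0 <- peptide_mass(seq, "average")
  structure(list(
    peptide_id = id, sequence = seq, n_bridges_max = n_max,
    monoisotopic_reduced = mono0, average_reduced = avg0,
    species = oxidized_species(mono0, avg0, n_max),
    epsilon_280 = extinction_coeff(seq),
    composition = elemental_composition(seq)
  ), class = "mass_profile")
}

#' Disulphide mass ladder
#'
#' Species with `n = 0..n_bridges_max` bridges; each bridge removes two
#' hydrogen atoms.
#'
#' @param mono_reduced,average_reduced Reduced-form masses in Da.
#' @param n_bridges_max Maximum bridge count (>= 0).
#' @return Data frame `n_bridges`, `mono`, `average`, masses strictly
#'   decreasing in `n_bridges`.
#' @export
oxidized_species <- function(mono_reduced, average_reduced, n_bridges_max) {
  stopifnot(n_bridges_max >= 0L)
  n <- 0:n_bridges_max
  data.frame(n_bridges = n,
             mono = mono_reduced - 2 * n * MH_MONO,
             average = average_reduced - 2 * n * MH_AVG)
}

## ---- isotope engine -------------------------------------------------------

## distribution of one element as abundance vector indexed by nucleon offset
element_offset_dist <- function(element) {
  iso <- ELEMENT_ISOTOPES[[element]]
  out <- numeric(max(iso$offset) + 1L)
  out[iso$offset + 1L] <- iso$abundance / sum(iso$abundance)
  out
}

convolve_dist <- function(a, b, prune = 0) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  if (prune > 0) {
    keep <- max(which(out > prune * max(out)))
    out <- out[seq_len(keep)]
  }
  out
}

## distribution of n identical atoms by binary exponentiation
atoms_dist <- function(base, n, prune = 0) {
  out <- 1
  p <- base
  while (n > 0L) {
    if (n %% 2L == 1L) out <- convolve_dist(out, p, prune)
    p <- convolve_dist(p, p, prune)
    n <- n %/% 2L
  }
  out
}

#' Aggregated isotope distribution for an elemental composition
#'
#' Convolves the per-element isotopologue distributions (binomial /
#' multinomial over the natural isotope abundances) into the aggregated
#' (nominal-offset) pattern.
#'
#' @param composition Named counts over C, H, N, O, S.
#' @param prune Internal pruning threshold relative to the running maximum
#'   (0 disables pruning; the default keeps full double precision for
#'   peptide-sized compositions).
#' @return Numeric vector of probabilities indexed by nucleon offset 0, 1,
#'   2, ... (sums to 1 up to pruning).
#' @export
isotope_distribution <- function(composition, prune = 1e-12) {
  out <- 1
  for (el in names(composition)) {
    n <- composition[[el]]
    if (n == 0) next
    out <- convolve_dist(out, atoms_dist(element_offset_dist(el), n, prune),
                         prune)
  }
  out
}

#' Theoretical isotope pattern of a peptide species
#'
#' Aggregated isotopic distribution of the peptide with `n_bridges`
#' disulphide bridges (composition minus 2 H per bridge), normalized to a
#' maximum abundance of 1 and truncated below `trunc`.
#'
#' @param sequence Amino-acid sequence.
#' @param n_bridges Bridge count of the species.
#' @param trunc Drop offsets with relative abundance below this (default
#'   1e-4).
#' @return Data frame `offset` (nominal Da above the monoisotopic peak) and
#'   `abundance` (max-normalized).
#' @export
theoretical_isotope_pattern <- function(sequence, n_bridges = 0L,
                                        trunc = 1e-4) {
  comp <- elemental_composition(sequence, n_bridges)
  d <- isotope_distribution(comp)
  rel <- d / max(d)
  keep <- rel >= trunc
  data.frame(offset = which(keep) - 1L, abundance = rel[keep])
}

## ---- observed-mass matching ----------------------------------------------

#' Call the oxidation state of an observed mass
#'
#' Selects the ladder species minimizing |observed - theoretical|; ties are
#' broken toward the more oxidized species (higher bridge count), mirroring
#' the observation that reduced forms are essentially never seen for
#' periplasmically oxidized peptides. No species within tolerance gives
#' `no_match`.
#'
#' @param profile A `mass_profile`.
#' @param observed Observed deconvoluted mass in Da.
#' @param tolerance Matching tolerance in Da (default 1.0, suited to
#'   average-mass deconvolution on quadrupole-class instruments).
#' @param mode `"average"` (default) or `"mono"`.
#' @return A `qc_result` list: `peptide_id`, `observed`, `matched_bridges`
#'   (NA when unmatched), `delta`, `status` in `fully_oxidized`,
#'   `partially_oxidized`, `reduced`, `no_match`, and `tolerance`.
#' @export
match_observed <- function(profile, observed, tolerance = 1.0,
                           mode = c("average", "mono")) {
  mode <- match.arg(mode)
  stopifnot(tolerance > 0)
  sp <- profile$species
  theo <- sp[[mode]]
  dev <- abs(observed - theo)
  # ties (to within float precision) resolve toward higher n_bridges
  tied <- which(dev <= min(dev) + 1e-9)
  best <- tied[which.max(sp$n_bridges[tied])]
  if (dev[best] > tolerance) {
    res <- list(peptide_id = profile$peptide_id, observed = observed,
                matched_bridges = NA_integer_, delta = NA_real_,
                status = "no_match", tolerance = tolerance, mode = mode)
  } else {
    n <- sp$n_bridges[best]
    status <- if (n == profile$n_bridges_max) "fully_oxidized"
      else if (n == 0L) "reduced" else "partially_oxidized"
    res <- list(peptide_id = profile$peptide_id, observed = observed,
                matched_bridges = n, delta = observed - theo[best],
                status = status, tolerance = tolerance, mode = mode)
  }
  structure(res, class = "qc_result")
}

#' QC a table of observed masses
#'
#' @param library A `peptide_library`.
#' @param observed Data frame with columns `id` and `mass_da` (or a CSV
#'   path).
#' @param tolerance Matching tolerance in Da.
#' @param mode `"average"` or `"mono"`.
#' @return Data frame: `id`, `observed`, `matched_bridges`, `delta`,
#'   `status`.
#' @export
qc_observed_masses <- function(library, observed, tolerance = 1.0,
                               mode = "average") {
  if (is.character(observed)) {
    observed <- read.delim(observed, sep = ",", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "mass_da") %in% names(observed)))
  do.call(rbind, lapply(seq_len(nrow(observed)), function(k) {
    i <- match(observed$id[k], library$id)
    if (is.na(i)) stop("observed mass for unknown peptide '",
                       observed$id[k], "'")
    r <- match_observed(mass_profile(library[i, ]), observed$mass_da[k],
                        tolerance, mode)
    data.frame(id = r$peptide_id, observed = r$observed,
               matched_bridges = r$matched_bridges, delta = r$delta,
               status = r$status, stringsAsFactors = FALSE)
  }))
}

## ---- quantification -------------------------------------------------------

#' A280 extinction coefficient (composition rule)
#'
#' `5500 * nTrp + 1490 * nTyr + 125 * n_cystine`, with `n_cystine` taken as
#' the maximum bridge count when `assume_cystine` is `TRUE`. A value of 0
#' (no Trp/Tyr/cystine) carries a `low_confidence` attribute: A280
#' quantification is unreliable for such peptides.
#'
#' @param sequence Amino-acid sequence.
#' @param assume_cystine Count cystines as `floor(n_cys / 2)` (default).
#' @return Extinction coefficient in per M per cm.
#' @export
extinction_coeff <- function(sequence, assume_cystine = TRUE) {
  assert_peptide(sequence)
  aa <- strsplit(sequence, "")[[1]]
  n_cystine <- if (assume_cystine) bridge_count(sum(aa == "C")) else 0L
  eps <- 5500 * sum(aa == "W") + 1490 * sum(aa == "Y") + 125 * n_cystine
  structure(eps, low_confidence = eps == 0)
}

#' Concentration, amount and culture yield
#'
#' Converts an A280 reading (or a directly supplied concentration) into
#' molar concentration, amount and yield per litre of culture.
#'
#' @param a280 Absorbance at 280 nm (1 cm path); give either this with
#'   `epsilon`, or `conc_uM`.
#' @param conc_uM Concentration in micromolar, if already known.
#' @param epsilon Extinction coefficient in per M per cm.
#' @param volume_uL Sample volume in microlitres (> 0).
#' @param mass_da Molecular mass in Da (> 0).
#' @param culture_mL Culture volume the sample derives from, in mL (> 0).
#' @return List: `conc_uM`, `amount_nmol`, `amount_ug`, `yield_mg_per_l`.
#' @export
concentration_and_yield <- function(a280 = NULL, conc_uM = NULL,
                                    epsilon = NULL, volume_uL, mass_da,
                                    culture_mL) {
  stopifnot(volume_uL > 0, mass_da > 0, culture_mL > 0)
  if (is.null(conc_uM)) {
    if (is.null(a280) || is.null(epsilon)) {
      stop("supply either conc_uM or both a280 and epsilon")
    }
    if (epsilon == 0) {
      stop("extinction coefficient is 0: A280 quantification impossible, ",
           "use chromatographic peak-area quantification instead")
    }
    conc_uM <- a280 / epsilon * 1e6
  }
  amount_nmol <- conc_uM * volume_uL / 1000
  amount_ug <- amount_nmol * mass_da / 1000
  list(conc_uM = conc_uM, amount_nmol = amount_nmol, amount_ug = amount_ug,
       yield_mg_per_l = (amount_ug / 1000) / (culture_mL / 1000))
}

#' Molar recovery of peptide relative to fusion
#'
#' `100 * (peptide_yield / peptide_mass) / (fusion_yield / fusion_mass)`:
#' the percentage of fusion moles recovered as purified peptide.
#'
#' @param fusion_yield Fusion yield in mg per litre of culture.
#' @param fusion_mass Fusion mass in Da.
#' @param peptide_yield Peptide yield in mg per litre of culture.
#' @param peptide_mass Peptide mass in Da.
#' @return Recovery in percent.
#' @export
molar_recovery <- function(fusion_yield, fusion_mass, peptide_yield,
                           peptide_mass) {
  stopifnot(fusion_yield > 0, fusion_mass > 0, peptide_yield > 0,
            peptide_mass > 0)
  100 * (peptide_yield / peptide_mass) / (fusion_yield / fusion_mass)
}
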