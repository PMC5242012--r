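test_that("peptide masses match standard residue tables and are additive", {
  expect_equal(peptide_mass("G", "mono"), 75.032, tolerance = 1e-3)
  expect_equal(peptide_mass("G", "average"), 75.067, tolerance = 1e-3)
  water_mono <- sum(venomlib:::WATER_FORMULA * venomlib:::ELEMENT_MONO)
  expect_equal(peptide_mass("GG", "mono"),
               2 * peptide_mass("G", "mono") - water_mono, tolerance = 1e-6)
  set.seed(3)
  for (mode in c("mono", "average")) {
    water <- if (mode == "mono") water_mono else
      sum(venomlib:::WATER_FORMULA * venomlib:::ELEMENT_AVG)
    for (i in 1:5) {
      s1 <- paste(sample(venomlib:::AA_LETTERS, 12, TRUE), collapse = "")
      s2 <- paste(sample(venomlib:::AA_LETTERS, 9, TRUE), collapse = "")
      expect_equal(peptide_mass(paste0(s1, s2), mode),
                   peptide_mass(s1, mode) + peptide_mass(s2, mode) - water,
                   tolerance = 1e-6)
    }
  }
  # heavier isotopes push the average above the monoisotopic mass
  expect_lt(peptide_mass("CMCMCACDEF", "mono"),
            peptide_mass("CMCMCACDEF", "average"))
  expect_error(peptide_mass("ABz"), "invalid amino-acid")
})

test_that("the disulphide ladder loses exactly two hydrogens per bridge", {
  sp <- oxidized_species(1000, 1001, 3L)
  expect_equal(sp$mono[2], 997.98435, tolerance = 1e-5)
  expect_equal(sp$n_bridges, 0:3)
  expect_equal(diff(sp$mono), rep(-2 * venomlib:::MH_MONO, 3),
               tolerance = 1e-12)
  expect_equal(diff(sp$average), rep(-2 * venomlib:::MH_AVG, 3),
               tolerance = 1e-12)
  expect_equal(sp$mono[1], 1000)  # n = 0 is the reduced form
  # strictly decreasing in n_bridges
  expect_true(all(diff(sp$mono) < 0) && all(diff(sp$average) < 0))
})

test_that("isotope engine matches single-atom ratios and normalization", {
  d <- isotope_distribution(c(C = 1))
  expect_equal(d[2] / d[1], 0.0107 / 0.9893, tolerance = 1e-9)
  d0 <- isotope_distribution(c(C = 30, H = 50, N = 10, O = 10, S = 4),
                             prune = 0)
  expect_equal(sum(d0), 1, tolerance = 1e-9)
  pat <- theoretical_isotope_pattern("GG")
  expect_equal(max(pat$abundance), 1)
  expect_true(all(pat$abundance >= 1e-4))
})

test_that("M+1/M grows about linearly with carbon count in poly-Gly", {
  ratios <- vapply(seq(10, 100, by = 10), function(n) {
    d <- isotope_distribution(elemental_composition(strrep("G", n)))
    d[2] / d[1]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  # deviation from the straight line through the endpoints stays tiny
  n <- seq(10, 100, by = 10)
  line <- ratios[1] + (ratios[10] - ratios[1]) * (n - 10) / 90
  expect_lt(max(abs(ratios - line)) / (ratios[10] - ratios[1]), 1e-3)
})

test_that("isotope engine agrees with an atom-by-atom expansion oracle", {
  # oracle: multiply in one atom at a time (plain polynomial expansion),
  # no binary exponentiation, no pruning
  oracle <- function(comp) {
    out <- 1
    for (el in names(comp)) {
      base <- venomlib:::element_offset_dist(el)
      for (i in seq_len(comp[[el]])) {
        new <- numeric(length(out) + length(base) - 1L)
        for (j in seq_along(base)) {
          idx <- j:(j + length(out) - 1L)
          new[idx] <- new[idx] + base[j] * out
        }
        out <- new
      }
    }
    out
  }
  comp <- c(C = 30, H = 50, N = 10, O = 10, S = 4)
  a <- isotope_distribution(comp, prune = 0)
  b <- oracle(comp)
  n <- min(length(a), length(b))
  expect_lt(max(abs(a[seq_len(n)] / max(a) - b[seq_len(n)] / max(b))), 1e-6)
})

test_that("oxidation-state calls follow nearest-species with oxidized ties", {
  lib <- generate_synthetic_library(1, seed = 5, bridge_range = c(3L, 3L))
  prof <- mass_profile(lib[1, ])
  full <- prof$species$average[prof$n_bridges_max + 1L]
  r <- match_observed(prof, full)
  expect_identical(r$status, "fully_oxidized")
  expect_equal(r$delta, 0)
  expect_identical(match_observed(prof, prof$average_reduced)$status,
                   "reduced")
  # midway between n=2 and n=3 resolves to the more oxidized species
  mid <- prof$average_reduced - 5 * venomlib:::MH_AVG
  r <- match_observed(prof, mid, tolerance = 1.5)
  expect_identical(r$matched_bridges, 3L)
  expect_identical(match_observed(prof, full + 50)$status, "no_match")
})

test_that("every generated peptide matches its fully oxidized mass", {
  lib <- generate_synthetic_library(40, seed = 17)
  for (i in seq_len(nrow(lib))) {
    prof <- mass_profile(lib[i, ])
    obs <- prof$species$average[prof$n_bridges_max + 1L]
    expect_identical(match_observed(prof, obs, 1.0)$status, "fully_oxidized")
  }
})

test_that("extinction coefficients follow the composition rule", {
  expect_equal(as.numeric(extinction_coeff("GGAG")), 0)
  expect_true(attr(extinction_coeff("GGAG"), "low_confidence"))
  expect_equal(as.numeric(extinction_coeff("GWG")), 5500)
  expect_equal(as.numeric(extinction_coeff("YYCC")), 2 * 1490 + 125)
  expect_equal(as.numeric(extinction_coeff("YYCC", assume_cystine = FALSE)),
               2 * 1490)
})

test_that("concentration and yield conversions are exact arithmetic", {
  r <- concentration_and_yield(conc_uM = 65.6, volume_uL = 250,
                               mass_da = 5935, culture_mL = 24)
  expect_equal(r$amount_nmol, 16.4)
  expect_equal(r$amount_ug, 16.4 * 5935 / 1000, tolerance = 1e-9)
  r2 <- concentration_and_yield(conc_uM = 16.4 / 250 * 1000, volume_uL = 250,
                                mass_da = 97e3 / 16.4, culture_mL = 24)
  expect_equal(r2$conc_uM, 65.6)
  expect_equal(r2$yield_mg_per_l, 0.097 / 0.024, tolerance = 1e-4)
  a <- concentration_and_yield(a280 = 0.55, epsilon = 5500, volume_uL = 250,
                               mass_da = 4000, culture_mL = 24)
  expect_equal(a$conc_uM, 100)
  expect_error(concentration_and_yield(a280 = 1, epsilon = 0,
                                       volume_uL = 250, mass_da = 4000,
                                       culture_mL = 24), "peak-area")
  expect_error(concentration_and_yield(conc_uM = 10, volume_uL = 0,
                                       mass_da = 4000, culture_mL = 24))
})

test_that("molar recovery reproduces the reference worked example", {
  fusion_mass_da <- 5935 / 0.176
  expect_equal(round(molar_recovery(186, fusion_mass_da, 3.91, 5935), 1),
               11.9)
  expect_equal(molar_recovery(10, 30000, 10 * 5000 / 30000, 5000), 100)
  expect_equal(molar_recovery(186, 33722, 2, 5935),
               2 * molar_recovery(186, 33722, 1, 5935))
})

test_that("QC tables join observed masses to profiles", {
  lib <- generate_synthetic_library(5, seed = 23)
  obs <- data.frame(
    id = lib$id,
    mass_da = vapply(seq_len(nrow(lib)), function(i) {
      p <- mass_profile(lib[i, ])
      p$species$average[p$n_bridges_max + 1L] + 0.2
    }, numeric(1)))
  qc <- qc_observed_masses(lib, obs)
  expect_equal(nrow(qc), 5L)
  expect_true(all(qc$status == "fully_oxidized"))
  expect_true(all(abs(qc$delta - 0.2) < 1e-9))
  expect_error(qc_observed_masses(lib, data.frame(id = "nope", mass_da = 1)),
               "unknown peptide")
})
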