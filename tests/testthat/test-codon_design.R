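test_that("relative adaptiveness normalizes within synonymous families", {
  fam <- data.frame(codon = c("AAA", "AAG"), aa = "K", freq = c(0.75, 0.25))
  expect_equal(relative_adaptiveness(fam), c(1, 1 / 3), tolerance = 1e-12)
  one <- data.frame(codon = "ATG", aa = "M", freq = 5)
  expect_equal(relative_adaptiveness(one), 1)
  tied <- data.frame(codon = c("GGT", "GGC"), aa = "G", freq = c(2, 2))
  expect_equal(relative_adaptiveness(tied), c(1, 1))
  zero <- data.frame(codon = c("AAA", "AAG"), aa = "K", freq = c(0, 0))
  expect_error(relative_adaptiveness(zero), "all-zero")
})

test_that("the packaged codon table is complete and valid", {
  expect_equal(nrow(default_table), 61L)
  maxw <- tapply(default_table$w, default_table$aa, max)
  expect_true(all(maxw == 1))
  expect_true(all(default_table$freq >= 0))
})

test_that("CAI is the geometric mean of w over scored codons", {
  # a gene of only w = 1 codons scores exactly 1
  dna <- back_translate_initial("GAVLK", default_table)
  expect_identical(cai(dna, default_table), 1)
  # two scored codons with w 1 and 0.25 -> sqrt(0.25)
  tab <- tweaked_table(c(AAA = 0.8, AAG = 0.2))
  expect_equal(cai("AAAAAG", tab), 0.5, tolerance = 1e-12)
  # Met/Trp are excluded by default but scorable on request
  expect_identical(cai("ATGTGG", default_table, exclude = character(0)), 1)
  expect_error(cai("ATGTGG", default_table), "no scorable codons")
  # internal stop is an error; a terminal stop run is not
  expect_error(cai("AAATAAAAA", default_table), "stop")
  expect_silent(cai("AAATAATAA", default_table))
  set.seed(1)
  for (pep in replicate(5, paste(sample(venomlib:::AA_LETTERS, 20,
                                        replace = TRUE), collapse = ""))) {
    v <- cai(back_translate_initial(pep, default_table), default_table)
    expect_true(v > 0 && v <= 1)
  }
})

test_that("GC content and run lengths are measured correctly", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGGG"), 100)
  expect_equal(gc_content("GAGAACCTGTACTTCCAA"), 100 * 8 / 18)
  expect_equal(max_run("AAAAAA", "homopolymer"), 6L)
  expect_equal(max_run("GCGCGCG", "gc_run"), 7L)
  expect_equal(max_run("GCGTA", "gc_run"), 3L)
  expect_equal(max_run("ATAT", "gc_run"), 0L)
})

test_that("initial back-translation uses top codons and balances cysteines", {
  expect_equal(back_translate_initial("M", default_table), "ATG")
  cc <- venomlib:::split_codons(back_translate_initial("CC", default_table))
  expect_setequal(cc, c("TGC", "TGT"))
  set.seed(2)
  for (pep in replicate(5, paste(sample(venomlib:::AA_LETTERS, 40,
                                        replace = TRUE), collapse = ""))) {
    dna <- back_translate_initial(pep, default_table)
    expect_identical(translate_dna(dna), pep)
    n_tgc <- sum(venomlib:::split_codons(dna) == "TGC")
    n_tgt <- sum(venomlib:::split_codons(dna) == "TGT")
    expect_lte(abs(n_tgc - n_tgt), 1L)
  }
})

test_that("motif screening reports both strands with 0-based positions", {
  hits <- screen_motifs("GGTATAATGG", "TATAAT")
  expect_equal(hits$position, 2L)
  expect_equal(hits$strand, "+")
  expect_equal(nrow(screen_motifs("GGGGGG", "TATAAT")), 0L)
  # plant the motif on the bottom strand only
  dna <- paste0("GGGCCC", revcomp("TATAAT"), "GGGCCC")
  hits <- screen_motifs(dna, "TATAAT")
  expect_equal(hits$strand, "-")
  expect_equal(hits$position, 6L)
})

test_that("optimized designs encode the TEV site, peptide and double stop", {
  lib <- generate_synthetic_library(5, seed = 21)
  for (i in seq_len(nrow(lib))) {
    d <- optimize_gene(lib[i, ], default_table, seed = 5)
    expect_equal(nchar(d$cds), 18L + 3L * lib$length[i] + 6L)
    expect_identical(substr(d$cds, 1, 18), "GAGAACCTGTACTTCCAA")
    expect_identical(substr(d$cds, nchar(d$cds) - 5L, nchar(d$cds)), "TAATAA")
    aa <- translate_dna(d$cds)
    expect_identical(sub("\\*+$", "", aa), paste0("ENLYFQ", lib$sequence[i]))
  }
})

test_that("homopolymer violations are repaired by synonymous swaps", {
  d <- optimize_gene("KKKKKKKKKK", default_table, seed = 1)
  expect_lte(max_run(d$cds, "homopolymer"), 5L)
  expect_true(d$flags[["homopolymer"]])
  # lysine runs can only be broken with AAG
  expect_true(grepl("AAG", d$cds, fixed = TRUE))
  expect_identical(translate_dna(d$cds), paste0("ENLYFQ", "KKKKKKKKKK", "**"))
})

test_that("the optimizer is deterministic under a fixed seed", {
  lib <- generate_synthetic_library(3, seed = 31)
  for (i in seq_len(nrow(lib))) {
    d1 <- optimize_gene(lib[i, ], default_table, seed = 99)
    d2 <- optimize_gene(lib[i, ], default_table, seed = 99)
    expect_identical(d1$cds, d2$cds)
  }
})

test_that("passing designs satisfy every constraint they flag", {
  lib <- generate_synthetic_library(30, seed = 41)
  designs <- design_genes(lib, default_table, seed = 8)
  cons <- design_constraints()
  for (d in designs) {
    if (!d$all_pass) next
    expect_gte(d$cai, cons$cai_min)
    expect_gte(d$gc_percent, cons$gc_min)
    expect_lte(d$gc_percent, cons$gc_max)
    expect_lte(d$max_homopolymer_observed, cons$max_homopolymer)
    expect_lte(d$max_gc_run_observed, cons$max_gc_run)
    expect_equal(nrow(d$motif_hits), 0L)
    expect_lte(abs(d$n_tgc - d$n_tgt), 1L)
  }
  expect_true(all(vapply(designs, `[[`, TRUE, "all_pass")))
})

test_that("unsatisfiable constraints yield failed flags, not errors", {
  # poly-F cannot reach 40% GC: TTT/TTC only
  d <- optimize_gene(strrep("F", 40), default_table, seed = 1)
  expect_s3_class(d, "gene_design")
  expect_false(d$flags[["gc"]])
  expect_false(d$all_pass)
})
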