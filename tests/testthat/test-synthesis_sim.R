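test_that("error model and policy validate their inputs", {
  expect_error(error_model(spectrum = c(deletion = 0.5, insertion = 0.5,
                                        substitution = 0.5)), "sum to 1")
  expect_error(error_model(rate_per_kb = -1))
  expect_error(screening_policy(0))
  m <- error_model()
  expect_equal(m$rate_per_kb, 1.06)
  expect_equal(unname(m$spectrum[c("deletion", "insertion", "substitution")]),
               c(0.76, 0.07, 0.17))
})

test_that("a zero error rate leaves clones untouched", {
  set.seed(1)
  g <- random_gene(500)
  r <- mutate_clone(g, error_model(rate_per_kb = 0))
  expect_identical(r$sequence, g)
  expect_equal(nrow(r$errors), 0L)
})

test_that("error counts and type spectrum converge to the model", {
  set.seed(2)
  g <- random_gene(1000)
  model <- error_model()          # 1.06 errors/kb on a 1 kb gene
  n_rep <- 30000
  counts <- integer(n_rep)
  types <- c(deletion = 0L, insertion = 0L, substitution = 0L)
  for (i in seq_len(n_rep)) {
    r <- mutate_clone(g, model)
    counts[i] <- nrow(r$errors)
    if (counts[i] > 0) {
      tc <- table(r$errors$type)
      types[names(tc)] <- types[names(tc)] + as.integer(tc)
    }
  }
  mc_se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - 1.06), 3 * mc_se)
  props <- types / sum(types)
  for (ty in names(model$spectrum)) {
    p <- model$spectrum[[ty]]
    se <- sqrt(p * (1 - p) / sum(types))
    expect_lt(abs(props[[ty]] - p), 4 * se)
  }
  # lengths shift by indels as expected
  dels <- sum(types["deletion"]); ins <- sum(types["insertion"])
  expect_true(dels > ins)
})

test_that("mutated clones differ where the error list says", {
  set.seed(3)
  g <- random_gene(300)
  model <- error_model(rate_per_kb = 10)
  for (i in 1:20) {
    r <- mutate_clone(g, model)
    n_del <- sum(r$errors$type == "deletion")
    n_ins <- sum(r$errors$type == "insertion")
    expect_equal(nchar(r$sequence), 300 - n_del + n_ins)
    if (nrow(r$errors) == 0) expect_identical(r$sequence, g)
  }
})

test_that("first-colony success matches the Poisson closed form", {
  set.seed(4)
  n <- 1500
  for (rate in c(0.5, 1.06, 2.0)) {
    for (L in c(137, 220, 413)) {
      genes <- rep(random_gene(L), n)
      sim <- simulate_screening(genes, error_model(rate_per_kb = rate),
                                seed = 17 + round(100 * rate) + L)
      p <- analytic_correct_prob(rate, L)
      se <- sqrt(p * (1 - p) / n)
      # 3.29 se (99.9% two-sided) keeps the family-wise error of the 9
      # rate-by-length combinations below about 1%
      expect_lt(abs(sim$fraction_correct_at[1] - p), 3.29 * se)
    }
  }
})

test_that("screening aggregates match sequential-success closed forms", {
  # per-clone success calibrated to 0.765 on 220-nt genes
  L <- 220
  p <- 0.765
  rate <- -log(p) * 1000 / L
  q <- 1 - p
  set.seed(5)
  genes <- replicate(4992, random_gene(L))
  sim <- simulate_screening(genes, error_model(rate_per_kb = rate), seed = 9)
  mean_theory <- (p + 2 * p * q + 3 * p * q^2) / (1 - q^3)
  expect_equal(sim$mean_colonies_recovered, mean_theory, tolerance = 0.03)
  expect_equal(sim$overall_recovery, 1 - q^3, tolerance = 0.006)
  expect_true(all(sim$per_gene$colonies <= 3L))
  expect_true(all(sim$fraction_correct_at >= 0 &
                    sim$fraction_correct_at <= 1))
})

test_that("screening runs are reproducible bit-for-bit under a seed", {
  genes <- replicate(50, random_gene(200))
  a <- simulate_screening(genes, seed = 7)
  b <- simulate_screening(genes, seed = 7)
  expect_identical(a[setdiff(names(a), "seed")], b[setdiff(names(b), "seed")])
  c <- simulate_screening(genes, seed = 8)
  expect_false(identical(a$per_gene, c$per_gene))
})

test_that("a zero rate recovers everything on the first colony", {
  genes <- replicate(20, random_gene(150))
  sim <- simulate_screening(genes, error_model(rate_per_kb = 0), seed = 1)
  expect_equal(sim$fraction_correct_at[1], 1)
  expect_equal(sim$mean_colonies_recovered, 1.0)
  expect_equal(sim$rate_naive, 0)
})

test_that("the analytic clone-correctness oracle behaves", {
  expect_equal(analytic_correct_prob(0, 220), 1.0)
  expect_equal(analytic_correct_prob(1.06, 220), exp(-0.2332))
  expect_equal(round(analytic_correct_prob(1.06, 220), 3), 0.792)
  Ls <- seq(100, 1000, by = 100)
  expect_true(all(diff(analytic_correct_prob(1.06, Ls)) < 0))
})

test_that("cascade statistics reproduce the reference screening counts", {
  s <- screening_statistics(c(3818, 809, 365), 4992)
  expect_equal(s$fraction_pct, c(76.5, 16.2, 7.3))
  expect_equal(s$mean_colonies, 1.3)
  expect_equal(s$overall_recovery_pct, 100)
  expect_equal(screening_statistics(c(10, 0, 0), 10)$mean_colonies, 1.0)
  expect_equal(screening_statistics(c(0, 0, 10), 10)$mean_colonies, 3.0)
  expect_error(screening_statistics(c(8, 4), 10), "exceeds")
})

test_that("estimated error rates bracket the configured rate", {
  set.seed(6)
  genes <- replicate(3000, random_gene(220))
  sim <- simulate_screening(genes, error_model(rate_per_kb = 1.06),
                            seed = 13)
  # ML estimator is consistent for the underlying per-base rate
  expect_equal(sim$rate_ml, 1.06, tolerance = 0.12)
  # naive estimator undercounts multi-error clones, so sits at or below the
  # true expected-errors-per-kb among incorrect clones
  expect_gt(sim$rate_naive, 0.8)
  expect_lt(sim$rate_naive, 1.2)
})
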