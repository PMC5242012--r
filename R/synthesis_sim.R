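# Simulation of errors introduced during oligo-based gene synthesis and of
# the sequential colony-screening policy used to recover correct clones.
# Errors are single-base events: per clone the error count is Poisson with
# mean rate_per_kb * L / 1000, positions are uniform and types follow the
# configured spectrum (deletion / insertion / substitution).

#' Gene-synthesis error model
#'
#' @param rate_per_kb Errors per 1000 nt of synthesized DNA (default 1.06,
#'   typical of uncorrected PCR assembly from chemically synthesized
#'   oligos).
#' @param spectrum Named proportions over `deletion`, `insertion`,
#'   `substitution`, summing to 1; the default 0.76 / 0.07 / 0.17 reflects
#'   the dominance of deletions from truncated oligos.
#' @return An `error_model` list.
#' @export
error_model <- function(rate_per_kb = 1.06,
                        spectrum = c(deletion = 0.76, insertion = 0.07,
                                     substitution = 0.17)) {
  stopifnot(rate_per_kb >= 0)
  if (abs(sum(spectrum) - 1) > 1e-9) stop("error spectrum must sum to 1")
  if (!all(sort(names(spectrum)) ==
             c("deletion", "insertion", "substitution"))) {
    stop("spectrum needs deletion, insertion and substitution entries")
  }
  structure(list(rate_per_kb = rate_per_kb, spectrum = spectrum),
            class = "error_model")
}

#' Colony-screening policy
#'
#' @param max_colonies Colonies screened per gene before giving up
#'   (default 3).
#' @return A `screening_policy` list.
#' @export
screening_policy <- function(max_colonies = 3L) {
  stopifnot(max_colonies >= 1L)
  structure(list(max_colonies = as.integer(max_colonies)),
            class = "screening_policy")
}

#' Mutate one synthesized clone of a gene
#'
#' Draws `Poisson(rate_per_kb * L / 1000)` single-base errors, with uniform
#' positions on the original sequence and types from the model spectrum.
#' Deletions remove one base, insertions insert one uniform base after the
#' position, substitutions replace the base with a different uniform base.
#' Uses the current RNG state; seed the caller for reproducibility.
#'
#' @param gene DNA string.
#' @param model An [error_model()].
#' @return List: `sequence` (mutated clone), `errors` data frame (`type`,
#'   `position` 1-based on the original gene, `from`, `to`).
#' @export
mutate_clone <- function(gene, model = error_model()) {
  assert_dna(gene)
  L <- nchar(gene)
  n_err <- rpois(1L, model$rate_per_kb * L / 1000)
  empty <- data.frame(type = character(0), position = integer(0),
                      from = character(0), to = character(0))
  if (n_err == 0L) return(list(sequence = gene, errors = empty))
  pos <- sample.int(L, n_err, replace = TRUE)
  type <- sample(names(model$spectrum), n_err, replace = TRUE,
                 prob = model$spectrum)
  b <- strsplit(gene, "")[[1]]
  errors <- data.frame(type = type, position = pos,
                       from = b[pos], to = NA_character_,
                       stringsAsFactors = FALSE)
  # apply right-to-left so earlier positions stay valid
  ord <- order(pos, decreasing = TRUE)
  out <- b
  for (k in ord) {
    p <- pos[k]
    if (type[k] == "deletion") {
      out <- out[-p]
    } else if (type[k] == "insertion") {
      ins <- sample(DNA_BASES, 1L)
      errors$to[k] <- ins
      out <- append(out, ins, after = p)
    } else {
      alt <- sample(setdiff(DNA_BASES, out[p]), 1L)
      errors$to[k] <- alt
      out[p] <- alt
    }
  }
  list(sequence = paste(out, collapse = ""), errors = errors)
}

#' Probability that a synthesized clone is error-free
#'
#' Poisson closed form `exp(-rate_per_kb * L / 1000)`; the analytic oracle
#' for the clone simulator.
#'
#' @param rate_per_kb Error rate per 1000 nt.
#' @param L Gene length in nt.
#' @return Probability in (0, 1].
#' @export
analytic_correct_prob <- function(rate_per_kb, L) {
  stopifnot(rate_per_kb >= 0, L >= 1)
  exp(-rate_per_kb * L / 1000)
}

#' Simulate sequential colony screening over a gene library
#'
#' For each gene, independent clones are drawn through [mutate_clone()]
#' until one is error-free or the policy's colony budget is exhausted.
#'
#' @param genes Character vector of gene sequences (or list of
#'   `gene_design` objects).
#' @param model An [error_model()].
#' @param policy A [screening_policy()].
#' @param seed Integer seed; the run is bit-for-bit reproducible.
#' @return A `sim_result` list: `per_gene` data frame (`gene`, `length_nt`,
#'   `colonies`, `recovered`), `fraction_correct_at` (per colony rank, of
#'   all genes), `overall_recovery`, `mean_colonies_recovered`,
#'   `error_type_counts`, `total_errors`, `kb_screened` and two errors/kb
#'   estimates: `rate_naive` (incorrect clones per kb screened, each
#'   incorrect clone counted as one error) and `rate_ml` (Poisson
#'   maximum-likelihood `-ln(first-colony success) / mean kb`).
#' @export
simulate_screening <- function(genes, model = error_model(),
                               policy = screening_policy(), seed = 1L) {
  if (is.list(genes) && !is.null(genes[[1L]]$cds)) {
    genes <- vapply(genes, `[[`, character(1), "cds")
  }
  stopifnot(length(genes) >= 1L)
  n <- length(genes)
  withr::with_seed(seed, {
    colonies <- integer(n)
    recovered <- logical(n)
    type_counts <- c(deletion = 0L, insertion = 0L, substitution = 0L)
    total_errors <- 0L
    incorrect_clones <- 0L
    clones_screened <- 0L
    kb_screened <- 0
    for (i in seq_len(n)) {
      for (k in seq_len(policy$max_colonies)) {
        clone <- mutate_clone(genes[i], model)
        clones_screened <- clones_screened + 1L
        kb_screened <- kb_screened + nchar(genes[i]) / 1000
        ok <- nrow(clone$errors) == 0L
        if (!ok) {
          incorrect_clones <- incorrect_clones + 1L
          total_errors <- total_errors + nrow(clone$errors)
          tc <- table(clone$errors$type)
          type_counts[names(tc)] <- type_counts[names(tc)] + as.integer(tc)
        }
        if (ok) {
          colonies[i] <- k
          recovered[i] <- TRUE
          break
        }
      }
      if (!recovered[i]) colonies[i] <- policy$max_colonies
    }
    correct_at <- vapply(seq_len(policy$max_colonies), function(k) {
      sum(recovered & colonies == k)
    }, integer(1))
    mean_len_kb <- mean(nchar(genes)) / 1000
    p1 <- correct_at[1L] / n
    structure(list(
      per_gene = data.frame(gene = seq_len(n), length_nt = nchar(genes),
                            colonies = colonies, recovered = recovered),
      n_genes = n,
      fraction_correct_at = correct_at / n,
      overall_recovery = sum(recovered) / n,
      mean_colonies_recovered = if (any(recovered))
        mean(colonies[recovered]) else NA_real_,
      error_type_counts = type_counts,
      total_errors = total_errors,
      clones_screened = clones_screened,
      kb_screened = kb_screened,
      rate_naive = incorrect_clones / kb_screened,
      rate_ml = if (p1 > 0) -log(p1) / mean_len_kb else Inf,
      seed = seed
    ), class = "sim_result")
  })
}

#' Screening-cascade statistics from observed counts
#'
#' Computes, from the counts of genes first found correct at each colony
#' rank, the per-rank fractions and the mean number of colonies screened
#' among the recovered genes.
#'
#' @param counts Integer vector: genes first correct at colony 1, 2, ...
#' @param total Total genes screened (>= `sum(counts)`).
#' @return List: `fraction_pct` (per rank, percent of `total`, 1 decimal),
#'   `overall_recovery_pct`, `mean_colonies` (1 decimal, among recovered).
#' @examples
#' screening_statistics(c(3818, 809, 365), 4992)
#' @export
screening_statistics <- function(counts, total) {
  stopifnot(all(counts >= 0), total >= 1)
  if (sum(counts) > total) stop("counts sum exceeds total")
  ranks <- seq_along(counts)
  mean_col <- if (sum(counts) > 0) sum(ranks * counts) / sum(counts)
    else NA_real_
  list(
    fraction_pct = round_half_up(100 * counts / total, 1L),
    overall_recovery_pct = round_half_up(100 * sum(counts) / total, 1L),
    mean_colonies = round_half_up(mean_col, 1L)
  )
}
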