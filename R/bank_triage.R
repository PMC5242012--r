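# Concentration triage into screening banks. Purified peptides are binned by
# measured concentration: above 20 uM the quantification is trusted and the
# stock is diluted to 10 uM; 5-20 uM goes into the 10 uM bank as-is; 1-5 uM
# into the separate 1 uM bank; below 1 uM the clone counts as non-producing.
# Boundaries are half-open so the prose ranges are disjoint: exactly 20 and
# exactly 5 fall in the as-is 10 uM bank, exactly 1 in the 1 uM bank.

FINAL_VOLUME_UL <- 250
TARGET_CONC_UM <- 10
PLATE_PEPTIDE_WELLS <- 80L
PLATE_COPIES <- 5L
ALIQUOT_UL <- 50

#' Triage one concentration into a banking bin
#'
#' @param conc Measured concentration in uM (>= 0).
#' @param peptide_id Identifier carried into the decision.
#' @return A `triage_decision` data frame row: `peptide_id`, `conc_uM`,
#'   `bin` (`adjust_to_10`, `bank10_asis`, `bank1`, `discard`), `bank`
#'   (`bank10`, `bank1` or NA), `stock_uL`, `water_uL`, `final_conc_uM`,
#'   `final_volume_uL`.
#' @examples
#' assign_bin(25)   # dilute: 100 uL stock + 150 uL water
#' assign_bin(0.5)  # discard
#' @export
assign_bin <- function(conc, peptide_id = "peptide") {
  if (conc < 0) stop("concentration must be non-negative")
  if (conc > 20) {
    stock <- FINAL_VOLUME_UL * TARGET_CONC_UM / conc
    out <- data.frame(peptide_id = peptide_id, conc_uM = conc,
                      bin = "adjust_to_10", bank = "bank10",
                      stock_uL = stock, water_uL = FINAL_VOLUME_UL - stock,
                      final_conc_uM = TARGET_CONC_UM,
                      final_volume_uL = FINAL_VOLUME_UL)
  } else if (conc >= 5) {
    out <- data.frame(peptide_id = peptide_id, conc_uM = conc,
                      bin = "bank10_asis", bank = "bank10",
                      stock_uL = FINAL_VOLUME_UL, water_uL = 0,
                      final_conc_uM = conc,
                      final_volume_uL = FINAL_VOLUME_UL)
  } else if (conc >= 1) {
    out <- data.frame(peptide_id = peptide_id, conc_uM = conc,
                      bin = "bank1", bank = "bank1",
                      stock_uL = FINAL_VOLUME_UL, water_uL = 0,
                      final_conc_uM = conc,
                      final_volume_uL = FINAL_VOLUME_UL)
  } else {
    out <- data.frame(peptide_id = peptide_id, conc_uM = conc,
                      bin = "discard", bank = NA_character_,
                      stock_uL = 0, water_uL = 0,
                      final_conc_uM = 0, final_volume_uL = 0)
  }
  class(out) <- c("triage_decision", class(out))
  out
}

#' Triage a vector of concentrations
#'
#' @param conc Concentrations in uM.
#' @param peptide_ids Identifiers (defaults to `p0001`, ...).
#' @return Data frame of triage decisions, one row per peptide.
#' @export
triage_library <- function(conc, peptide_ids = NULL) {
  if (is.null(peptide_ids)) {
    peptide_ids <- sprintf("p%04d", seq_along(conc))
  }
  stopifnot(length(conc) == length(peptide_ids))
  if (length(conc) == 0L) {
    out <- assign_bin(10)[0, ]
  } else {
    out <- do.call(rbind, Map(assign_bin, conc, peptide_ids))
  }
  rownames(out) <- NULL
  out
}

#' Lay out banked peptides on 96-well plates
#'
#' Fills plates in input order, the 10 uM and 1 uM banks separately. Each
#' full plate holds 80 peptides; the 16 wells of columns 1 and 12 are
#' reserved for assay controls. The last plate of a bank may be partial.
#' Each source deep-well plate spawns 5 microtiter copies of 50 uL
#' (5 x 50 uL = 250 uL stock, so copying is always feasible).
#'
#' @param decisions Triage decision data frame ([triage_library()]); discards
#'   are dropped.
#' @return List of `plate_layout` objects: `plate_id`, `bank`, `copies`,
#'   `aliquot_uL` and a 96-row `wells` data frame (`well`, `content`).
#' @export
layout_plates <- function(decisions) {
  decisions <- decisions[decisions$bin != "discard", , drop = FALSE]
  stopifnot(PLATE_COPIES * ALIQUOT_UL <= FINAL_VOLUME_UL)
  rows <- LETTERS[1:8]
  control_wells <- c(paste0(rows, 1), paste0(rows, 12))
  peptide_wells <- as.vector(t(outer(rows, 2:11, paste0)))  # A2..A11, B2..
  plates <- list()
  for (bank in c("bank10", "bank1")) {
    ids <- decisions$peptide_id[decisions$bank == bank]
    if (length(ids) == 0L) next
    n_plates <- ceiling(length(ids) / PLATE_PEPTIDE_WELLS)
    for (p in seq_len(n_plates)) {
      chunk <- ids[((p - 1L) * PLATE_PEPTIDE_WELLS + 1L):
                     min(p * PLATE_PEPTIDE_WELLS, length(ids))]
      wells <- data.frame(
        well = c(control_wells, peptide_wells),
        content = c(rep("CONTROL", length(control_wells)),
                    chunk,
                    rep(NA_character_,
                        length(peptide_wells) - length(chunk))),
        stringsAsFactors = FALSE
      )
      plates[[length(plates) + 1L]] <- structure(
        list(plate_id = sprintf("%s_plate%02d", bank, p), bank = bank,
             copies = PLATE_COPIES, aliquot_uL = ALIQUOT_UL, wells = wells),
        class = "plate_layout")
    }
  }
  plates
}

#' Summarize a triaged library
#'
#' @param decisions Triage decision data frame.
#' @return A `bank_summary` list: per-bin counts, integer percentages
#'   (half-away-from-zero rounding, the rendering convention used in
#'   production reports), bank totals, the above-20 uM sub-count within the
#'   10 uM bank and plate counts per bank.
#' @export
bank_summary <- function(decisions) {
  n <- nrow(decisions)
  bins <- c("adjust_to_10", "bank10_asis", "bank1", "discard")
  counts <- setNames(vapply(bins, function(b) sum(decisions$bin == b),
                            integer(1)), bins)
  if (is.null(n)) n <- 0L
  pct <- if (n > 0) round_half_up(100 * counts / n) else counts * 0
  n_bank10 <- counts[["adjust_to_10"]] + counts[["bank10_asis"]]
  n_bank1 <- counts[["bank1"]]
  structure(list(
    n = n,
    counts = counts,
    percent = pct,
    n_bank10 = n_bank10,
    n_bank1 = n_bank1,
    n_above20 = counts[["adjust_to_10"]],
    pct_above20_in_bank10 = if (n_bank10 > 0)
      round_half_up(100 * counts[["adjust_to_10"]] / n_bank10) else 0,
    plates_bank10 = as.integer(ceiling(n_bank10 / PLATE_PEPTIDE_WELLS)),
    plates_bank1 = as.integer(ceiling(n_bank1 / PLATE_PEPTIDE_WELLS))
  ), class = "bank_summary")
}

#' @export
print.bank_summary <- function(x, ...) {
  cat("Bank summary:", x$n, "peptides\n")
  for (b in names(x$counts)) {
    cat(sprintf("  %-13s %5d (%d%%)\n", b, x$counts[[b]], x$percent[[b]]))
  }
  cat(sprintf("  10 uM bank: %d peptides on %d plates (%d%% above 20 uM)\n",
              x$n_bank10, x$plates_bank10, x$pct_above20_in_bank10))
  cat(sprintf("  1 uM bank:  %d peptides on %d plates\n",
              x$n_bank1, x$plates_bank1))
  invisible(x)
}

#' Production success report by peptide group
#'
#' Groups production records and reports per-group totals, produced counts
#' and integer success percentages, ordered by group size (descending).
#'
#' @param records Data frame with at least `produced` (logical) plus the
#'   grouping columns: `taxon_group`, `length`, `n_bridges_max`,
#'   `odd_cysteines`, `sequence` or `nterm`, `pattern`.
#' @param group_by One of `taxon`, `length_class`, `n_bridges`,
#'   `odd_even_cys`, `nterm`, `pattern`.
#' @param length_breaks Bin edges for `length_class` grouping.
#' @return Data frame `group`, `n`, `n_produced`, `success_pct`.
#' @export
production_report <- function(records,
                              group_by = c("taxon", "length_class",
                                           "n_bridges", "odd_even_cys",
                                           "nterm", "pattern"),
                              length_breaks = DEFAULT_LENGTH_BREAKS) {
  stopifnot(nrow(records) > 0, is.logical(records$produced))
  group_by <- match.arg(group_by)
  key <- switch(group_by,
    taxon = records$taxon_group,
    length_class = length_class(records$length, length_breaks),
    n_bridges = as.character(records$n_bridges_max),
    odd_even_cys = ifelse(records$odd_cysteines, "odd", "even"),
    nterm = if (!is.null(records$nterm)) records$nterm else
      substr(records$sequence, 1L, 1L),
    pattern = records$pattern
  )
  agg <- do.call(rbind, lapply(split(seq_along(key), key), function(i) {
    data.frame(n = length(i), n_produced = sum(records$produced[i]))
  }))
  out <- data.frame(group = rownames(agg), n = agg$n,
                    n_produced = agg$n_produced,
                    success_pct = round_half_up(100 * agg$n_produced / agg$n),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write plate layouts as a CSV plate map
#'
#' @param plates List of `plate_layout` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_maps <- function(plates, path) {
  tab <- do.call(rbind, lapply(plates, function(p) {
    data.frame(plate = p$plate_id, bank = p$bank, well = p$wells$well,
               content = p$wells$content, stringsAsFactors = FALSE)
  }))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
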