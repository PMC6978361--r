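DRUG_CATEGORIES <- c("lethal", "sub_effective", "non_effective",
                     "growth_stimulatory")

#' Negative-control growth statistics
#'
#' @param fold_changes per-well fold changes of the negative-control
#'   (DMSO) wells.
#' @return list with `mean_fc`, `sd_fc`, `n`.
#' @export
neg_growth_stats <- function(fold_changes) {
  fold_changes <- fold_changes[is.finite(fold_changes)]
  if (length(fold_changes) < 1 || any(fold_changes <= 0)) {
    stop_ndr("negative-control fold changes must be positive",
             "ndr_domain_error")
  }
  sd_fc <- if (length(fold_changes) > 1) sd(fold_changes) else 0
  list(mean_fc = mean(fold_changes), sd_fc = sd_fc,
       n = length(fold_changes))
}

#' Classify a drug's potency from its top-concentration fold change
#'
#' Four categories, defined against the growth of the negative control:
#' * `lethal` — fold change < 1 (net loss of signal: more killing than
#'   growth);
#' * `sub_effective` — fold change >= 1 but more than `k_sd` standard
#'   deviations below the mean negative-control fold change (cytostatic or
#'   weakly toxic);
#' * `growth_stimulatory` — fold change more than `k_sd` SD above the
#'   negative-control mean;
#' * `non_effective` — within the negative-control band (boundary values
#'   inclusive: an effect is only claimed on strict exceedance).
#'
#' The bands partition the positive reals, so every valid fold change maps
#' to exactly one category.
#'
#' @param final_fc fold change(s) at the highest tested concentration.
#' @param stats a [neg_growth_stats()] list (`mean_fc`, `sd_fc`).
#' @param k_sd width of the negative-control band in standard deviations
#'   (default 1).
#' @return factor with levels lethal, sub_effective, non_effective,
#'   growth_stimulatory.
#' @export
classify_drug <- function(final_fc, stats, k_sd = 1) {
  if (any(!is.finite(final_fc)) || any(final_fc <= 0)) {
    stop_ndr("final fold change must be finite and > 0", "ndr_domain_error")
  }
  if (!is.finite(k_sd) || k_sd <= 0) {
    stop_ndr("k_sd must be > 0", "ndr_config_error")
  }
  lower <- stats$mean_fc - k_sd * stats$sd_fc
  upper <- stats$mean_fc + k_sd * stats$sd_fc
  out <- ifelse(final_fc < 1, "lethal",
         ifelse(final_fc < lower, "sub_effective",
         ifelse(final_fc > upper, "growth_stimulatory", "non_effective")))
  factor(out, levels = DRUG_CATEGORIES)
}

#' Classify every drug of a scored screen
#'
#' For each drug, takes the well at its highest tested concentration,
#' computes the fold change there, and applies [classify_drug()] against
#' the negative-control fold-change statistics (per plate by default).
#' Drugs whose top-concentration well is unusable (zero start readout) are
#' skipped with a warning.
#'
#' @param table a `screen_table` (scored or not; only readouts are needed).
#' @param k_sd band width in SD, see [classify_drug()].
#' @param per_plate compute negative-control statistics per plate (TRUE,
#'   default) or pooled over the screen.
#' @return data.frame with one row per drug: `drug_name`, `plate_id`,
#'   `concentration`, `final_fc`, `category`; per-category counts in
#'   attribute `"category_counts"`.
#' @export
classify_screen <- function(table, k_sd = 1, per_plate = TRUE) {
  stopifnot(inherits(table, "screen_table"))
  active <- table[table$role != "excluded", , drop = FALSE]
  drugs <- active[active$role == "drug", , drop = FALSE]
  if (nrow(drugs) == 0) {
    stop_ndr("no drug wells to classify", "ndr_validation_error")
  }
  stats_for <- function(plate) {
    neg <- active$role == "negative_control" &
      (if (per_plate) active$plate_id == plate else TRUE)
    neg_growth_stats(active$end_readout[neg] / active$start_readout[neg])
  }
  rows <- lapply(split(drugs, drugs$drug_name), function(d) {
    top <- d[which.max(d$concentration), , drop = FALSE]
    if (top$start_readout <= 0) {
      warn_ndr(sprintf(
        "drug %s: top-concentration well has zero start readout; skipped",
        top$drug_name), "ndr_skipped_drug_warning")
      return(NULL)
    }
    fc <- top$end_readout / top$start_readout
    data.frame(drug_name = top$drug_name, plate_id = top$plate_id,
               concentration = top$concentration, final_fc = fc,
               category = classify_drug(fc, stats_for(top$plate_id), k_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "category_counts") <- table(out$category)
  out
}
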