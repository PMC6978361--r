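# Guard against controls whose fold change is (numerically) 1: both the NDR
# and GR formulas divide by log2 of a control fold change.
LOG2_GUARD <- 1e-9

#' Fold change of a well between start and endpoint readouts
#'
#' @param start start readout (luminescence); must be > 0.
#' @param end endpoint readout; must be >= 0.
#' @param well optional well id used in error messages.
#' @return `end / start`.
#' @export
fold_change <- function(start, end, well = NULL) {
  if (any(!is.finite(start)) || any(start <= 0)) {
    stop_ndr(paste0("fold change undefined: start readout must be > 0",
                    if (!is.null(well)) paste0(" (well ", well, ")")),
             "ndr_domain_error")
  }
  if (any(!is.finite(end)) || any(end < 0)) {
    stop_ndr("fold change undefined: end readout must be finite and >= 0",
             "ndr_domain_error")
  }
  end / start
}

#' Aggregate a plate's control wells
#'
#' Summarizes the negative (DMSO) and positive (benzethonium chloride)
#' control wells of one plate into the quantities the response metrics
#' need: the median of the per-well fold changes of each control group
#' (robust against control outliers) and the median endpoint readout of
#' each group (used by the endpoint-only PI metric). Excluded wells are
#' ignored.
#'
#' The default aggregates per-well fold changes and then takes the median.
#' Set `aggregation = "fold_change_of_medians"` to instead take the fold
#' change of the median start and end readings.
#'
#' @param wells data.frame of one plate's wells (rows of a `screen_table`).
#' @param aggregation `"median_of_fold_changes"` (default) or
#'   `"fold_change_of_medians"`.
#' @return a `control_summary` list with `fold_change_neg`,
#'   `fold_change_pos`, `end_median_neg`, `end_median_pos`, `n_neg`, `n_pos`.
#' @export
aggregate_controls <- function(wells,
                               aggregation = c("median_of_fold_changes",
                                               "fold_change_of_medians")) {
  aggregation <- match.arg(aggregation)
  neg <- wells[wells$role == "negative_control", , drop = FALSE]
  pos <- wells[wells$role == "positive_control", , drop = FALSE]
  plate <- if (nrow(wells)) wells$plate_id[1] else "?"
  if (nrow(neg) < 2 || nrow(pos) < 2) {
    stop_ndr(sprintf(
      "plate %s: need >= 2 negative and >= 2 positive control wells (found %d / %d)",
      plate, nrow(neg), nrow(pos)), "ndr_control_error")
  }
  if (any(neg$start_readout <= 0) || any(pos$start_readout <= 0)) {
    stop_ndr(sprintf("plate %s: control well with start readout <= 0", plate),
             "ndr_domain_error")
  }
  fc_of <- function(ctrl) {
    if (aggregation == "median_of_fold_changes") {
      median(ctrl$end_readout / ctrl$start_readout)
    } else {
      median(ctrl$end_readout) / median(ctrl$start_readout)
    }
  }
  structure(list(
    plate_id = plate,
    fold_change_neg = fc_of(neg),
    fold_change_pos = fc_of(pos),
    end_median_neg = median(neg$end_readout),
    end_median_pos = median(pos$end_readout),
    n_neg = nrow(neg),
    n_pos = nrow(pos)
  ), class = "control_summary")
}

check_control_fc <- function(fc, which) {
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    stop_ndr(paste0(which, " fold change must be finite and > 0"),
             "ndr_domain_error")
  }
  if (any(abs(log2(fc)) < LOG2_GUARD)) {
    stop_ndr(paste0(which, " fold change is 1 (no net signal change); ",
                    "the metric is undefined for a non-responding control"),
             if (grepl("positive", which)) "ndr_positive_control_error"
            else "ndr_negative_control_error")
  }
  invisible(fc)
}

#' Normalized drug response (NDR)
#'
#' The NDR compares the log2 fold change of the drug-treated condition and
#' of the negative control, each relative to the log2 fold change of the
#' positive control (the assay's background, since the positive control is
#' expected to be 100% lethal):
#'
#' \deqn{NDR = \max\!\left(-1,\;
#'   \frac{1 - 2^{\log_2(fc_{drug}) / \log_2(fc_{pos})}}
#'        {1 - 2^{\log_2(fc_{neg}) / \log_2(fc_{pos})}}\right)}
#'
#' Interpretation: 1 = growth as in the negative control; 0 = complete
#' growth inhibition (cytostatic); -1 = complete killing (clamped); values
#' above 1 indicate a growth-stimulatory (proliferative) effect. There is
#' no upper clamp.
#'
#' @param fc_drug fold change(s) of the drug-treated condition.
#' @param fc_neg median fold change of the negative controls.
#' @param fc_pos median fold change of the positive controls.
#' @return NDR value(s), clamped below at -1.
#' @export
ndr <- function(fc_drug, fc_neg, fc_pos) {
  if (any(!is.finite(fc_drug)) || any(fc_drug <= 0)) {
    stop_ndr("drug fold change must be finite and > 0", "ndr_domain_error")
  }
  check_control_fc(fc_pos, "positive control")
  check_control_fc(fc_neg, "negative control")
  num <- 1 - 2^(log2(fc_drug) / log2(fc_pos))
  den <- 1 - 2^(log2(fc_neg) / log2(fc_pos))
  pmax(-1, num / den)
}

#' Growth rate (GR) metric
#'
#' Normalizes the drug-treated fold change against the negative control
#' only: \eqn{GR = 2^{\log_2(fc_{drug}) / \log_2(fc_{neg})} - 1}. GR = 1
#' for negative-control-like growth, 0 for complete growth inhibition, and
#' approaches -1 for complete killing. Unlike [ndr()], GR does not use the
#' positive control and therefore cannot correct for assay background.
#'
#' @inheritParams ndr
#' @return GR value(s).
#' @export
gr <- function(fc_drug, fc_neg) {
  if (any(!is.finite(fc_drug)) || any(fc_drug <= 0)) {
    stop_ndr("drug fold change must be finite and > 0", "ndr_domain_error")
  }
  check_control_fc(fc_neg, "negative control")
  2^(log2(fc_drug) / log2(fc_neg)) - 1
}

#' Percent inhibition (PI)
#'
#' Endpoint-only normalization between the control endpoints:
#' \eqn{PI = (end_{neg} - end_{drug}) / (end_{neg} - end_{pos})}.
#' Returned as a fraction (0 at the negative-control endpoint, 1 at the
#' positive-control endpoint); the conventional x100 percent scale is
#' applied by [scale_for_dss()].
#'
#' @param end_drug endpoint readout(s) of the drug-treated well(s).
#' @param end_neg median endpoint readout of the negative controls.
#' @param end_pos median endpoint readout of the positive controls.
#' @return PI fraction(s).
#' @export
percent_inhibition <- function(end_drug, end_neg, end_pos) {
  if (any(end_neg == end_pos)) {
    stop_ndr("degenerate controls: negative and positive endpoint medians are equal",
             "ndr_degenerate_controls_error")
  }
  (end_neg - end_drug) / (end_neg - end_pos)
}

#' Transform a response metric onto the percent-inhibition scale for DSS
#'
#' The drug sensitivity score integrates an inhibition curve anchored at
#' 0 (no inhibition) and 100 (complete inhibition). The three metrics are
#' mapped onto that scale as: PI_scaled = PI x 100;
#' GR_scaled = 0.5 x (1 - GR) x 100; NDR_scaled = 0.5 x (1 - NDR) x 100.
#' Values outside [0, 100] are permitted (growth-stimulatory responses map
#' below 0, super-lethal NDR < -1 cannot occur because of the clamp).
#'
#' @param metric one of "NDR", "GR", "PI".
#' @param value response value(s) on the metric's native scale (PI as a
#'   fraction).
#' @return value(s) on the percent-inhibition scale.
#' @export
scale_for_dss <- function(metric, value) {
  switch(toupper(metric),
    PI  = value * 100,
    GR  = 0.5 * (1 - value) * 100,
    NDR = 0.5 * (1 - value) * 100,
    stop_ndr(paste0("unknown metric: ", metric), "ndr_config_error")
  )
}

#' Score every well of a screen with a response metric
#'
#' Aggregates the control wells of each plate with [aggregate_controls()],
#' then evaluates the chosen metric for every non-excluded well (controls
#' included, so that plate QC can operate on metric-transformed control
#' values). Wells flagged with a zero start readout are rejected for the
#' fold-change-based metrics.
#'
#' @param table a `screen_table`.
#' @param metric one of "NDR", "GR", "PI".
#' @param aggregation control aggregation mode, see [aggregate_controls()].
#' @return the table with added columns `fold_change` and `response`, the
#'   metric recorded in attribute `"metric"` and the per-plate
#'   `control_summary` objects in attribute `"control_summaries"`.
#' @export
score_screen <- function(table, metric = c("NDR", "GR", "PI"),
                         aggregation = "median_of_fold_changes") {
  stopifnot(inherits(table, "screen_table"))
  metric <- match.arg(toupper(metric[1]), c("NDR", "GR", "PI"))
  active <- table$role != "excluded"
  if (metric != "PI" && any(active & table$zero_start_flag)) {
    bad <- table[active & table$zero_start_flag, ]
    stop_ndr(sprintf(
      "zero start readout in well(s) %s: fold change undefined for %s",
      paste(paste0(bad$plate_id, ":", bad$well), collapse = ", "), metric),
      "ndr_domain_error")
  }
  table$fold_change <- NA_real_
  ok_start <- active & table$start_readout > 0
  table$fold_change[ok_start] <-
    table$end_readout[ok_start] / table$start_readout[ok_start]
  table$response <- NA_real_
  summaries <- list()
  for (plate in unique(table$plate_id)) {
    on_plate <- table$plate_id == plate & active
    cs <- tryCatch(
      aggregate_controls(table[on_plate, , drop = FALSE], aggregation),
      error = function(e) {
        stop_ndr(paste0("plate ", plate, ": ", conditionMessage(e)),
                 class(e)[1])
      })
    summaries[[plate]] <- cs
    idx <- which(on_plate)
    table$response[idx] <- switch(metric,
      NDR = ndr(table$fold_change[idx], cs$fold_change_neg, cs$fold_change_pos),
      GR  = gr(table$fold_change[idx], cs$fold_change_neg),
      PI  = percent_inhibition(table$end_readout[idx],
                               cs$end_median_neg, cs$end_median_pos))
  }
  attr(table, "metric") <- metric
  attr(table, "control_summaries") <- summaries
  table
}

#' Estimate a plate-wide start readout from an assumed fold change
#'
#' External dose-response datasets often provide only endpoint readouts.
#' Given the fold change observed for the same cell line in a screen that
#' did measure both time points, a uniform start readout is estimated as
#' the median negative-control endpoint divided by the assumed fold change,
#' and assigned to every well of the plate (uniform seeding assumption).
#'
#' @param end_readouts endpoint readouts of the plate's negative-control
#'   wells.
#' @param assumed_fold_change fold change assumed for unperturbed growth
#'   (e.g. 3.2 for MDA-MB-231 over 72 h).
#' @return the single start-readout estimate.
#' @export
estimate_start_readout <- function(end_readouts, assumed_fold_change) {
  if (length(end_readouts) == 0) {
    stop_ndr("no negative-control end readouts supplied", "ndr_control_error")
  }
  if (!is.finite(assumed_fold_change) || assumed_fold_change <= 0) {
    stop_ndr("assumed fold change must be > 0", "ndr_domain_error")
  }
  median(end_readouts) / assumed_fold_change
}

#' Fill missing start readouts of a screen from an assumed fold change
#'
#' Applies [estimate_start_readout()] per plate and writes the estimate
#' into `start_readout` for every well of that plate.
#'
#' @param table a `screen_table` (its start readouts are overwritten).
#' @param assumed_fold_change see [estimate_start_readout()].
#' @return the table with estimated start readouts.
#' @export
apply_start_estimate <- function(table, assumed_fold_change) {
  stopifnot(inherits(table, "screen_table"))
  for (plate in unique(table$plate_id)) {
    on_plate <- table$plate_id == plate
    neg <- on_plate & table$role == "negative_control"
    if (!any(neg)) {
      stop_ndr(paste0("plate ", plate, ": no negative controls for start estimation"),
               "ndr_control_error")
    }
    table$start_readout[on_plate] <-
      estimate_start_readout(table$end_readout[neg], assumed_fold_change)
  }
  table$zero_start_flag <- table$start_readout == 0
  table
}
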