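#' Construct a dose-response series
#'
#' Bundles one drug's concentrations with the responses measured at them
#' and a tag naming the scale the responses live on: a raw metric ("NDR",
#' "GR", "PI" as viability = 100 x (1 - PI)) or the percent-inhibition
#' scale produced by [scale_series_for_dss()] ("inhibition").
#'
#' @param drug_name drug label.
#' @param concentrations strictly increasing positive concentrations
#'   (molar).
#' @param responses numeric responses, one per concentration.
#' @param metric one of "NDR", "GR", "PI", "inhibition".
#' @return a `dose_series` object.
#' @export
response_series <- function(drug_name, concentrations, responses,
                            metric = c("NDR", "GR", "PI", "inhibition")) {
  metric <- match.arg(metric)
  concentrations <- as.numeric(concentrations)
  responses <- as.numeric(responses)
  if (length(concentrations) != length(responses)) {
    stop_ndr("concentrations and responses differ in length",
             "ndr_validation_error")
  }
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop_ndr("concentrations must be positive and strictly increasing",
             "ndr_validation_error")
  }
  structure(list(drug_name = drug_name, concentrations = concentrations,
                 responses = responses, metric = metric),
            class = "dose_series")
}

# Four-parameter log-logistic evaluated at log10 concentration x:
#   R(x) = r_min + (r_max - r_min) / (1 + 10^(slope * (log10(ec50) - x)))
# slope > 0: response increases with concentration (inhibition curves).
ll4 <- function(x, r_min, r_max, ec50, slope) {
  r_min + (r_max - r_min) / (1 + 10^(slope * (log10(ec50) - x)))
}

#' Predicted responses of a fitted 4PL curve
#'
#' @param curve a `logistic_curve` (component `curve` of a fit).
#' @param concentrations concentrations (molar) at which to evaluate.
#' @return predicted responses.
#' @export
predict_curve <- function(curve, concentrations) {
  ll4(log10(concentrations), curve$r_min, curve$r_max, curve$ec50,
      curve$slope)
}

new_logistic_curve <- function(r_min, r_max, ec50, slope) {
  # canonical orientation: top asymptote >= bottom asymptote
  if (r_max < r_min) {
    tmp <- r_min; r_min <- r_max; r_max <- tmp
    slope <- -slope
  }
  structure(list(r_min = r_min, r_max = r_max, ec50 = ec50, slope = slope),
            class = "logistic_curve")
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of the 4PL model in log10-concentration space by
#' Levenberg-Marquardt, with five data-driven starts: top/bottom asymptotes
#' from the extreme responses, EC50 from the concentration whose response is
#' nearest the half-range, and Hill slopes 0.5, 1 and 2 in the orientation
#' suggested by the data (plus two starts in the opposite orientation, so
#' non-monotone noise cannot trap the fit). The candidate with the lowest
#' residual sum of squares wins; ties are broken by the smallest absolute
#' slope. Curves are canonicalized so that `r_max >= r_min`, with the slope
#' sign carrying the direction (positive = response rises with
#' concentration).
#'
#' Identical responses at all concentrations yield a flat curve (both
#' asymptotes at that value, slope 0) with RMSD 0; this is a valid
#' degenerate fit, not an error.
#'
#' @param series a `dose_series` with at least 4 distinct concentrations.
#' @param max_iterations Levenberg-Marquardt iteration cap per start.
#' @return a `curve_fit` list: `curve` (`logistic_curve`), `fitted_values`,
#'   `observed`, `rmsd`, `converged`, `n_points`.
#' @export
fit_dose_response <- function(series, max_iterations = 200) {
  stopifnot(inherits(series, "dose_series"))
  x <- log10(series$concentrations)
  y <- series$responses
  n <- length(y)
  if (length(unique(series$concentrations)) < 4) {
    stop_ndr("4PL fitting requires >= 4 distinct concentrations",
             "ndr_fit_error")
  }
  finish <- function(curve, converged) {
    est <- ll4(x, curve$r_min, curve$r_max, curve$ec50, curve$slope)
    structure(list(curve = curve, fitted_values = est, observed = y,
                   rmsd = curve_rmsd(y, est), converged = converged,
                   n_points = n),
              class = "curve_fit")
  }
  if (diff(range(y)) == 0) {
    return(finish(new_logistic_curve(y[1], y[1],
                                     10^mean(range(x)), 0), TRUE))
  }
  # data-driven starting values
  lo <- min(y); hi <- max(y)
  half <- (lo + hi) / 2
  m0 <- x[which.min(abs(y - half))]
  updown <- sign(stats::cor(x, y, method = "spearman"))
  if (!is.finite(updown) || updown == 0) updown <- 1
  slopes <- c(0.5, 1, 2) * updown
  slopes <- c(slopes, c(0.5, 1) * -updown)
  best <- NULL
  for (s0 in slopes) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ rmin + (rmax - rmin) / (1 + 10^(b * (m - x))),
        start = list(rmin = lo, rmax = hi, m = m0, b = s0),
        control = minpack.lm::nls.lm.control(maxiter = max_iterations)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    b_est <- coef(fit)[["b"]]
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && abs(b_est) < abs(best$b))) {
      best <- list(fit = fit, rss = rss, b = b_est)
    }
  }
  if (is.null(best)) {
    # no start converged: report the flat mean curve, flagged
    return(finish(new_logistic_curve(mean(y), mean(y),
                                     10^mean(range(x)), 0), FALSE))
  }
  cf <- coef(best$fit)
  curve <- new_logistic_curve(cf[["rmin"]], cf[["rmax"]], 10^cf[["m"]],
                              cf[["b"]])
  finish(curve, isTRUE(best$fit$convInfo$isConv %||% TRUE))
}

#' Root mean squared distance between observed and fitted responses
#'
#' \eqn{RMSD = \sqrt{\frac{1}{N}\sum_i (O_i - E_i)^2}}.
#'
#' @param observed,estimated numeric vectors of equal length (N >= 1).
#' @return the RMSD.
#' @export
curve_rmsd <- function(observed, estimated) {
  if (length(observed) != length(estimated) || length(observed) < 1) {
    stop_ndr("observed and estimated must have equal length >= 1",
             "ndr_validation_error")
  }
  sqrt(mean((observed - estimated)^2))
}

#' Baseline distance of a dose-response series
#'
#' The lowest tested concentration is expected to show no effect; its
#' deviation from the negative-control viability level (1 for NDR and GR,
#' 100 for PI on the viability scale) is the baseline distance. Large
#' baseline distances signal normalization artifacts that bias fitted
#' IC50/EC50 values.
#'
#' @param series a `dose_series` tagged "NDR", "GR" or "PI" (PI responses
#'   on the 100-anchored viability orientation, viability = 100 x (1-PI)).
#' @return `|response at lowest concentration - baseline|`.
#' @export
baseline_distance <- function(series) {
  stopifnot(inherits(series, "dose_series"))
  baseline <- switch(series$metric,
    NDR = 1, GR = 1, PI = 100,
    stop_ndr("baseline distance is defined for NDR, GR and PI series",
             "ndr_config_error"))
  abs(series$responses[1] - baseline)
}

#' Rescale a series onto the percent-inhibition scale for DSS
#'
#' @param series a `dose_series` tagged "NDR", "GR" or "PI" (PI as a
#'   fraction).
#' @return the series with responses transformed by [scale_for_dss()] and
#'   metric set to "inhibition".
#' @export
scale_series_for_dss <- function(series) {
  stopifnot(inherits(series, "dose_series"))
  if (series$metric == "inhibition") return(series)
  response_series(series$drug_name, series$concentrations,
                  scale_for_dss(series$metric, series$responses),
                  metric = "inhibition")
}

#' DSS configuration
#'
#' @param a_min minimum activity level in percent inhibition; responses
#'   below it do not contribute to the score. Default 10.
#' @return a `dss_config` list.
#' @export
dss_config <- function(a_min = 10) {
  if (!is.finite(a_min) || a_min < 0 || a_min >= 100) {
    stop_ndr("a_min must lie in [0, 100)", "ndr_config_error")
  }
  structure(list(a_min = a_min), class = "dss_config")
}

# numerically stable log10(1 + 10^u) * ln(10)
log1p10 <- function(u) {
  ifelse(u > 15, u * log(10), log1p(10^u))
}

# Analytic integral of max(0, R(x) - a_min) for a monotone 4PL R over
# [x1, x2] in log10-concentration units.
ll4_area_above <- function(curve, a_min, x1, x2) {
  r_min <- curve$r_min; r_max <- curve$r_max
  s <- curve$slope; m <- log10(curve$ec50)
  L <- r_max - r_min
  if (abs(s) < 1e-9 || L < 1e-12) {
    level <- if (L < 1e-12) (r_min + r_max) / 2 else {
      # slope ~ 0 with distinct asymptotes: curve sits at its midpoint
      (r_min + r_max) / 2
    }
    return(max(0, level - a_min) * (x2 - x1))
  }
  r1 <- ll4(x1, r_min, r_max, curve$ec50, s)
  r2 <- ll4(x2, r_min, r_max, curve$ec50, s)
  if (max(r1, r2) <= a_min) return(0)
  if (min(r1, r2) >= a_min) {
    a <- x1; b <- x2
  } else {
    # crossing point of the monotone curve with a_min
    frac <- (a_min - r_min) / L              # in (0, 1) here
    xc <- m - log10(1 / frac - 1) / s
    if (r1 < a_min) { a <- xc; b <- x2 } else { a <- x1; b <- xc }
  }
  # antiderivative of R(x): r_min * x + L/(s ln10) * ln(1 + 10^(s(x - m)))
  F <- function(x) r_min * x + L / (s * log(10)) * log1p10(s * (x - m))
  (F(b) - F(a)) - a_min * (b - a)
}

#' Drug sensitivity score (DSS) of a fitted inhibition curve
#'
#' Integrates the fitted 4PL inhibition curve over the part of the tested
#' log10-concentration window where it exceeds the minimum activity level
#' `a_min`, and normalizes so that a curve pinned at 100% inhibition across
#' the whole window scores 100:
#'
#' \deqn{DSS = 100 \cdot
#'   \frac{\int_{x_{min}}^{x_{max}} \max(0, R(x) - A_{min})\,dx}
#'        {(100 - A_{min})(x_{max} - x_{min})}}
#'
#' The integral is evaluated in closed form from the fitted curve
#' parameters (top and bottom asymptotes, EC50/IC50, Hill slope).
#'
#' @param fit a `curve_fit` from [fit_dose_response()] on the scaled
#'   (percent-inhibition) series.
#' @param series the scaled `dose_series` that was fitted (defines the
#'   concentration window); must be tagged "inhibition".
#' @param config a [dss_config()].
#' @return the DSS, >= 0; 0 when the curve never exceeds `a_min`.
#' @export
compute_dss <- function(fit, series, config = dss_config()) {
  stopifnot(inherits(fit, "curve_fit"), inherits(series, "dose_series"),
            inherits(config, "dss_config"))
  if (series$metric != "inhibition") {
    stop_ndr("DSS requires responses on the percent-inhibition scale; apply scale_series_for_dss() first",
             "ndr_config_error")
  }
  x1 <- log10(min(series$concentrations))
  x2 <- log10(max(series$concentrations))
  area <- ll4_area_above(fit$curve, config$a_min, x1, x2)
  100 * area / ((100 - config$a_min) * (x2 - x1))
}

#' DSS for a uniformly growth-stimulatory (negative-response) series
#'
#' A drug whose scaled responses are negative at every tested concentration
#' stimulates growth; its dose-response curve is mirrored about the
#' zero-inhibition baseline (R -> -R), the DSS of the mirrored curve is
#' computed, and the score is reported with a negative sign. Series with
#' mixed-sign responses fall back to [compute_dss()] on the original fit.
#'
#' @param series a scaled (`"inhibition"`) `dose_series`.
#' @param config a [dss_config()].
#' @return the (possibly negative) DSS.
#' @export
negative_dss <- function(series, config = dss_config()) {
  stopifnot(inherits(series, "dose_series"))
  if (series$metric != "inhibition") {
    stop_ndr("DSS requires responses on the percent-inhibition scale; apply scale_series_for_dss() first",
             "ndr_config_error")
  }
  r <- series$responses
  if (all(r == 0)) return(0)
  if (all(r <= 0)) {
    mirrored <- response_series(series$drug_name, series$concentrations,
                                -r, metric = "inhibition")
    fit <- fit_dose_response(mirrored)
    return(-compute_dss(fit, mirrored, config))
  }
  warn_ndr("negative_dss called on mixed-sign responses; computing ordinary DSS",
           "ndr_mixed_sign_warning")
  fit <- fit_dose_response(series)
  compute_dss(fit, series, config)
}

#' Fit and score one series, choosing the negative-DSS path automatically
#'
#' Convenience wrapper used by the pipeline: series that are negative at
#' every concentration go through [negative_dss()], everything else through
#' [fit_dose_response()] + [compute_dss()].
#'
#' @inheritParams negative_dss
#' @return a list with `dss` and the `fit` used (NULL on the mirrored
#'   path's original orientation).
#' @export
dss_score <- function(series, config = dss_config()) {
  stopifnot(inherits(series, "dose_series"))
  if (series$metric != "inhibition") series <- scale_series_for_dss(series)
  if (all(series$responses <= 0) && any(series$responses < 0)) {
    return(list(dss = negative_dss(series, config), fit = NULL))
  }
  fit <- fit_dose_response(series)
  list(dss = compute_dss(fit, series, config), fit = fit)
}
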