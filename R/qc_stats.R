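#' Z'-factor plate quality statistic
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`, computed on the
#' metric-transformed control values of one plate (sample standard
#' deviations). Z' is at most 1, equals 1 only when both control groups
#' have zero spread, and values above 0.5 indicate a high-quality assay.
#'
#' @param neg_values responses of the negative-control wells (>= 2).
#' @param pos_values responses of the positive-control wells (>= 2).
#' @return the Z'-factor.
#' @export
z_prime <- function(neg_values, pos_values) {
  if (length(neg_values) < 2 || length(pos_values) < 2) {
    stop_ndr("need >= 2 values per control group", "ndr_validation_error")
  }
  mu_n <- mean(neg_values); mu_p <- mean(pos_values)
  if (mu_n == mu_p) {
    stop_ndr("control means are equal; Z'-factor undefined",
             "ndr_degenerate_controls_error")
  }
  1 - 3 * (sd(pos_values) + sd(neg_values)) / abs(mu_p - mu_n)
}

#' Per-plate Z'-factors of a scored screen
#'
#' @param scored a `screen_table` scored with [score_screen()].
#' @return data.frame `plate_id`, `z_prime`, `n_neg`, `n_pos`, `metric`.
#' @export
screen_z_prime <- function(scored) {
  stopifnot(inherits(scored, "screen_table"))
  if (is.null(scored$response)) {
    stop_ndr("screen is not scored; run score_screen() first",
             "ndr_config_error")
  }
  metric <- attr(scored, "metric")
  rows <- lapply(unique(scored$plate_id), function(p) {
    on_plate <- scored$plate_id == p
    neg <- scored$response[on_plate & scored$role == "negative_control"]
    pos <- scored$response[on_plate & scored$role == "positive_control"]
    data.frame(plate_id = p, z_prime = z_prime(neg, pos),
               n_neg = length(neg), n_pos = length(pos),
               metric = metric, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Absolute response differences between two replicate screens
#'
#' Matches drug wells by (plate, well) position and returns the absolute
#' difference of the responses at matched positions; a replicate-consistent
#' screen yields differences near zero. Unmatched wells are reported via a
#' warning.
#'
#' @param table_a,table_b scored `screen_table`s of two replicates.
#' @param drug_only match only drug wells (default TRUE).
#' @return numeric vector of per-well absolute differences.
#' @export
replicate_abs_diff <- function(table_a, table_b, drug_only = TRUE) {
  for (tb in list(table_a, table_b)) {
    if (is.null(tb$response)) {
      stop_ndr("both tables must be scored; run score_screen() first",
               "ndr_config_error")
    }
  }
  pick <- function(tb) {
    keep <- if (drug_only) tb$role == "drug" else tb$role != "excluded"
    tb <- tb[keep, , drop = FALSE]
    setNames(tb$response, paste(tb$plate_id, tb$well))
  }
  a <- pick(table_a); b <- pick(table_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) {
    stop_ndr("no matching (plate, well) positions between replicates",
             "ndr_validation_error")
  }
  unmatched <- length(a) + length(b) - 2 * length(shared)
  if (unmatched > 0) {
    warn_ndr(sprintf("%d well position(s) present in only one replicate",
                     unmatched), "ndr_unmatched_wells_warning")
  }
  abs(a[shared] - b[shared])
}

#' Deviation of responses from the per-well median across time points
#'
#' For screens measured at several end time points, computes for every
#' shared well and time the difference between the response at that time
#' and the median response of the well across all times. A time-consistent
#' metric keeps these differences near zero.
#'
#' @param responses_by_time named list (time label -> scored
#'   `screen_table`) with at least two time points.
#' @param drug_only use only drug wells (default TRUE).
#' @return data.frame `plate_id`, `well`, `time`, `response`, `difference`.
#' @export
time_consistency <- function(responses_by_time, drug_only = TRUE) {
  if (length(responses_by_time) < 2) {
    stop_ndr("need >= 2 time points", "ndr_validation_error")
  }
  times <- names(responses_by_time) %||%
    as.character(seq_along(responses_by_time))
  long <- do.call(rbind, lapply(seq_along(responses_by_time), function(i) {
    tb <- responses_by_time[[i]]
    if (is.null(tb$response)) {
      stop_ndr("all tables must be scored; run score_screen() first",
               "ndr_config_error")
    }
    keep <- if (drug_only) tb$role == "drug" else tb$role != "excluded"
    data.frame(plate_id = tb$plate_id[keep], well = tb$well[keep],
               time = times[i], response = tb$response[keep],
               stringsAsFactors = FALSE)
  }))
  key <- paste(long$plate_id, long$well)
  counts <- table(key)
  shared <- names(counts)[counts == length(responses_by_time)]
  long <- long[key %in% shared, , drop = FALSE]
  med <- tapply(long$response, paste(long$plate_id, long$well), median)
  long$difference <- as.numeric(long$response -
                                  med[paste(long$plate_id, long$well)])
  rownames(long) <- NULL
  long
}

#' Overlapping coefficient of two normal densities
#'
#' The integral of the pointwise minimum of two normal densities: 1 for
#' identical distributions, approaching 0 as they separate. For equal
#' variances the closed form `2 * pnorm(-|mu1 - mu2| / (2 sd))` is used;
#' otherwise the densities' intersection points (roots of a quadratic in
#' x) partition the line and the smaller density's mass is accumulated per
#' interval.
#'
#' @param mu1,sd1 mean and standard deviation of the first density
#'   (sd > 0).
#' @param mu2,sd2 mean and standard deviation of the second density.
#' @return the overlap, in `[0, 1]`.
#' @export
overlap_coefficient <- function(mu1, sd1, mu2, sd2) {
  if (sd1 <= 0 || sd2 <= 0) {
    stop_ndr("standard deviations must be > 0", "ndr_domain_error")
  }
  if (abs(sd1 - sd2) < 1e-12 * max(sd1, sd2)) {
    return(2 * pnorm(-abs(mu1 - mu2) / (2 * sd1)))
  }
  # intersection points: solve log f1(x) = log f2(x)
  A <- 1 / (2 * sd2^2) - 1 / (2 * sd1^2)
  B <- mu1 / sd1^2 - mu2 / sd2^2
  C <- mu2^2 / (2 * sd2^2) - mu1^2 / (2 * sd1^2) + log(sd2 / sd1)
  disc <- B^2 - 4 * A * C
  roots <- if (disc <= 0) numeric(0) else {
    # numerically stable quadratic roots (avoids cancellation when A is small)
    q <- -(B + sign(B) * sqrt(disc)) / 2
    sort(c(q / A, C / q))
  }
  cuts <- c(-Inf, roots, Inf)
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    a <- cuts[i]; b <- cuts[i + 1]
    mid <- if (is.infinite(a) && is.infinite(b)) (mu1 + mu2) / 2
           else if (is.infinite(a)) b - 1
           else if (is.infinite(b)) a + 1
           else (a + b) / 2
    # compare on the log scale: far tails underflow ordinary densities
    d1 <- stats::dnorm(mid, mu1, sd1, log = TRUE)
    d2 <- stats::dnorm(mid, mu2, sd2, log = TRUE)
    if (d1 <= d2) {
      total <- total + pnorm(b, mu1, sd1) - pnorm(a, mu1, sd1)
    } else {
      total <- total + pnorm(b, mu2, sd2) - pnorm(a, mu2, sd2)
    }
  }
  min(1, max(0, total))
}
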