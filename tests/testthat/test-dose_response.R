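ll4_ref <- function(x, r_min, r_max, ec50, slope) {
  r_min + (r_max - r_min) / (1 + 10^(slope * (log10(ec50) - x)))
}

# quadrature oracle for the DSS integral
dss_quadrature <- function(curve, a_min, x1, x2) {
  q <- integrate(function(x) {
    pmax(0, ll4_ref(x, curve$r_min, curve$r_max, curve$ec50, curve$slope) -
           a_min)
  }, x1, x2, rel.tol = 1e-10, subdivisions = 2000)
  100 * q$value / ((100 - a_min) * (x2 - x1))
}

test_that("noise-free 4PL data is recovered to 1e-3 relative", {
  concs <- dilution_series(1e-5, 5, 10)
  truth <- list(r_min = 0, r_max = 100, ec50 = 1e-7, slope = 1)
  y <- ll4_ref(log10(concs), truth$r_min, truth$r_max, truth$ec50,
               truth$slope)
  fit <- fit_dose_response(response_series("d", concs, y, "inhibition"))
  expect_true(fit$converged)
  expect_equal(fit$curve$r_max, truth$r_max, tolerance = 1e-3)
  expect_equal(fit$curve$ec50, truth$ec50, tolerance = 1e-3)
  expect_equal(fit$curve$slope, truth$slope, tolerance = 1e-3)
  expect_lt(abs(fit$curve$r_min), 1e-3 * truth$r_max)
  expect_lt(fit$rmsd, 1e-6)
  # refitting the fitted values reproduces the curve (idempotence)
  refit <- fit_dose_response(response_series("d", concs, fit$fitted_values,
                                             "inhibition"))
  expect_equal(refit$curve$ec50, fit$curve$ec50, tolerance = 1e-6)
  expect_equal(refit$curve$slope, fit$curve$slope, tolerance = 1e-6)
})

test_that("decreasing (viability-oriented) curves fit with a negative slope", {
  concs <- dilution_series(1e-5, 5, 10)
  y <- ll4_ref(log10(concs), 0, 1, 1e-7, -1.5)  # NDR-like, falls with dose
  fit <- fit_dose_response(response_series("d", concs, y, "NDR"))
  expect_equal(fit$curve$ec50, 1e-7, tolerance = 1e-3)
  expect_lt(fit$curve$slope, 0)
  expect_gte(fit$curve$r_max, fit$curve$r_min)
  expect_lt(fit$rmsd, 1e-6)
})

test_that("under 2% noise the EC50 is recovered within 0.1 log10 units (median of 200)", {
  set.seed(7)
  concs <- dilution_series(1e-5, 5, 10)
  y0 <- ll4_ref(log10(concs), 0, 100, 1e-7, 1)
  err <- replicate(200, {
    y <- y0 + rnorm(5, sd = 2)  # 2% of the 0-100 scale
    fit <- fit_dose_response(response_series("d", concs, y, "inhibition"))
    abs(log10(fit$curve$ec50) - log10(1e-7))
  })
  expect_lt(median(err), 0.1)
})

test_that("constant responses give a flat degenerate fit with zero RMSD", {
  concs <- dilution_series(1e-5, 5, 10)
  fit <- fit_dose_response(response_series("d", concs, rep(0, 5),
                                           "inhibition"))
  expect_equal(fit$curve$r_min, fit$curve$r_max)
  expect_equal(fit$rmsd, 0)
  expect_true(fit$converged)
  expect_error(
    fit_dose_response(response_series("d", concs[1:3], c(0, 50, 100),
                                      "inhibition")),
    class = "ndr_fit_error")
})

test_that("RMSD matches the closed formula and its invariances", {
  expect_equal(curve_rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(curve_rmsd(c(0, 0, 50, 100, 100), c(0, 10, 50, 90, 100)),
               sqrt(200 / 5))
  expect_equal(curve_rmsd(5, 2), 3)
  o <- runif(10); e <- runif(10); p <- sample(10)
  expect_equal(curve_rmsd(o, e), curve_rmsd(o[p], e[p]))
  expect_error(curve_rmsd(1:3, 1:2), class = "ndr_validation_error")
})

test_that("baseline distance measures deviation from control-level response at the lowest dose", {
  concs <- dilution_series(1e-5, 5, 10)
  expect_equal(baseline_distance(response_series("d", concs,
                                                 c(0.95, 0.9, 0.5, 0.1, 0),
                                                 "NDR")), 0.05)
  expect_equal(baseline_distance(response_series("d", concs,
                                                 c(1, 0.9, 0.5, 0.1, 0),
                                                 "NDR")), 0)
  expect_equal(baseline_distance(response_series("d", concs,
                                                 c(88, 80, 50, 20, 5),
                                                 "PI")), 12)
})

test_that("DSS is 0 for flat-zero curves and 100 for full-scale plateaus", {
  concs <- dilution_series(1e-5, 5, 10)
  zero <- response_series("d", concs, rep(0, 5), "inhibition")
  expect_equal(compute_dss(fit_dose_response(zero), zero), 0)
  full <- response_series("d", concs, rep(100, 5), "inhibition")
  fit <- fit_dose_response(full)
  expect_equal(compute_dss(fit, full, dss_config(a_min = 10)), 100,
               tolerance = 1e-6)
  raw <- response_series("d", concs, c(1, 0.9, 0.5, 0, -0.2), "NDR")
  expect_error(compute_dss(fit, raw), "scale_series_for_dss")
})

test_that("a steep curve active over half the window scores half the plateau DSS", {
  concs <- dilution_series(1e-5, 5, 10)
  # inflection at the window midpoint, near-step transition 0 -> 100
  curve <- structure(list(r_min = 0, r_max = 100, ec50 = 1e-7, slope = 40),
                     class = "logistic_curve")
  fit <- structure(list(curve = curve,
                        fitted_values = predict_curve(curve, concs),
                        observed = predict_curve(curve, concs),
                        rmsd = 0, converged = TRUE, n_points = 5),
                   class = "curve_fit")
  series <- response_series("d", concs, predict_curve(curve, concs),
                            "inhibition")
  half <- compute_dss(fit, series, dss_config(a_min = 10))
  expect_equal(half, 50, tolerance = 0.5)
  expect_equal(half, dss_quadrature(curve, 10, -9, -5), tolerance = 1e-6)
})

test_that("analytic DSS agrees with quadrature over random 4PL draws", {
  set.seed(11)
  concs <- dilution_series(1e-5, 5, 10)
  series <- response_series("d", concs, rep(0, 5), "inhibition")
  for (i in 1:1000) {
    curve <- structure(list(
      r_min = runif(1, -10, 30),
      r_max = runif(1, 30, 120),
      ec50 = 10^runif(1, -10, -4),
      slope = runif(1, -4, 4)), class = "logistic_curve")
    fit <- structure(list(curve = curve, fitted_values = NULL,
                          observed = NULL, rmsd = 0, converged = TRUE,
                          n_points = 5), class = "curve_fit")
    a_min <- runif(1, 0, 50)
    got <- compute_dss(fit, series, dss_config(a_min))
    want <- dss_quadrature(curve, a_min, -9, -5)
    expect_lt(abs(got - want), 1e-6 * 100)
  }
})

test_that("DSS is monotone: pointwise-larger responses never score lower", {
  set.seed(23)
  concs <- dilution_series(1e-5, 5, 10)
  for (i in 1:20) {
    base <- sort(runif(5, 0, 80))
    bump <- base + sort(runif(5, 0, 20))
    d1 <- dss_score(response_series("d", concs, base, "inhibition"))$dss
    d2 <- dss_score(response_series("d", concs, bump, "inhibition"))$dss
    expect_gte(d2 + 1e-6, d1)
  }
})

test_that("uniformly negative responses are mirrored into a negative DSS", {
  concs <- dilution_series(1e-5, 5, 10)
  neg <- response_series("d", concs, rep(-20, 5), "inhibition")
  pos <- response_series("d", concs, rep(20, 5), "inhibition")
  expect_equal(negative_dss(neg),
               -compute_dss(fit_dose_response(pos), pos))
  expect_equal(negative_dss(response_series("d", concs, rep(0, 5),
                                            "inhibition")), 0)
  # stimulatory NDR series: NDR 1.4 everywhere scales to -20% inhibition
  stim <- scale_series_for_dss(response_series("d", concs, rep(1.4, 5),
                                               "NDR"))
  expect_equal(stim$responses, rep(-20, 5))
  expect_lt(dss_score(stim)$dss, 0)
  mixed <- response_series("d", concs, c(-5, -5, 5, 5, 5), "inhibition")
  expect_warning(negative_dss(mixed), class = "ndr_mixed_sign_warning")
})
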