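# Literal transcriptions of the published formulas, kept independent of the
# package implementation, used as oracles below.
ref_ndr <- function(fd, fn, fp) {
  max(-1, (1 - 2^(log2(fd) / log2(fp))) / (1 - 2^(log2(fn) / log2(fp))))
}
ref_gr <- function(fd, fn) 2^(log2(fd) / log2(fn)) - 1
ref_pi <- function(ed, en, ep) (en - ed) / (en - ep)

test_that("fold change is end over start and rejects zero starts", {
  expect_equal(fold_change(100, 400), 4)
  expect_equal(fold_change(100, 100), 1)
  expect_equal(fold_change(200, 100), 0.5)
  expect_error(fold_change(0, 100, well = "A01"), "A01")
  expect_error(fold_change(0, 100), class = "ndr_domain_error")
})

test_that("NDR hits its anchor points: 1 at DMSO-like growth, 0 at stasis, -1 at full kill", {
  expect_identical(ndr(4, 4, 0.5), 1)
  expect_identical(ndr(1, 4, 0.5), 0)
  expect_identical(ndr(0.5, 4, 0.5), -1)  # raw -4/3 clamped
  expect_equal(ndr(2, 4, 0.5), 0.5 / 0.75)
  expect_equal(ndr(8, 4, 0.5), 1 + 1 / 6)  # proliferative, > 1, no upper clamp
})

test_that("GR and PI hit their anchor points", {
  expect_equal(gr(4, 4), 1)
  expect_equal(gr(1, 4), 0)
  expect_equal(gr(2, 4), sqrt(2) - 1)
  expect_equal(percent_inhibition(1000, 1000, 100), 0)
  expect_equal(percent_inhibition(100, 1000, 100), 1)
  expect_equal(percent_inhibition(550, 1000, 100), 0.5)
})

test_that("metric guards reject non-responding or degenerate controls", {
  expect_error(ndr(2, 4, 1), class = "ndr_positive_control_error")
  expect_error(ndr(2, 1, 0.5), class = "ndr_negative_control_error")
  expect_error(ndr(-2, 4, 0.5), class = "ndr_domain_error")
  expect_error(gr(2, 1), class = "ndr_negative_control_error")
  expect_error(percent_inhibition(500, 300, 300),
               class = "ndr_degenerate_controls_error")
})

test_that("metrics agree with literal formula transcriptions on random inputs", {
  set.seed(42)
  n <- 10000
  fd <- exp(runif(n, log(0.05), log(20)))
  fn <- exp(runif(n, log(1.5), log(16)))
  fp <- exp(runif(n, log(0.1), log(0.9)))
  got_ndr <- ndr(fd, fn, fp)
  got_gr <- gr(fd, fn)
  ref_n <- mapply(ref_ndr, fd, fn, fp)
  ref_g <- mapply(ref_gr, fd, fn)
  expect_lt(max(abs(got_ndr - ref_n) / pmax(abs(ref_n), 1)), 1e-12)
  expect_lt(max(abs(got_gr - ref_g) / pmax(abs(ref_g), 1)), 1e-12)
  ed <- runif(n, 0, 2000); en <- runif(n, 500, 3000); ep <- runif(n, 0, 400)
  expect_lt(max(abs(percent_inhibition(ed, en, ep) -
                    mapply(ref_pi, ed, en, ep))), 1e-12)
  expect_true(all(got_ndr >= -1))
})

test_that("NDR is non-decreasing in the drug fold change and clamped at -1", {
  fd <- exp(seq(log(0.01), log(30), length.out = 500))
  v <- ndr(fd, 4, 0.5)
  expect_true(all(diff(v) >= 0))
  unclamped <- v > -1
  expect_true(all(diff(v[unclamped]) > 0))
  expect_true(all(diff(gr(fd, 4)) > 0))
})

test_that("NDR and GR are invariant to rescaling all readouts; PI to rescaling endpoints", {
  tab <- make_plate(drug_fc = c(a = 2, b = 0.8, c = 6))
  scaled <- tab
  scaled$start_readout <- tab$start_readout * 37.5
  scaled$end_readout <- tab$end_readout * 37.5
  for (m in c("NDR", "GR", "PI")) {
    expect_equal(score_screen(scaled, m)$response,
                 score_screen(tab, m)$response, tolerance = 1e-12)
  }
})

test_that("control aggregation takes the median of per-well fold changes", {
  tab <- make_plate(drug_fc = c(a = 2), neg_fc = c(3.9, 4.0, 4.2),
                    pos_fc = c(0.4, 0.5))
  cs <- aggregate_controls(tab)
  expect_equal(cs$fold_change_neg, 4.0)
  expect_equal(cs$fold_change_pos, 0.45)
  expect_equal(cs$n_neg, 3)
  expect_equal(cs$n_pos, 2)
  # alternative mode: fold change of the median readings
  uneven <- tab
  uneven$start_readout[uneven$role == "negative_control"] <- c(90, 100, 110)
  uneven$end_readout[uneven$role == "negative_control"] <- c(400, 420, 380)
  cs2 <- aggregate_controls(uneven, "fold_change_of_medians")
  expect_equal(cs2$fold_change_neg, 400 / 100)
})

test_that("excluded control wells are left out of the medians", {
  tab <- make_plate(drug_fc = c(a = 2), neg_fc = c(3.9, 4.0, 40),
                    pos_fc = c(0.4, 0.5))
  # the 40-fold outlier well is an artifact; exclude it by label
  tab$label[tab$role == "negative_control"][3] <- "DMSO_artifact"
  cleaned <- exclude_wells(tab, "DMSO_artifact")
  cs <- aggregate_controls(cleaned[cleaned$role != "excluded", ])
  expect_equal(cs$fold_change_neg, median(c(3.9, 4.0)))
  expect_error(aggregate_controls(make_plate(neg_fc = 4)[-2, ]),
               class = "ndr_control_error")
})

test_that("scaling transforms map metrics onto the percent-inhibition scale", {
  expect_equal(scale_for_dss("PI", 1.0), 100)
  expect_equal(scale_for_dss("NDR", 1.0), 0)
  expect_equal(scale_for_dss("NDR", -1.0), 100)
  expect_equal(scale_for_dss("NDR", 1.2), -10)  # stimulatory, below 0
  expect_equal(scale_for_dss("GR", 1.0), 0)
  expect_error(scale_for_dss("bogus", 1), class = "ndr_config_error")
})

test_that("score_screen reproduces fixed points and spans the scenario range", {
  # every drug well duplicates the negative controls
  tab <- make_plate(drug_fc = c(a = 4, b = 4, c = 4))
  expect_equal(score_screen(tab, "NDR")$response[1:3], rep(1, 3))
  expect_equal(score_screen(tab, "GR")$response[1:3], rep(1, 3))
  # a drug-rate grid spanning the scenario-1 fold-change range
  fcs <- exp(seq(log(0.5), log(8), length.out = 20))
  names(fcs) <- sprintf("d%02d", seq_along(fcs))
  grid_tab <- make_plate(drug_fc = fcs)
  v <- score_screen(grid_tab, "NDR")$response[1:20]
  expect_equal(min(v), -1)
  expect_gt(max(v), 1)
})

test_that("start-readout estimation divides the negative-control end median by the assumed fold change", {
  expect_equal(estimate_start_readout(c(300, 320, 340), 3.2), 100)
  expect_equal(estimate_start_readout(c(300, 320, 340), 1.0), 320)
  expect_error(estimate_start_readout(numeric(0), 3.2),
               class = "ndr_control_error")
  # self-consistency: a neg-control well at the median end recovers 3.2
  tab <- make_plate(drug_fc = c(a = 2), neg_fc = c(3.1, 3.2, 3.3))
  est <- apply_start_estimate(tab, 3.2)
  expect_equal(unique(est$start_readout), 100)
  neg_med_end <- 320
  expect_equal(fold_change(est$start_readout[2], neg_med_end), 3.2)
})
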