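# Builders for small in-code fixtures.

# One plate with explicit control fold changes and drug-well fold changes.
# Start readouts default to 100; ends are start * fold change.
make_plate <- function(plate_id = "P1",
                       drug_fc = c(a = 2, b = 0.5),
                       neg_fc = c(4, 4), pos_fc = c(0.5, 0.5),
                       start = 100, drug_conc = NULL) {
  n_drug <- length(drug_fc)
  if (is.null(drug_conc)) drug_conc <- rep(1e-6, n_drug)
  drug_names <- names(drug_fc) %||% sprintf("drug%d", seq_len(n_drug))
  wells <- sprintf("%s%02d", "A", seq_len(n_drug + length(neg_fc) + length(pos_fc)))
  df <- data.frame(
    plate_id = plate_id,
    well = wells,
    role = c(rep("drug", n_drug),
             rep("negative_control", length(neg_fc)),
             rep("positive_control", length(pos_fc))),
    label = c(drug_names, rep("DMSO", length(neg_fc)),
              rep("BzCl", length(pos_fc))),
    drug_name = c(drug_names, rep(NA, length(neg_fc) + length(pos_fc))),
    concentration = c(drug_conc, rep(NA, length(neg_fc) + length(pos_fc))),
    start_readout = start,
    end_readout = start * c(drug_fc, neg_fc, pos_fc),
    stringsAsFactors = FALSE)
  screen_table(df)
}

# A drug titrated at n concentrations on one plate (for classification and
# series-based tests); fc_by_conc is ordered low -> high concentration.
make_titration_plate <- function(drugs, neg_fc = c(4, 4, 4),
                                 pos_fc = c(0.5, 0.5), start = 100) {
  concs <- dilution_series(1e-5, length(drugs[[1]]), 10)
  rows <- list()
  w <- 0
  nxt <- function() {
    w <<- w + 1
    sprintf("%s%02d", LETTERS[(w - 1) %/% 24 + 1], (w - 1) %% 24 + 1)
  }
  for (d in names(drugs)) {
    for (i in seq_along(concs)) {
      rows[[length(rows) + 1]] <- data.frame(
        plate_id = "P1", well = nxt(), role = "drug", label = d,
        drug_name = d, concentration = concs[i],
        start_readout = start, end_readout = start * drugs[[d]][i],
        stringsAsFactors = FALSE)
    }
  }
  for (fc in neg_fc) {
    rows[[length(rows) + 1]] <- data.frame(
      plate_id = "P1", well = nxt(), role = "negative_control",
      label = "DMSO", drug_name = NA, concentration = NA,
      start_readout = start, end_readout = start * fc,
      stringsAsFactors = FALSE)
  }
  for (fc in pos_fc) {
    rows[[length(rows) + 1]] <- data.frame(
      plate_id = "P1", well = nxt(), role = "positive_control",
      label = "BzCl", drug_name = NA, concentration = NA,
      start_readout = start, end_readout = start * fc,
      stringsAsFactors = FALSE)
  }
  screen_table(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
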