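#' Exponential growth of a viability readout
#'
#' Base-2 exponential growth law: `readout(t) = start * 2^(g * t)`, so the
#' doubling time of a growing population is `1/g` hours (g = 0.03 per hour
#' doubles in ~33 h) and the half-life of a dying one is `1/|g|`.
#'
#' @param start starting readout (> 0).
#' @param g growth rate per hour (negative for death).
#' @param t elapsed time in hours (>= 0).
#' @return the readout at time `t`.
#' @export
grow <- function(start, g, t) {
  if (any(start <= 0)) stop_ndr("start must be > 0", "ndr_domain_error")
  if (any(t < 0)) stop_ndr("t must be >= 0", "ndr_domain_error")
  start * 2^(g * t)
}

#' Define a simulation scenario
#'
#' A scenario fixes the control conditions and the grid of drug-induced
#' fold changes over which the response metrics are evaluated. Fold
#' changes are the normative specification (a rate/duration pair implies
#' `fc = 2^(g * t)`); the growth rates and times are carried along for
#' readout-level simulation.
#'
#' Three stock scenarios mirror common benchmarking setups:
#' * `"s1"` — fixed controls: fc_neg = 4, fc_pos = 0.5, drug fold changes
#'   spanning 0.5-8 (growth rates 0.03 / -0.01 per hour);
#' * `"s2"` — varying positive control: fc_pos in 0.4-0.8, fc_neg = 4;
#' * `"s3"` — varying negative control: fc_neg in 2-15, fc_pos = 0.5.
#'
#' @param name one of "s1", "s2", "s3", or "custom".
#' @param fc_neg negative-control fold change (scalar) or range (length-2).
#' @param fc_pos positive-control fold change or range.
#' @param fc_drug_range range of drug fold changes.
#' @param g_neg,g_pos growth rates per hour (metadata for readout-level
#'   simulation).
#' @param duration experiment duration in hours.
#' @param eval_time time point at which metrics are computed (defaults to
#'   `duration`).
#' @return a `simulation_scenario`.
#' @export
simulation_scenario <- function(name = c("s1", "s2", "s3", "custom"),
                                fc_neg = NULL, fc_pos = NULL,
                                fc_drug_range = NULL,
                                g_neg = 0.03, g_pos = -0.01,
                                duration = 72, eval_time = duration) {
  name <- match.arg(name)
  defaults <- switch(name,
    s1 = list(fc_neg = 4,        fc_pos = 0.5,         fc_drug = c(0.5, 8)),
    s2 = list(fc_neg = 4,        fc_pos = c(0.4, 0.8), fc_drug = c(0.5, 8)),
    s3 = list(fc_neg = c(2, 15), fc_pos = 0.5,         fc_drug = c(0.5, 8)),
    custom = list(fc_neg = 4, fc_pos = 0.5, fc_drug = c(0.5, 8)))
  fc_neg <- fc_neg %||% defaults$fc_neg
  fc_pos <- fc_pos %||% defaults$fc_pos
  fc_drug_range <- fc_drug_range %||% defaults$fc_drug
  if (duration <= 0 || eval_time <= 0 || eval_time > duration) {
    stop_ndr("need 0 < eval_time <= duration", "ndr_config_error")
  }
  chk <- function(v, nm) {
    if (!length(v) %in% 1:2 || any(v <= 0) || is.unsorted(v)) {
      stop_ndr(paste0(nm, " must be a positive scalar or ordered range"),
               "ndr_config_error")
    }
    v
  }
  structure(list(name = name, fc_neg = chk(fc_neg, "fc_neg"),
                 fc_pos = chk(fc_pos, "fc_pos"),
                 fc_drug_range = chk(fc_drug_range, "fc_drug_range"),
                 g_neg = g_neg, g_pos = g_pos, duration = duration,
                 eval_time = eval_time),
            class = "simulation_scenario")
}

# log-spaced grid over a fold-change range (fold changes are ratios)
fc_grid <- function(range, n) {
  if (length(range) == 1) return(range)
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Evaluate the response metrics over a scenario's condition grid
#'
#' Expands the drug fold-change grid (log-spaced, default 100 points)
#' against the control grid(s) (log-spaced, default 5 points when a control
#' is given as a range) and computes NDR, GR and PI at every combination.
#' PI is derived from endpoint readouts under uniform seeding (start = 1,
#' so endpoints equal fold changes). Grid points where the negative-control
#' fold change is 1 are degenerate (no net control growth) and are skipped
#' with a warning.
#'
#' @param scenario a [simulation_scenario()].
#' @param grid_size number of drug fold-change grid points.
#' @param control_grid_size grid points for a control given as a range.
#' @return data.frame with columns `fc_drug`, `fc_neg`, `fc_pos`, `ndr`,
#'   `gr`, `pi`.
#' @export
run_scenario <- function(scenario, grid_size = 100, control_grid_size = 5) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (grid_size < 2) stop_ndr("grid_size must be >= 2", "ndr_config_error")
  grid <- expand.grid(
    fc_drug = fc_grid(scenario$fc_drug_range, grid_size),
    fc_neg = fc_grid(scenario$fc_neg, control_grid_size),
    fc_pos = fc_grid(scenario$fc_pos, control_grid_size),
    KEEP.OUT.ATTRS = FALSE)
  degenerate <- abs(log2(grid$fc_neg)) < LOG2_GUARD |
    abs(log2(grid$fc_pos)) < LOG2_GUARD
  if (any(degenerate)) {
    warn_ndr(sprintf("skipping %d degenerate grid point(s) with control fold change = 1",
                     sum(degenerate)), "ndr_degenerate_grid_warning")
    grid <- grid[!degenerate, , drop = FALSE]
  }
  grid$ndr <- ndr(grid$fc_drug, grid$fc_neg, grid$fc_pos)
  grid$gr <- gr(grid$fc_drug, grid$fc_neg)
  # uniform seeding: endpoint readouts equal the fold changes
  grid$pi <- percent_inhibition(grid$fc_drug, grid$fc_neg, grid$fc_pos)
  rownames(grid) <- NULL
  grid
}

#' Dilution series of test concentrations
#'
#' @param top highest concentration (molar).
#' @param n number of concentrations (>= 2).
#' @param dilution_factor fold dilution between consecutive concentrations
#'   (> 1). Five 10-fold dilutions span a 10,000-fold range.
#' @return increasing vector of `n` concentrations ending at `top`.
#' @export
dilution_series <- function(top, n = 5, dilution_factor = 10) {
  if (n < 2) stop_ndr("n must be >= 2", "ndr_config_error")
  if (dilution_factor <= 1) {
    stop_ndr("dilution_factor must be > 1", "ndr_config_error")
  }
  top / dilution_factor^((n - 1):0)
}

#' Noise model for synthetic screens
#'
#' Multiplicative log-normal noise with unit mean: `seeding_cv` perturbs
#' the true number of cells deposited in each well (and hence both true
#' readouts of that well), `readout_cv` perturbs each measured readout
#' independently (luminescence measurement error).
#'
#' @param seeding_cv coefficient of variation of per-well seeding.
#' @param readout_cv coefficient of variation of each measurement.
#' @param seed integer random seed; identical seeds give identical screens.
#' @return a `noise_model`.
#' @export
noise_model <- function(seeding_cv = 0.2, readout_cv = 0.02, seed = 1L) {
  if (seeding_cv < 0 || readout_cv < 0) {
    stop_ndr("noise CVs must be >= 0", "ndr_config_error")
  }
  structure(list(seeding_cv = seeding_cv, readout_cv = readout_cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Random per-drug 4PL potency parameters
#'
#' Draws ground-truth potencies on the inhibition-fraction scale: bottom
#' asymptote 0, top asymptote (maximal inhibition) spanning lethal through
#' growth-stimulatory behavior (negative top = stimulation), EC50
#' log-uniform within the tested range, Hill slope in 0.5-2. Uses the
#' current RNG stream.
#'
#' @param n_drugs number of drugs.
#' @param concentrations tested concentrations (for the EC50 range).
#' @return data.frame `drug_name`, `r_min`, `r_max`, `ec50`, `slope`.
#' @export
random_potency <- function(n_drugs, concentrations) {
  lo <- log10(min(concentrations)); hi <- log10(max(concentrations))
  data.frame(
    drug_name = sprintf("drug_%03d", seq_len(n_drugs)),
    r_min = 0,
    r_max = runif(n_drugs, -0.3, 1.2),
    ec50 = 10^runif(n_drugs, lo + 0.5, hi - 0.5),
    slope = runif(n_drugs, 0.5, 2),
    stringsAsFactors = FALSE)
}

#' Generate a full synthetic screen with ground truth
#'
#' Builds a multi-plate 384-well screen: each plate carries 16 DMSO
#' negative-control and 16 benzethonium-chloride positive-control wells
#' plus up to 352 drug wells; each drug occupies `n_concentrations`
#' consecutive wells of one plate at a dilution series. Per-well readouts
#' follow the base-2 exponential growth law: the effective growth rate of
#' a drug well interpolates linearly between the negative-control rate
#' (0% inhibition) and the positive-control rate (100% inhibition)
#' according to the drug's true 4PL inhibition at that concentration
#' (inhibition > 1 pushes below the positive-control rate, < 0 above the
#' negative-control rate, i.e. growth stimulation).
#'
#' With both noise CVs at 0 the measured readouts equal the ground truth
#' exactly, so the scored screen reproduces the true per-well metrics.
#'
#' @param n_drugs number of drugs (default 131).
#' @param n_concentrations concentrations per drug (default 5).
#' @param plates number of plates (default 2).
#' @param scenario a [simulation_scenario()] supplying the control growth
#'   rates and duration.
#' @param noise a [noise_model()].
#' @param true_potency optional data.frame as from [random_potency()];
#'   drawn randomly (seeded) when NULL.
#' @param top_concentration,dilution_factor dilution series parameters.
#' @param base_start nominal seeded readout per well.
#' @return list with `screen` (a `screen_table`), `truth_wells`
#'   (per-well true fold changes and NDR) and `truth_drugs` (per-drug true
#'   category and potency parameters).
#' @export
generate_synthetic_screen <- function(n_drugs = 131, n_concentrations = 5,
                                      plates = 2,
                                      scenario = simulation_scenario("s1"),
                                      noise = noise_model(),
                                      true_potency = NULL,
                                      top_concentration = 1e-5,
                                      dilution_factor = 10,
                                      base_start = 100) {
  n_ctrl <- 16L
  capacity <- 384L - 2L * n_ctrl
  drugs_per_plate <- capacity %/% n_concentrations
  if (n_drugs > plates * drugs_per_plate) {
    stop_ndr(sprintf(
      "layout overflow: %d drugs x %d concentrations need > %d plates",
      n_drugs, n_concentrations,
      ceiling(n_drugs / drugs_per_plate)), "ndr_config_error")
  }
  set.seed(noise$seed)
  concs <- dilution_series(top_concentration, n_concentrations,
                           dilution_factor)
  if (is.null(true_potency)) {
    true_potency <- random_potency(n_drugs, concs)
  }
  stopifnot(nrow(true_potency) == n_drugs)
  t <- scenario$duration
  g_neg <- scenario$g_neg; g_pos <- scenario$g_pos
  fc_neg_true <- 2^(g_neg * t)
  fc_pos_true <- 2^(g_pos * t)

  all_wells <- sprintf("%s%02d", rep(LETTERS[1:16], each = 24), 1:24)
  wells <- list(); truth <- list()
  drug_idx <- 0L
  for (p in seq_len(plates)) {
    if (drug_idx >= n_drugs && p > 1) break  # no empty control-only plates
    plate_id <- sprintf("P%d", p)
    pos_cursor <- 1L
    take_wells <- function(k) {
      w <- all_wells[pos_cursor:(pos_cursor + k - 1L)]
      pos_cursor <<- pos_cursor + k
      w
    }
    add <- function(w, role, label, drug, conc, g_eff) {
      n <- length(w)
      seeded <- base_start * rlnorm_cv(n, noise$seeding_cv)
      true_start <- seeded
      true_end <- grow(true_start, g_eff, t)
      meas_start <- true_start * rlnorm_cv(n, noise$readout_cv)
      meas_end <- true_end * rlnorm_cv(n, noise$readout_cv)
      wells[[length(wells) + 1L]] <<- data.frame(
        plate_id = plate_id, well = w, role = role, label = label,
        drug_name = if (role == "drug") drug else NA_character_,
        concentration = if (role == "drug") conc else NA_real_,
        start_readout = meas_start, end_readout = meas_end,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        plate_id = plate_id, well = w, role = role,
        drug_name = if (role == "drug") drug else NA_character_,
        concentration = if (role == "drug") conc else NA_real_,
        g_eff = g_eff, true_fold_change = 2^(g_eff * t),
        true_ndr = ndr(2^(g_eff * t), fc_neg_true, fc_pos_true),
        stringsAsFactors = FALSE)
    }
    add(take_wells(n_ctrl), "negative_control", "DMSO", NA, NA,
        rep(g_neg, n_ctrl))
    add(take_wells(n_ctrl), "positive_control", "BzCl", NA, NA,
        rep(g_pos, n_ctrl))
    while (drug_idx < n_drugs && pos_cursor + n_concentrations - 1L <= 384L) {
      drug_idx <- drug_idx + 1L
      tp <- true_potency[drug_idx, ]
      inhibition <- ll4(log10(concs), tp$r_min, tp$r_max, tp$ec50, tp$slope)
      g_eff <- g_neg + inhibition * (g_pos - g_neg)
      add(take_wells(n_concentrations), "drug", tp$drug_name,
          tp$drug_name, concs, g_eff)
      if (drug_idx %% drugs_per_plate == 0L) break
    }
  }
  screen <- screen_table(do.call(rbind, wells),
                         metadata = list(simulated = "TRUE",
                                         seed = noise$seed,
                                         duration_h = t))
  truth_wells <- do.call(rbind, truth)
  rownames(truth_wells) <- NULL
  drug_rows <- truth_wells[truth_wells$role == "drug", , drop = FALSE]
  top_fc <- vapply(split(drug_rows, drug_rows$drug_name), function(d) {
    d$true_fold_change[which.max(d$concentration)]
  }, numeric(1))
  stats <- list(mean_fc = fc_neg_true, sd_fc = 0)
  truth_drugs <- data.frame(
    drug_name = names(top_fc), true_final_fc = unname(top_fc),
    true_category = classify_drug(unname(top_fc), stats),
    stringsAsFactors = FALSE)
  truth_drugs <- merge(truth_drugs, true_potency, by = "drug_name",
                       sort = TRUE)
  list(screen = screen, truth_wells = truth_wells,
       truth_drugs = truth_drugs)
}
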