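---
title: "Quantifying drug sensitivity with the normalized drug response metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug sensitivity with the normalized drug response metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndrscreen)
```

## The problem

High-throughput cell-based drug screens measure a whole-well viability
surrogate (here: luminescence from a metabolic reagent) and normalize each
drug-treated well against control wells on the same plate. Two artifacts
routinely bias the resulting response estimates: cells grow at different
rates across cell lines and culture conditions, and the assay background —
the non-zero signal in a positive control where every cell is expected to
die — varies between plates, readouts and time points. Endpoint-only
normalization (percent inhibition, PI) ignores growth entirely; growth-rate
normalization (GR) corrects for doubling time but ignores the background.

The normalized drug response (NDR) uses four quantities per plate — the
start and endpoint readouts of the drug-treated wells and of both control
conditions — and normalizes the drug-induced log2 fold change against the
positive-control fold change as well as the negative-control one.

## The metrics

With $fc_{cond} = \mathrm{End}/\mathrm{Start}$ the fold change of a
condition between the two measurement time points:

$$\mathrm{NDR} = \max\!\left(-1,\;
  \frac{1 - 2^{\log_2 fc_{drug}/\log_2 fc_{pos}}}
       {1 - 2^{\log_2 fc_{neg}/\log_2 fc_{pos}}}\right), \qquad
\mathrm{GR} = 2^{\log_2 fc_{drug}/\log_2 fc_{neg}} - 1, \qquad
\mathrm{PI} = \frac{end_{neg} - end_{drug}}{end_{neg} - end_{pos}}.$$

NDR and GR share the anchor points 1 (growth as in the negative control)
and 0 (complete growth inhibition); NDR additionally anchors $-1$ at
"behaves like the positive control" (complete killing) and is clamped there,
while values above 1 indicate growth stimulation. The exponent base is
fixed at 2; other bases give equivalent orderings, and keeping the base
fixed keeps outputs reproducible. PI is kept as a fraction internally; the
$\times 100$ percent scale is applied only by `scale_for_dss()` and display
code.

Per plate, the control fold changes entering the formulas are the *median
of the per-well fold changes* of each control group (the more outlier-robust
reading; the fold-change-of-median-readings alternative is available via
`aggregate_controls(..., "fold_change_of_medians")`). Controls are
aggregated per plate, not per screen, because plate-level artifacts are the
dominant noise source — the same reason plate quality is judged per plate
with the Z'-factor.

Guards: a control whose fold change is numerically 1 makes the formulas
degenerate (division by $\log_2 fc$), so $|\log_2 fc| < 10^{-9}$ raises an
error rather than returning infinities. Wells with a start readout of 0 are
accepted by the reader but flagged, and rejected by the fold-change-based
metrics.

## Dose-response curves and DSS

Five-concentration series (10-fold dilutions spanning a 10,000-fold range
by default) are fitted with a four-parameter log-logistic model in
log10-concentration space,

$$R(x) = R_{min} + \frac{R_{max} - R_{min}}{1 + 10^{\,s\,(\log_{10}EC_{50} - x)}},$$

by Levenberg–Marquardt least squares (`minpack.lm`), with five data-driven
starts: asymptotes from the extreme responses, EC50 at the concentration
nearest the half-range response, Hill slopes $\{0.5, 1, 2\}$ in the
orientation suggested by a rank correlation of response with dose plus two
opposite-orientation starts. The lowest residual sum of squares wins; ties
go to the smallest $|s|$. Curves are canonicalized to $R_{max} \ge R_{min}$
with the slope sign carrying direction. All-identical responses yield a
degenerate flat fit (RMSD 0) rather than an error; fits where no start
converges are reported with `converged = FALSE`, never dropped silently.

Fit quality is summarized by the RMSD between observed and fitted responses
and by the *baseline distance*: the deviation of the lowest-concentration
response from the negative-control level (1 for NDR/GR, 100 for PI on the
viability orientation $100 \times (1 - \mathrm{PI})$). The lowest dose is
expected to do nothing, so a large baseline distance flags a normalization
artifact that will bias EC50 estimates.

The drug sensitivity score integrates the fitted inhibition curve above a
minimum activity level $A_{min}$ over the tested log10 window
$[x_{min}, x_{max}]$, normalized so that a full-scale plateau scores 100:

$$\mathrm{DSS} = 100 \cdot
  \frac{\int \max(0, R(x) - A_{min})\,dx}{(100 - A_{min})(x_{max}-x_{min})}.$$

Published DSS implementations differ in their exact closed form; this
normalized-AUC variant was chosen because it is fully auditable from the
four curve parameters, and both $A_{min}$ (default 10, percent inhibition)
and the normalization are exposed in `dss_config()`. The integral is
evaluated analytically from the 4PL antiderivative (with a numerically
stable $\log(1+10^u)$ for large $u$, and a constant-curve branch for
near-zero slopes); the test suite checks it against adaptive quadrature.
Before DSS, metric values are mapped to the percent-inhibition scale:
$\mathrm{PI}\times 100$, $0.5(1-\mathrm{GR})\times 100$,
$0.5(1-\mathrm{NDR})\times 100$. A drug whose scaled responses are negative
at every concentration (growth-stimulatory) is scored by mirroring the
responses about the zero-inhibition baseline, fitting the mirrored curve,
and negating the resulting score; mixed-sign series fall back to the
ordinary score with a warning.

## Drug classification

Each drug is classified from the fold change of its highest tested
concentration against the negative-control fold-change distribution
(mean $\mu$, SD $\sigma$, per plate by default): **lethal** if $fc < 1$;
**sub-effective** if $1 \le fc < \mu - k\sigma$; **growth-stimulatory** if
$fc > \mu + k\sigma$; **non-effective** otherwise. Boundary values land in
non-effective — claiming an effect requires strict exceedance. The band
width defaults to $k = 1$ SD (the procedural definition), with $k = 2$
reachable via `k_sd = 2` since both conventions appear in practice.

## The simulator

The ground-truth generator drives every readout from base-2 exponential
growth, $S(t) = S_0 \cdot 2^{g t}$, so a rate of $g = 0.03\,h^{-1}$ doubles
in $1/g \approx 33$ h and $g = -0.01\,h^{-1}$ halves in 100 h. The base-2
convention (rather than $e$) is deliberate and documented prominently
because it changes every simulated number: it makes the stated rates match
their stated doubling times ("~30 h" for 0.03, "~25 h" for 0.04).

Three scenario presets evaluate the metrics on condition grids specified
directly as fold changes (the normative quantity — a stated rate/time pair
and a stated fold change need not agree, and when they do not, the fold
change wins): scenario 1 fixes $fc_{neg} = 4$, $fc_{pos} = 0.5$ and sweeps
drug fold changes over 0.5–8; scenario 2 varies the positive control over
0.4–0.8; scenario 3 varies the negative control over 2–15. Grids are
log-spaced (fold changes are ratios) with 100 drug points by default, both
config-exposed.

`generate_synthetic_screen()` builds full 384-well plates: 16 DMSO and 16
benzethonium-chloride control wells per plate plus up to 352 drug wells
(the default 131 drugs × 5 concentrations fills 2 plates, mirroring a
typical oncology-library screen). Each drug's true potency is a 4PL curve
on the inhibition-fraction scale; the effective growth rate at a
concentration interpolates linearly between the negative-control rate (0%
inhibition) and the positive-control rate (100%), with out-of-range
inhibition extrapolating to super-lethal or stimulatory rates. Noise is
multiplicative log-normal with unit mean: a seeding component (default CV
0.2, reflecting the marked seeding variability seen in hard-to-suspend cell
lines) scales the true cell number of a well, and a measurement component
(default CV 0.02, typical luminescence reader precision) perturbs each
readout independently. All randomness flows through one integer seed;
identical seeds give identical screens.

What the simulator does *not* emulate: spatial plate effects (edge
evaporation, dispensing gradients), signal bleed-through between wells,
drug-specific kinetics between the two time points, and the
concurrent-growth-and-death ambiguity of metabolic readouts. Passing tests
on simulated screens therefore demonstrate correctness of the computations
and the direction of noise effects (e.g. that seeding noise hurts
endpoint-only PI more than NDR), not the full error structure of real
screens.

## QC statistics

`z_prime()` implements $Z' = 1 - 3(\sigma_{pos} + \sigma_{neg}) /
|\mu_{pos} - \mu_{neg}|$ on metric-transformed control values (sample SDs,
since control groups are small; raw-readout Z' is available by scoring with
a different input). Replicate consistency is the per-well absolute response
difference between matched (plate, well) positions of two replicate
screens, drug wells only by default; time-point consistency is the per-well
deviation from the across-time median response. The overlapping coefficient
of two normal densities uses the closed form $2\Phi(-|\mu_1-\mu_2|/2\sigma)$
for equal variances and otherwise integrates the pointwise minimum exactly
via the densities' intersection points (stable quadratic roots, log-scale
density comparisons to survive far-tail underflow). Standard hypothesis
tests used in screen reports (Wilcoxon, Kolmogorov–Smirnov, F, Welch t,
Shapiro–Wilk) are deliberately left to base R's `stats` routines.

## Problem sizes and numerical choices

The test suite exercises the metric formulas against literal formula
transcriptions on 10,000 random fold-change triples (agreement to 1e-12
relative), curve fitting on noise-free data (parameter recovery to 1e-3
relative) and under 2% Gaussian noise (median absolute log10-EC50 error
below 0.1 over 200 replicates), the analytic DSS integral against adaptive
quadrature (1e-6 of full scale), and the full
simulate → score → fit → classify pipeline on noise-free screens (exact
category recovery). Replicate-noise comparisons use 100 simulated replicate
pairs of 15–20 drug plates — large enough for stable medians while keeping
the whole suite under a minute of compute.

## Limitations

* The two-time-point design cannot separate concurrent growth and death;
  time-lapse methods are out of scope.
* NDR requires a measured (or assumed, via `apply_start_estimate()`) start
  readout; purely endpoint datasets depend on the assumed fold change.
* The DSS closed form here is one member of the DSS family; scores are
  comparable within this package, not numerically interchangeable with
  other DSS implementations.
* No 5PL or biphasic dose-response models, and no confidence bands on
  fitted curves.
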