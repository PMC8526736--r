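---
title: "Damped cosinor rhythms: model, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Damped cosinor rhythms: model, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmfit)
library(dplyr)
```

# The model

Gene-expression time courses sampled against zeitgeber time (ZT, hours
relative to lights-on) often show oscillations whose amplitude shrinks over
the sampling window — for instance glucocorticoid-responsive transcripts
that peak just before dawn and decay through the morning. `rhythmfit`
models such series with a damped sinusoid, a cosinor model with an
exponential amplitude envelope:

$$y(t) = m + a\, e^{-bt} \sin\!\big(c\,(t - d)\big)$$

* `m` — the MESOR (Midline Estimating Statistic Of Rhythm), the
  rhythm-adjusted mean, in expression units;
* `a` — the amplitude at `t = 0` (expression units, canonical `a >= 0`);
* `b` — the exponential decay rate of the envelope (per hour; `b = 0`
  recovers the plain cosinor);
* `c` — the angular frequency (radians per hour), so the period is
  `2 * pi / c`;
* `d` — the phase shift in hours (the sinusoid's argument is `c (t - d)`).

The parameterization has two exact symmetries: `(a, d)` and
`(-a, d + pi/c)` produce the same curve, as do `d` and `d + 2*pi/c`.
`canonicalize_sinusoid()` resolves both, mapping every fit to `a >= 0`,
`c > 0`, `d` in `[0, period)`; all fits returned by the package are
canonical. A consequence of the functional form worth knowing: stationary
points satisfy `tan(c (t - d)) = c / b` and are therefore spaced exactly
`pi / c` apart for *every* decay rate, so the fitted peak-to-nadir interval
is always half the fitted period. Shorter peak-to-nadir intervals are
expressed through shorter fitted periods, not through asymmetry.

# Fitting

`fit_sinusoid()` performs nonlinear least squares on the per-timepoint
replicate means by default (`collapse_replicates = FALSE` fits raw points).
Replicate means are the quantity plotted and modelled in rhythm time-course
figures; fitting them also makes the randomization test below well-defined.
Fitting requires at least 6 distinct timepoints (five constants plus one
residual degree of freedom).

The SSE surface in `(b, c, d)` is multimodal, so optimization is
multi-start:

* candidate starts are a coarse grid — `b` in {0, 0.05, 0.2} per hour,
  period seeds {6, 8, 9.5, 12, 24} h, 8 equispaced phases per period
  (120 starts; `n_starts` above 120 adds seeded random starts);
* for each candidate the linear constants `(m, a)` are profiled out by
  ordinary least squares, which both improves the start and makes
  screening nearly free;
* the `n_polish` (default 10) best-screened starts are refined by
  Levenberg–Marquardt (`minpack.lm::nls.lm`) with an analytic Jacobian.

Box bounds keep solutions interpretable: `b` in `[0, 2]` per hour and the
period in `[2, 48]` h, the latter excluding aliasing solutions on a 15-min
grid. Negative fitted amplitudes are folded away by canonicalization
afterwards rather than by constraining the optimizer. Convergence is a
relative SSE change below `1e-10`; a start that exhausts its iteration
budget is kept only as a `converged = FALSE` fallback, and ties between
converged starts break by lowest SSE, then lowest `b`, then lowest `d`.
When two conditions are compared, hybrid refits (below) are initialized at
the pooled-data best fit — the fit to the two conditions' averaged means —
with a 3-start screened fallback on divergence.

## Model-fit ANOVA

`model_anova()` tests the five-constant model against the intercept-only
model with the nested-regression F statistic

$$F = \frac{(\mathrm{SSE}_0 - \mathrm{SSE}_1)/4}{\mathrm{SSE}_1/(n-5)}$$

referred to `F(4, n - 5)` — the standard cosinor zero-amplitude test
generalized to the four non-intercept constants. Because the frequency and
phase are *estimated* before the test, the reference distribution is an
approximation and the test is mildly anti-conservative: on flat-data null
simulations the package's own test suite measures a rejection rate of
roughly 7% at a nominal 5%. For screening fits this is immaterial (the
rhythmic fits of interest reject at p far below 1e-4); for borderline
rhythms, treat the p-value as descriptive. An exact fit (`SSE_1`
numerically zero, as with noiseless synthetic data) is reported as
`p_value = 0` with an `exact_fit` flag.

## Timing metrics

`rhythm_metrics()` reports the period, the peak and nadir times, and the
peak-to-nadir interval. The peak is the stationary maximum with the
largest curve value inside the requested window (for a decaying envelope
that is the earliest maximum); the nadir is the first stationary minimum
after the peak, which may fall past the window's end — it is the timing of
the fitted curve's descent, not a grid search truncated at the last
sample. The window must span at least one period so a maximum exists.

# The MESOR randomization test

To decide whether two conditions (vehicle vs. treatment, wild type vs.
mutant) differ in rhythm-adjusted mean expression, `mesor_null_test()`
implements a condition-shuffled randomization: at every timepoint,
independently with probability 1/2, a hybrid series takes the
per-timepoint mean of condition A or of condition B. Each of `n_iter`
(default 1,000) hybrids is refit and its MESOR recorded; a real condition
effect leaves the two observed MESORs at opposite extremes of the
approximately normal null distribution.

Design choices, each pinned by a test:

* **Resampling unit.** The per-timepoint replicate *mean*, matching the
  fitting target; resampling raw replicates would change the statistic's
  variance.
* **Empirical p.** Add-one rule,
  `p = (1 + #extreme) / (n_converged + 1)`, one-sided per condition with
  the side chosen by the observed MESOR's position relative to the null
  mean. The observed fits never enter the null, and `p > 0` always.
  Because the side is data-chosen, the reported p behaves like a
  two-sided p under the null: `P(p <= alpha) ~ 2 * alpha`. Compare it to
  half your intended level, or use the joint statistic
  `min(p_a, p_b) <= alpha/2`, which the test suite shows holds its size.
* **Coin-flip stream.** Iteration-major from one seeded generator, so a
  given `(data, n_iter, seed)` reproduces bit-identically on any machine,
  and `hybrid_resample()` regenerates exactly the series the test fitted.
* **Divergent hybrid fits** are excluded and counted (`n_failed`); the
  test aborts if more than 20% diverge.

Power scales with the MESOR separation measured in units of the fitted
MESOR's sampling SD (`mesor_sampling_sd()` estimates it by simulation;
there is no closed form for the nonlinear fit). The hybrid null's spread
is itself about one sampling SD, so separations of a few SD are needed
before both conditions sit reliably in the tails; the acceptance suite
measures the joint rejection rate rising monotonically over separations of
0–3 SD, reaching only ~30% at 3 SD with 41 timepoints, CV 0.1 and three
replicates. Interpret a significant result as strong evidence, but do not
expect small MESOR shifts to be detectable at these noise levels.

`paired_timepoint_test()` complements the randomization with the classical
paired t-test across timepoints (two-sided, `n - 1` df, pairing the
conditions at each shared time). Differences with zero variance are
reported as an exact tie rather than an error.

# The synthetic-data generator

`simulate_timecourse()` and `simulate_two_conditions()` emulate the
sampling design the models assume, and their defaults are the study
conditions used throughout the tests: samples every 15 min from ZT −4 to
+6 h (41 timepoints), three biological replicates per timepoint, period
9.5 h, decay 0.05 per hour, MESOR 1, amplitude 0.5, and multiplicative
noise with a 10% coefficient of variation.

The noise is lognormal, parameterized so the *linear-scale* mean equals
the model curve and the linear-scale CV equals `noise_cv`
(`sdlog^2 = log(1 + cv^2)` with the mean-preserving offset). Expression
measurements are positive and fold-change-natured, which makes a
multiplicative model the natural default; an additive-Gaussian mode
(sd `= cv * |curve|`) is available for checking that conclusions do not
hinge on the noise family. The lognormal mode refuses curves that touch
zero rather than silently truncating.

What the generator deliberately does **not** model: batch or dish random
effects (replicates are i.i.d. within timepoint), time-varying noise
(the CV is constant across the course), autocorrelated residuals, and
counting noise of sequencing-type data. Passing tests therefore
demonstrate correctness of the estimators under the stated noise model,
not robustness to structured noise in real experiments.

`simulate_ocr()` generates linear oxygen-consumption-rate series —
`intercept + slope * t` plus Gaussian noise — per well; its defaults (12
measurement cycles 8 min apart, ~150 pmol O2/min, 20 wells) are of the
order of an extracellular-flux run on embryos.

# Count-panel utilities

`normalize_to_references()` scales each sample so all samples share the
same geometric mean over the designated reference genes (e.g. *actb2*,
*rpl13a*, *eif5a*), the convention of panel-count normalizers; the target
is the global mean of the per-sample reference geomeans, which makes the
operation idempotent. Note that rescaling one sample moves that global
target, so normalized values are defined up to a common factor — ratios
and Z-scores downstream are unaffected. `z_scale_by_gene()` computes
per-gene Z-scores of log2 counts with the sample (n − 1) SD; constant
genes become all-zero rows with a warning and a `constant_genes`
attribute, keeping heat-map matrices rectangular. `condition_log2_ratio()`
takes replicate means before forming `log2(B/A)` at matched timepoints.
`relative_expression()` is the efficiency-corrected delta-Ct formula with
a default doubling efficiency.

# OCR analysis

The first measurement cycle of an extracellular-flux run is routinely
inconsistent; `exclude_first_point()` drops it per well and (by default)
rebases time so `t = 0` is the first retained cycle — the fitted intercept
then reads "basal rate at run start after exclusion".
`fit_ocr_line()` returns OLS slope and intercept with closed-form SEs.
Both analysis paths are provided: fitting each well and averaging
coefficients, or averaging the series within genotype × treatment and
fitting once (`ocr_average_series()`); for a shared time grid the two give
identical point estimates, differing only in how replicate scatter is
summarized. `compare_intercepts()` runs the two-factor ANOVA (genotype,
treatment, interaction; Type II sums of squares, which is also exact in
the balanced case) and Šídák-adjusts the pairwise cell contrasts with
`p_adj = 1 - (1 - p)^k` over all `k` contrasts, computed in `expm1` form
so tiny p-values do not underflow to zero.

# Problem sizes and numerical choices

The test and acceptance suites run at sizes chosen to give stable Monte
Carlo answers on a single CPU in a few minutes: 100 seeds for parameter
recovery, 500 simulated experiments for the randomization test's size
(with `n_iter = 200` per experiment), 20 seeds per effect size for power,
200 seeds for OCR recovery, and 500 simulations for ANOVA calibration.
Dense-grid oracles use a 1e-4 h step; identity checks (normalization,
canonicalization) are asserted to 1e-12; exact recovery of noiseless data
to 1e-6 relative error. Empirical-rate assertions carry 3-binomial-SE
tolerances.

# Known limitations

* The model-fit F test is mildly anti-conservative (above).
* The reported randomization p is one-sided with a data-chosen side;
  under the null it behaves like a two-sided p (above).
* The damped sinusoid cannot represent asymmetric waveforms
  (peak-to-nadir is always half the period); a compressed descent shows
  up as a shorter fitted period.
* Single-component sinusoid only: no harmonics, no nonparametric rhythm
  detection, no multi-gene FDR machinery.
* The generator's i.i.d., constant-CV noise understates the structure of
  real replicate variability; treat statistical-recovery numbers as
  best-case calibrations.
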