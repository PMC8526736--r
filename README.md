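# rhythmfit

Damped cosinor modelling and randomization inference for gene-expression
rhythms.

Circadian and ultradian transcripts — for example glucocorticoid-responsive
genes that peak just before lights-on and fall through the morning — are
measured as replicated time courses against zeitgeber time (ZT). Two
questions dominate the analysis of such data: *what is the rhythm* (its
mean level, amplitude, period, peak timing), and *did a condition change
it* (a treatment, a mutant genotype). `rhythmfit` answers both for the
damped sinusoid, a cosinor model with an exponentially decaying amplitude
envelope:

    y(t) = m + a · e^(−b·t) · sin(c · (t − d))

where `m` is the MESOR (Midline Estimating Statistic Of Rhythm, the
rhythm-adjusted mean), `a` the amplitude, `b` the decay rate per hour,
`c` the angular frequency (period = 2π/c), and `d` the phase shift in
hours. Fitting is multi-start nonlinear least squares on per-timepoint
replicate means, with a model-vs-flat F test, canonical parameters, and
analytic peak/nadir timing.

Condition effects on the MESOR are tested with a condition-shuffled
randomization: hybrid time series are built by picking, independently at
each timepoint, one condition's mean with probability ½; each hybrid is
refit, and the observed per-condition MESORs are located within the null
MESOR distribution (add-one empirical p-values). A paired-across-timepoints
t-test is included as the classical counterpart.

Around the model core the package ships the standard plumbing of this kind
of study: reference-gene (geometric-mean) normalization and per-gene
Z-scaling of count panels, log2 condition-ratio matrices,
efficiency-corrected ΔCt relative expression, oxygen-consumption-rate
(OCR) linear fits with first-cycle exclusion and a two-factor
genotype × treatment comparison with Šídák-adjusted contrasts, and a
seed-reproducible synthetic-data generator that emulates the sampling
designs the models assume (15-min sampling from ZT −4 to +6 h, three
replicates, multiplicative noise).

Everything is tidyverse-native: functions take a data frame first and
return tibbles, fitted objects have `tidy()`/`glance()`/`autoplot()`
methods, and all simulators are bit-reproducible under a seed.

## Worked example

```r
library(rhythmfit)
library(dplyr)

spec <- rhythm_sim_spec(mesor = 1, amplitude = 0.5, decay_rate = 0.05,
                        period_hours = 9.5, noise_cv = 0.1, seed = 42)
sim <- simulate_two_conditions(spec,
  condition_effect(delta_mesor = 0.15, delta_phase = 35 / 60),
  cond_a = "VEH", cond_b = "CORT")

fit_veh <- fit_sinusoid(filter(sim, condition == "VEH"))
fit_veh
#> <cosinor_fit> damped sinusoid m + a exp(-b t) sin(c (t - d))
#>   m=0.9906 a=0.5007 b=0.03399/h period=9.468 h d=9.447 h
#>   n=41 timepoints, SSE=0.1206, F(4,36)=369, p=1.12e-28

rhythm_metrics(fit_veh, window = c(-4, 6))
#> # A tibble: 1 × 5
#>   period peak_time nadir_time peak_to_nadir mesor
#>    <dbl>     <dbl>      <dbl>         <dbl> <dbl>
#> 1   9.47      2.27       7.00          4.73 0.991

rt <- mesor_null_test(sim, "VEH", "CORT", n_iter = 1000, seed = 42)
rt
#> <mesor_randomization>
#>   1000 hybrid series (1000 converged, 0 failed), seed 42
#>   null MESOR: mean 1.063, sd 0.03119
#>   VEH MESOR 0.9906 (p = 0.002997); CORT MESOR 1.141 (p = 0.008991)

paired_timepoint_test(sim, "VEH", "CORT")$p_value
#> [1] 3.07e-07
```

Reading the output: the vehicle condition's fitted rhythm has MESOR 0.99,
period 9.47 h and its peak at ZT 2.3 h; the simulated treatment raised the
MESOR by 0.15. Both observed MESORs sit in the far tails of the
1,000-hybrid null distribution (p ≈ 0.003 and 0.009, one-sided add-one
rule), so the treatment's elevation of mean expression is significant by
the randomization test, and the paired t-test across the 41 timepoints
agrees. `autoplot(fit_veh)` draws the fitted curve over the data and
`autoplot(rt)` the null histogram with the observed MESORs.

The methods vignette (`vignettes/damped-cosinor-rhythms.Rmd`) documents
the model, the multi-start fitting scheme, the randomization-test
conventions and their calibration, the generator's noise model, and known
limitations.

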