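#' Specification for a simulated rhythmic time course
#'
#' Describes one gene-by-condition time course with damped-sinusoid mean
#' structure `m + a * exp(-b * t) * sin(c * (t - d))` sampled on a regular
#' zeitgeber-time (ZT) grid with replicated, noisy measurements. The defaults
#' mirror a high-density larval sampling design: measurements every 15 min
#' from ZT -4 to ZT +6 h, three biological replicates per timepoint, a
#' period of 9.5 h and a measurement coefficient of variation of 10%.
#'
#' @param mesor Rhythm-adjusted mean `m` (expression units).
#' @param amplitude Amplitude `a` at `t = 0` (expression units, >= 0).
#' @param decay_rate Exponential decay rate `b` of the amplitude envelope
#'   (per hour, >= 0; 0 means an undamped sinusoid).
#' @param period_hours Oscillation period in hours; converted internally to
#'   the angular frequency `c = 2 * pi / period_hours`. Supply exactly one of
#'   `period_hours` or `angular_frequency`.
#' @param angular_frequency Angular frequency `c` in radians per hour (> 0).
#' @param phase_shift Phase shift `d` in hours (the sinusoid is evaluated at
#'   `c * (t - d)`).
#' @param t_start,t_end First and last sampling time (hours ZT; negative
#'   times are meaningful and denote hours before lights-on).
#' @param dt Sampling interval in hours (> 0).
#' @param n_replicates Biological replicates per timepoint (>= 1).
#' @param noise_cv Coefficient of variation of the measurement noise on the
#'   linear scale (dimensionless, >= 0).
#' @param noise_model `"lognormal"` (default) for multiplicative noise whose
#'   linear-scale mean equals the model curve and whose CV equals
#'   `noise_cv`; `"additive"` for Gaussian noise with sd
#'   `noise_cv * |curve|`.
#' @param seed Integer seed used by the simulators unless overridden.
#' @return An object of class `rhythm_sim_spec`.
#' @seealso [simulate_timecourse()], [simulate_two_conditions()]
#' @examples
#' spec <- rhythm_sim_spec(mesor = 1, amplitude = 0.5, decay_rate = 0.05)
#' spec$angular_frequency   # 2 * pi / 9.5
#' @export
rhythm_sim_spec <- function(mesor = 1,
                            amplitude = 0.5,
                            decay_rate = 0.05,
                            period_hours = 9.5,
                            angular_frequency = NULL,
                            phase_shift = 0,
                            t_start = -4,
                            t_end = 6,
                            dt = 0.25,
                            n_replicates = 3,
                            noise_cv = 0.1,
                            noise_model = c("lognormal", "additive"),
                            seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_number(mesor, "mesor")
  check_number(amplitude, "amplitude", lower = 0)
  check_number(decay_rate, "decay_rate", lower = 0)
  if (is.null(angular_frequency)) {
    check_number(period_hours, "period_hours", lower = 0, allow_lower = FALSE)
    angular_frequency <- 2 * pi / period_hours
  } else {
    check_number(angular_frequency, "angular_frequency",
                 lower = 0, allow_lower = FALSE)
  }
  check_number(phase_shift, "phase_shift")
  check_number(t_start, "t_start")
  check_number(t_end, "t_end")
  if (t_end <= t_start) stop_field("t_end", "must be greater than t_start")
  check_number(dt, "dt", lower = 0, allow_lower = FALSE)
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_number(noise_cv, "noise_cv", lower = 0)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)

  structure(
    list(
      mesor = mesor, amplitude = amplitude, decay_rate = decay_rate,
      angular_frequency = angular_frequency, phase_shift = phase_shift,
      t_start = t_start, t_end = t_end, dt = dt,
      n_replicates = n_replicates, noise_cv = noise_cv,
      noise_model = noise_model, seed = seed
    ),
    class = "rhythm_sim_spec"
  )
}

#' @export
print.rhythm_sim_spec <- function(x, ...) {
  cat("<rhythm_sim_spec>\n")
  cat(sprintf("  curve : m=%g a=%g b=%g/h period=%g h d=%g h\n",
              x$mesor, x$amplitude, x$decay_rate,
              2 * pi / x$angular_frequency, x$phase_shift))
  cat(sprintf("  grid  : ZT %g..%g h every %g h, %d replicates\n",
              x$t_start, x$t_end, x$dt, x$n_replicates))
  cat(sprintf("  noise : %s, CV=%g (seed %d)\n",
              x$noise_model, x$noise_cv, x$seed))
  invisible(x)
}

#' Condition effect applied to a rhythm simulation
#'
#' Parameterizes how a second experimental condition (e.g. chronic
#' glucocorticoid treatment, or a mutant genotype) differs from the
#' baseline: an additive MESOR shift, a phase delay in hours, and a
#' multiplicative amplitude change.
#'
#' @param delta_mesor Additive shift of the MESOR (expression units).
#' @param delta_phase Shift of the phase `d` in hours; positive values delay
#'   the peak.
#' @param amplitude_scale Multiplicative factor on the amplitude (>= 0).
#' @return An object of class `condition_effect`.
#' @export
condition_effect <- function(delta_mesor = 0, delta_phase = 0,
                             amplitude_scale = 1) {
  check_number(delta_mesor, "delta_mesor")
  check_number(delta_phase, "delta_phase")
  check_number(amplitude_scale, "amplitude_scale", lower = 0)
  structure(
    list(delta_mesor = delta_mesor, delta_phase = delta_phase,
         amplitude_scale = amplitude_scale),
    class = "condition_effect"
  )
}

#' Specification for a simulated oxygen-consumption-rate run
#'
#' Linear mean structure `intercept + slope * t` sampled at regular
#' intervals in minutes, one series per well, with additive Gaussian noise.
#' The defaults emulate an extracellular-flux run: 12 measurement cycles
#' spanning at least 85 min and OCR values of order 100 pmol O2/min.
#'
#' @param intercept OCR at the first measurement (pmol O2/min).
#' @param slope Rate of change of OCR (pmol O2/min per minute).
#' @param n_timepoints Measurements per well (>= 3).
#' @param dt Minutes between measurements (> 0).
#' @param n_wells Number of wells (>= 1).
#' @param noise_sd Additive Gaussian noise sd (pmol O2/min, >= 0).
#' @param seed Integer seed.
#' @return An object of class `ocr_sim_spec`.
#' @seealso [simulate_ocr()]
#' @export
ocr_sim_spec <- function(intercept = 150, slope = -0.2, n_timepoints = 12,
                         dt = 8, n_wells = 20, noise_sd = 5, seed = 1L) {
  check_number(intercept, "intercept")
  check_number(slope, "slope")
  n_timepoints <- check_count(n_timepoints, "n_timepoints", lower = 3L)
  check_number(dt, "dt", lower = 0, allow_lower = FALSE)
  n_wells <- check_count(n_wells, "n_wells")
  check_number(noise_sd, "noise_sd", lower = 0)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  structure(
    list(intercept = intercept, slope = slope, n_timepoints = n_timepoints,
         dt = dt, n_wells = n_wells, noise_sd = noise_sd, seed = seed),
    class = "ocr_sim_spec"
  )
}

# Mean curve of a rhythm spec on its own sampling grid
spec_times <- function(spec) {
  seq(spec$t_start, spec$t_end, by = spec$dt)
}

spec_curve <- function(spec, t) {
  damped_sinusoid(t, spec$mesor, spec$amplitude, spec$decay_rate,
                  spec$angular_frequency, spec$phase_shift)
}

# Draws noisy values for one spec using the current RNG state.
# Values are laid out replicate-major within timepoint: the noise matrix is
# drawn as rnorm(n_times * n_replicates) filled column-by-replicate.
sim_values <- function(spec) {
  t <- spec_times(spec)
  mu <- spec_curve(spec, t)
  n_t <- length(t)
  n_r <- spec$n_replicates
  z <- matrix(rnorm(n_t * n_r), nrow = n_t, ncol = n_r)
  if (spec$noise_cv == 0) {
    vals <- matrix(mu, nrow = n_t, ncol = n_r)
  } else if (spec$noise_model == "lognormal") {
    if (any(mu <= 0)) {
      stop_field("noise_model",
                 paste("lognormal noise requires a strictly positive model",
                       "curve; use noise_model = 'additive' or raise the",
                       "mesor"))
    }
    s <- sqrt(log(1 + spec$noise_cv^2))
    vals <- mu * exp(s * z - s^2 / 2)
  } else {
    vals <- mu + spec$noise_cv * abs(mu) * z
  }
  tibble(
    zt_hours = rep(t, times = n_r),
    replicate = rep(seq_len(n_r), each = n_t),
    value = as.numeric(vals)
  )
}

#' Simulate a replicated rhythmic time course
#'
#' Draws one gene-by-condition time course from the damped-sinusoid model of
#' the supplied [rhythm_sim_spec()]. Noise is multiplicative lognormal
#' parameterized so that the linear-scale mean equals the model curve and
#' the linear-scale coefficient of variation equals `noise_cv` (an additive
#' Gaussian mode is available via the spec). With `noise_cv = 0` every
#' replicate lies exactly on the curve. Identical `(spec, seed)` give
#' bit-identical output.
#'
#' @param spec A [rhythm_sim_spec()].
#' @param gene,condition Labels written into the output columns.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A tibble with columns `gene`, `condition`, `zt_hours`,
#'   `replicate`, `value` (long format, one row per measurement).
#' @examples
#' tc <- simulate_timecourse(rhythm_sim_spec(noise_cv = 0))
#' head(tc)
#' @export
simulate_timecourse <- function(spec, gene = "gene", condition = "A",
                                seed = spec$seed) {
  stopifnot(inherits(spec, "rhythm_sim_spec"))
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  set.seed(seed)
  out <- sim_values(spec)
  tibble(gene = gene, condition = condition, out)
}

# Applies a condition_effect to a spec
apply_effect <- function(spec, effect) {
  spec$mesor <- spec$mesor + effect$delta_mesor
  spec$phase_shift <- spec$phase_shift + effect$delta_phase
  spec$amplitude <- spec$amplitude * effect$amplitude_scale
  spec
}

#' Simulate a two-condition rhythm experiment
#'
#' Condition `cond_a` is drawn from `spec`; condition `cond_b` from the same
#' spec with its MESOR shifted by `delta_mesor`, its phase delayed by
#' `delta_phase` hours and its amplitude scaled by `amplitude_scale`
#' (see [condition_effect()]). Both conditions share the time grid and
#' replicate count and receive independent noise draws from one seeded
#' stream (condition A first).
#'
#' @param spec Baseline [rhythm_sim_spec()].
#' @param effect A [condition_effect()].
#' @param cond_a,cond_b Condition labels (e.g. `"VEH"`, `"CORT"`).
#' @param gene Gene label.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A long tibble with both conditions stacked (columns `gene`,
#'   `condition`, `zt_hours`, `replicate`, `value`).
#' @examples
#' sim <- simulate_two_conditions(
#'   rhythm_sim_spec(noise_cv = 0),
#'   condition_effect(delta_mesor = 0.5)
#' )
#' @export
simulate_two_conditions <- function(spec, effect = condition_effect(),
                                    cond_a = "A", cond_b = "B",
                                    gene = "gene", seed = spec$seed) {
  stopifnot(inherits(spec, "rhythm_sim_spec"),
            inherits(effect, "condition_effect"))
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  spec_b <- apply_effect(spec, effect)
  set.seed(seed)
  a <- sim_values(spec)
  b <- sim_values(spec_b)
  dplyr::bind_rows(
    tibble(gene = gene, condition = cond_a, a),
    tibble(gene = gene, condition = cond_b, b)
  )
}

#' Simulate oxygen-consumption-rate series
#'
#' Each well's series is `intercept + slope * t + N(0, noise_sd)` at times
#' `0, dt, ..., (n_timepoints - 1) * dt` minutes; seed-reproducible.
#'
#' @param spec An [ocr_sim_spec()].
#' @param genotype,treatment Labels written into the output.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @param well_prefix Prefix for well ids.
#' @return A tibble with columns `well`, `genotype`, `treatment`,
#'   `t_minutes`, `ocr`.
#' @examples
#' ocr <- simulate_ocr(ocr_sim_spec(noise_sd = 0, n_wells = 2))
#' @export
simulate_ocr <- function(spec, genotype = "WT", treatment = "VEH",
                         seed = spec$seed, well_prefix = "w") {
  stopifnot(inherits(spec, "ocr_sim_spec"))
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  set.seed(seed)
  t <- (seq_len(spec$n_timepoints) - 1) * spec$dt
  n_t <- spec$n_timepoints
  wells <- sprintf("%s%02d", well_prefix, seq_len(spec$n_wells))
  noise <- matrix(rnorm(n_t * spec$n_wells, sd = spec$noise_sd),
                  nrow = n_t, ncol = spec$n_wells)
  tibble(
    well = rep(wells, each = n_t),
    genotype = genotype,
    treatment = treatment,
    t_minutes = rep(t, times = spec$n_wells),
    ocr = as.numeric(spec$intercept + spec$slope * t + noise)
  )
}

#' Estimate the sampling standard deviation of the fitted MESOR
#'
#' Simulates repeated experiments from `spec`, fits the damped sinusoid to
#' each, and returns the standard deviation of the fitted MESOR. This is
#' the natural scale for condition effects in power analyses of the MESOR
#' randomization test.
#'
#' @param spec A [rhythm_sim_spec()].
#' @param n_sims Number of simulated experiments.
#' @param seed Integer seed.
#' @param ... Passed to [fit_sinusoid()].
#' @return A single number: the SD of fitted MESORs across simulations.
#' @export
mesor_sampling_sd <- function(spec, n_sims = 200, seed = 1L, ...) {
  n_sims <- check_count(n_sims, "n_sims", lower = 2L)
  mesors <- vapply(seq_len(n_sims), function(i) {
    tc <- simulate_timecourse(spec, seed = seed + i - 1L)
    fit <- fit_sinusoid(tc, ...)
    fit$params[["m"]]
  }, numeric(1))
  sd(mesors)
}
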