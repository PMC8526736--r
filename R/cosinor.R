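#' Evaluate the damped sinusoid
#'
#' The model curve `m + a * exp(-b * t) * sin(c * (t - d))`, where `m` is
#' the MESOR (rhythm-adjusted mean), `a` the amplitude at `t = 0`, `b` the
#' exponential decay rate of the amplitude envelope (per hour), `c` the
#' angular frequency (radians per hour; period = `2 * pi / c`), and `d` the
#' phase shift in hours.
#'
#' @param t Time in hours (vectorized).
#' @param m,a,b,c,d Model constants. Alternatively pass a single named list
#'   or vector as `m` (elements `m`, `a`, `b`, `c`, `d`).
#' @return Numeric vector of model values.
#' @examples
#' damped_sinusoid(1, m = 2, a = 1, b = 0, c = pi / 2, d = 0)  # 3
#' @export
damped_sinusoid <- function(t, m, a, b, c, d) {
  if (missing(a) && (is.list(m) || length(m) == 5L)) {
    p <- unlist(m)
    return(p[["m"]] + p[["a"]] * exp(-p[["b"]] * t) *
             sin(p[["c"]] * (t - p[["d"]])))
  }
  m + a * exp(-b * t) * sin(c * (t - d))
}

check_params <- function(params) {
  p <- unlist(params)
  if (!all(c("m", "a", "b", "c", "d") %in% names(p))) {
    stop_field("params", "needs named elements m, a, b, c, d")
  }
  p <- p[c("m", "a", "b", "c", "d")]
  if (!all(is.finite(p))) stop_field("params", "all constants must be finite")
  p
}

#' Canonicalize damped-sinusoid parameters
#'
#' The model has exact symmetries `(a, d) == (-a, d + pi/c)` and
#' `d == d + 2*pi/c`; canonical form has `a >= 0`, `c > 0` and `d` reduced
#' modulo the period into `[0, 2*pi/c)`. The returned parameters evaluate
#' identically to the input at every `t`.
#'
#' @param params Named list or vector with elements `m`, `a`, `b`, `c`, `d`.
#' @return Named list of canonical constants.
#' @examples
#' canonicalize_sinusoid(list(m = 0, a = -1, b = 0, c = pi, d = 0))
#' @export
canonicalize_sinusoid <- function(params) {
  p <- check_params(params)
  m <- p[["m"]]; a <- p[["a"]]; b <- p[["b"]]; c <- p[["c"]]; d <- p[["d"]]
  if (c == 0) stop_rf("angular frequency c must be nonzero",
                      "rhythmfit_zero_frequency")
  if (c < 0) {  # sin(c(t-d)) = -sin((-c)(t-d)): flip the sign into a
    c <- -c
    a <- -a
  }
  period <- 2 * pi / c
  if (a < 0) {  # -|a| sin(theta) = |a| sin(theta - pi): delay d by half period
    a <- -a
    d <- d + period / 2
  }
  d <- d %% period
  list(m = m, a = a, b = b, c = c, d = d)
}

# Residuals and analytic Jacobian for the Levenberg-Marquardt solver.
# par = c(m, a, b, c, d); residual = y - f(t, par).
ds_resid <- function(par, t, y) {
  y - (par[1] + par[2] * exp(-par[3] * t) * sin(par[4] * (t - par[5])))
}

ds_jac <- function(par, t, y) {
  e <- exp(-par[3] * t)
  th <- par[4] * (t - par[5])
  s <- sin(th)
  co <- cos(th)
  # d(resid)/d(par) = -d(f)/d(par)
  cbind(
    -1,
    -e * s,
    par[2] * t * e * s,
    -par[2] * e * co * (t - par[5]),
    par[2] * e * co * par[4]
  )
}

# Profile the linear constants (m, a) for fixed (b, c, d): least squares of
# y on [1, exp(-b t) sin(c (t - d))]. Returns c(m, a, sse).
profile_linear <- function(t, y, b, c, d) {
  s <- exp(-b * t) * sin(c * (t - d))
  n <- length(t)
  ss <- sum(s); s2 <- sum(s * s)
  sy <- sum(y); sys <- sum(y * s)
  det <- n * s2 - ss * ss
  if (!is.finite(det) || abs(det) < 1e-12 * max(n * s2, 1)) {
    m <- mean(y)
    return(c(m, 0, sum((y - m)^2)))
  }
  m <- (s2 * sy - ss * sys) / det
  a <- (n * sys - ss * sy) / det
  r <- y - m - a * s
  c(m, a, sum(r * r))
}

# Default multi-start schedule: b in {0, 0.05, 0.2} per hour, period seeds
# {6, 8, 9.5, 12, 24} h, 8 equispaced phases per period (120 starts); extra
# random starts (seeded) beyond 120 if requested.
default_start_grid <- function(n_starts, seed = NULL) {
  b0 <- c(0, 0.05, 0.2)
  per0 <- c(6, 8, 9.5, 12, 24)
  grid <- expand.grid(b = b0, period = per0, frac = (0:7) / 8)
  grid$d <- grid$frac * grid$period
  grid <- grid[c("b", "period", "d")]
  if (n_starts < nrow(grid)) {
    grid  # screened later; all are cheap to score
  } else if (n_starts > nrow(grid)) {
    n_extra <- n_starts - nrow(grid)
    if (!is.null(seed)) set.seed(seed)
    extra <- data.frame(
      b = runif(n_extra, 0, 0.5),
      period = runif(n_extra, 4, 24)
    )
    extra$d <- runif(n_extra, 0, extra$period)
    rbind(grid, extra)
  } else {
    grid
  }
}

# Core multi-start Levenberg-Marquardt fit on per-timepoint means.
# starts: list of numeric c(m, a, b, c, d). Convergence is a relative SSE
# change below 1e-10 (or a parameter/gradient criterion of the same order);
# a solution that exhausts the iteration budget is kept as a non-converged
# fallback rather than discarded.
fit_damped_core <- function(t, y, starts, b_max = 2,
                            period_range = c(2, 48),
                            maxiter = 1000L) {
  lower <- c(-Inf, -Inf, 0, 2 * pi / period_range[2], -Inf)
  upper <- c(Inf, Inf, b_max, 2 * pi / period_range[1], Inf)
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-10,
                                     ptol = 1e-10, gtol = 0)
  best <- NULL
  best_any <- NULL
  n_tried <- 0L
  for (p0 in starts) {
    n_tried <- n_tried + 1L
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                           fn = ds_resid, jac = ds_jac, t = t, y = y,
                           control = ctrl)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$deviance)) next
    cand <- list(par = fit$par, sse = fit$deviance)
    # info 1-4: converged; 6-8: requested tolerance unachievable, i.e. no
    # further reduction possible at the minimum (accepted as converged);
    # -1/5: iteration budget exhausted (kept only as fallback).
    if (fit$info %in% c(1:4, 6:8)) {
      if (is.null(best) || better_solution(cand, best)) best <- cand
    } else {
      if (is.null(best_any) || better_solution(cand, best_any)) {
        best_any <- cand
      }
    }
  }
  list(best = best, best_any = best_any, n_tried = n_tried)
}

# Tie-break: lower SSE, then (at SSE ties) lower decay b, then lower phase d
# of the canonical form.
better_solution <- function(cand, best, tol = 1e-12) {
  if (cand$sse < best$sse * (1 - tol) - tol) return(TRUE)
  if (cand$sse > best$sse * (1 + tol) + tol) return(FALSE)
  pc <- canonicalize_sinusoid(setNames(as.list(cand$par),
                                       c("m", "a", "b", "c", "d")))
  pb <- canonicalize_sinusoid(setNames(as.list(best$par),
                                       c("m", "a", "b", "c", "d")))
  if (abs(pc$b - pb$b) > 1e-9) return(pc$b < pb$b)
  pc$d < pb$d
}

# Screen candidate (b, period, d) starts by profiled-SSE; returns list of
# full start vectors for the top `n_polish`.
screen_starts <- function(t, y, grid, n_polish) {
  sses <- numeric(nrow(grid))
  ms <- numeric(nrow(grid))
  as_ <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pl <- profile_linear(t, y, grid$b[i], 2 * pi / grid$period[i], grid$d[i])
    ms[i] <- pl[1]; as_[i] <- pl[2]; sses[i] <- pl[3]
  }
  ord <- order(sses)[seq_len(min(n_polish, nrow(grid)))]
  lapply(ord, function(i) {
    c(ms[i], as_[i], grid$b[i], 2 * pi / grid$period[i], grid$d[i])
  })
}

#' Fit the damped sinusoid to a time course
#'
#' Nonlinear least squares fit of
#' `value = m + a * exp(-b * t) * sin(c * (t - d))` to a replicated time
#' course. By default replicate values are collapsed to per-timepoint means
#' before fitting (the plotted and modelled quantity in rhythm time-course
#' figures); set `collapse_replicates = FALSE` to fit all replicate points.
#' Optimization is multi-start Levenberg-Marquardt: candidate starts from a
#' coarse grid over decay, period and phase (the linear constants `m`, `a`
#' profiled out) are screened by their profiled SSE, and the best
#' `n_polish` are refined. The decay rate is bounded to `[0, b_max]` and the
#' period to `period_range` (aliasing guard for a 15-min grid); the returned
#' parameters are canonical (`a >= 0`, `d` in `[0, period)`).
#'
#' @param data Data frame with one row per measurement.
#' @param time,value Columns holding time (hours) and expression values
#'   (tidy-eval; defaults `zt_hours`, `value`).
#' @param init Optional named list/vector `m`, `a`, `b`, `c`, `d` used as
#'   the sole initializer (e.g. the pooled-data best fit when refitting
#'   hybrid series). If it fails to converge the multi-start grid is used
#'   as fallback.
#' @param n_starts Number of grid starts to generate (default 120: 3 decay
#'   x 5 period x 8 phase seeds); values above 120 add seeded random starts.
#' @param n_polish Number of screened starts refined by the optimizer.
#' @param seed Seed for random extra starts (only used if `n_starts > 120`).
#' @param collapse_replicates Fit per-timepoint means (default) or raw
#'   points.
#' @param b_max Upper bound for the decay rate (per hour).
#' @param period_range Lower/upper period bounds in hours.
#' @return An object of class `cosinor_fit`: fitted canonical `params`,
#'   `sse`, `sse_null` (intercept-only), `f_stat` / `p_value` from the
#'   model-vs-intercept F test, `n` timepoints, `converged`,
#'   `n_starts_tried`, and the fitted `data` (per-timepoint means).
#' @examples
#' tc <- simulate_timecourse(rhythm_sim_spec(noise_cv = 0))
#' fit <- fit_sinusoid(tc)
#' tidy(fit)
#' glance(fit)
#' @export
fit_sinusoid <- function(data, time = zt_hours, value = value, init = NULL,
                         n_starts = 120, n_polish = 10, seed = NULL,
                         collapse_replicates = TRUE, b_max = 2,
                         period_range = c(2, 48)) {
  tq <- enquo(time); vq <- enquo(value)
  tt <- dplyr::pull(data, !!tq)
  yy <- dplyr::pull(data, !!vq)
  if (collapse_replicates) {
    tm <- timepoint_means(tt, yy)
  } else {
    ord <- order(tt)
    tm <- tibble(t = tt[ord], y = yy[ord])
    if (!all(is.finite(tm$t) & is.finite(tm$y))) {
      stop_field("value", "all times and values must be finite")
    }
  }
  n_distinct_t <- length(unique(tm$t))
  if (n_distinct_t < 6L) {
    stop_rf(sprintf(
      "need >= 6 distinct timepoints to fit 5 constants (got %d)",
      n_distinct_t), "rhythmfit_too_few_timepoints")
  }

  res_init <- if (!is.null(init)) {
    fit_damped_core(tm$t, tm$y, list(unname(check_params(init))),
                    b_max, period_range)
  }
  if (!is.null(res_init) && !is.null(res_init$best)) {
    res <- res_init
  } else {
    grid <- default_start_grid(n_starts, seed)
    gstarts <- screen_starts(tm$t, tm$y, grid, n_polish)
    res <- fit_damped_core(tm$t, tm$y, gstarts, b_max, period_range)
    res$n_tried <- res$n_tried + (res_init$n_tried %||% 0L)
    if (is.null(res$best_any) && !is.null(res_init$best_any)) {
      res$best_any <- res_init$best_any
    }
  }
  converged <- !is.null(res$best)
  sol <- res$best %||% res$best_any
  if (is.null(sol)) {
    stop_rf(sprintf("no start converged (%d tried)", res$n_tried),
            "rhythmfit_all_starts_diverged", n_starts_tried = res$n_tried)
  }

  params <- canonicalize_sinusoid(
    setNames(as.list(sol$par), c("m", "a", "b", "c", "d"))
  )
  sse_model <- sol$sse
  ybar <- mean(tm$y)
  sse_null <- sum((tm$y - ybar)^2)
  sse_model <- min(sse_model, sse_null)  # guard FP noise on flat data
  an <- anova_from_sse(sse_null, sse_model, nrow(tm))

  structure(
    list(
      params = params, sse = sse_model, sse_null = sse_null,
      f_stat = an$f_stat, p_value = an$p_value, exact_fit = an$exact_fit,
      n = nrow(tm), converged = converged, n_starts_tried = res$n_tried,
      data = tm
    ),
    class = "cosinor_fit"
  )
}

# Model-vs-intercept F test with (4, n - 5) degrees of freedom
anova_from_sse <- function(sse_null, sse_model, n) {
  if (n <= 5L) stop_rf("F test needs more than 5 timepoints",
                       "rhythmfit_too_few_timepoints")
  if (sse_model <= 1e-12 * max(sse_null, .Machine$double.eps)) {
    return(list(f_stat = Inf, p_value = 0, exact_fit = TRUE))
  }
  f <- ((sse_null - sse_model) / 4) / (sse_model / (n - 5))
  f <- max(f, 0)
  list(f_stat = f, p_value = pf(f, 4, n - 5, lower.tail = FALSE),
       exact_fit = FALSE)
}

#' Model-fit ANOVA for a damped-sinusoid fit
#'
#' Nested-model regression F test of the five-constant sinusoid against the
#' intercept-only (flat) model:
#' `F = ((SSE_null - SSE_model) / 4) / (SSE_model / (n - 5))`, referred to
#' the F(4, n - 5) distribution. An exact fit (`SSE_model` numerically 0)
#' is reported as `p_value = 0` with `exact_fit = TRUE`.
#'
#' @param fit A `cosinor_fit` from [fit_sinusoid()].
#' @return A tibble with `f_stat`, `p_value`, `df1`, `df2`, `exact_fit`.
#' @export
model_anova <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  an <- anova_from_sse(fit$sse_null, fit$sse, fit$n)
  tibble(f_stat = an$f_stat, p_value = an$p_value,
         df1 = 4L, df2 = fit$n - 5L, exact_fit = an$exact_fit)
}

#' Rhythm timing metrics of a fitted damped sinusoid
#'
#' Period, peak and nadir times, and the peak-to-nadir interval from the
#' fitted constants. Stationary points of the curve satisfy
#' `tan(c * (t - d)) = c / b` (for `b = 0` they sit at quarter and
#' three-quarter period after `d`); consecutive stationary points are
#' exactly half a period apart for every decay rate. `peak_time` is the
#' stationary maximum with the largest curve value inside the window (the
#' earliest maximum when the envelope decays); `nadir_time` is the first
#' stationary minimum after the peak.
#'
#' @param object A `cosinor_fit` or a named parameter list/vector
#'   (`m`, `a`, `b`, `c`, `d`; canonical form assumed).
#' @param window Length-2 numeric `(t_lo, t_hi)` in hours ZT; must span at
#'   least one period.
#' @return A tibble with `period`, `peak_time`, `nadir_time`,
#'   `peak_to_nadir`, `mesor` (all times in hours).
#' @examples
#' rhythm_metrics(list(m = 1, a = 1, b = 0, c = 2 * pi / 24, d = 0),
#'                window = c(0, 24))
#' @export
rhythm_metrics <- function(object, window = c(-4, 6)) {
  p <- if (inherits(object, "cosinor_fit")) object$params else
    as.list(check_params(object))
  if (p$c <= 0) stop_rf("angular frequency c must be positive (canonical)",
                        "rhythmfit_zero_frequency")
  if (p$a <= 0) stop_rf("rhythm metrics are undefined for zero amplitude",
                        "rhythmfit_zero_amplitude")
  period <- 2 * pi / p$c
  if (length(window) != 2L || diff(window) < period) {
    stop_rf(sprintf(
      "window must span at least one period (%.3g h)", period),
      "rhythmfit_window_too_short")
  }
  # stationary maxima: c*(t - d) = atan2(c, b) + 2k*pi
  theta <- atan2(p$c, p$b)
  t0 <- p$d + theta / p$c
  k_lo <- ceiling((window[1] - t0) / period)
  k_hi <- floor((window[2] - t0) / period)
  if (k_hi < k_lo) {
    stop_rf("no stationary maximum inside the window",
            "rhythmfit_window_too_short")
  }
  peaks <- t0 + (k_lo:k_hi) * period
  vals <- damped_sinusoid(peaks, p$m, p$a, p$b, p$c, p$d)
  peak_time <- peaks[which.max(vals)]
  nadir_time <- peak_time + period / 2
  tibble(
    period = period, peak_time = peak_time, nadir_time = nadir_time,
    peak_to_nadir = nadir_time - peak_time, mesor = p$m
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  p <- x$params
  cat("<cosinor_fit> damped sinusoid m + a exp(-b t) sin(c (t - d))\n")
  cat(sprintf("  m=%.4g a=%.4g b=%.4g/h period=%.4g h d=%.4g h\n",
              p$m, p$a, p$b, 2 * pi / p$c, p$d))
  cat(sprintf("  n=%d timepoints, SSE=%.4g, F(4,%d)=%.4g, p=%.3g\n",
              x$n, x$sse, x$n - 5L, x$f_stat, x$p_value))
  invisible(x)
}

#' @rdname fit_sinusoid
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @export
tidy.cosinor_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("mesor", "amplitude", "decay_rate", "angular_frequency",
             "phase_shift"),
    estimate = c(p$m, p$a, p$b, p$c, p$d)
  )
}

#' @rdname fit_sinusoid
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble(
    sse = x$sse, sse_null = x$sse_null, f_stat = x$f_stat,
    p_value = x$p_value, n_timepoints = x$n,
    period_hours = 2 * pi / x$params$c,
    converged = x$converged, n_starts_tried = x$n_starts_tried
  )
}

#' @rdname fit_sinusoid
#' @param object A `cosinor_fit`.
#' @export
autoplot.cosinor_fit <- function(object, ...) {
  grid <- tibble(
    t = seq(min(object$data$t), max(object$data$t), length.out = 400)
  )
  grid$y <- damped_sinusoid(grid$t, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Expression",
                  title = "Damped-sinusoid fit") +
    ggplot2::theme_minimal()
}
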