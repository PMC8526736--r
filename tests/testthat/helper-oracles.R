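# Independent oracles used across tests. These deliberately avoid the
# package's fitting path: raw formula arithmetic, exhaustive grids, and
# stats::optim (Nelder-Mead) only.

# Direct evaluation of the model curve, written out long-hand.
oracle_curve <- function(t, m, a, b, c, d) {
  m + a * exp(-b * t) * sin(c * (t - d))
}

# Brute-force grid search over (m, a, b, period, d) with `n_grid` points
# per axis, followed by a Nelder-Mead polish of the best grid point.
# The (m, a) axes are evaluated through sufficient statistics so the full
# n_grid^5 grid stays cheap.
oracle_grid_fit <- function(t, y, n_grid = 15) {
  mg <- seq(min(y), max(y), length.out = n_grid)
  ag <- seq(0, max(y) - min(y), length.out = n_grid)
  bg <- seq(0, 0.5, length.out = n_grid)
  pg <- seq(4, 24, length.out = n_grid)
  dg <- seq(0, 24, length.out = n_grid)
  n <- length(t)
  syy <- sum(y * y); sy <- sum(y)
  best_sse <- Inf
  best <- NULL
  for (b in bg) {
    e <- exp(-b * t)
    for (per in pg) {
      c_ <- 2 * pi / per
      for (d in dg) {
        s <- e * sin(c_ * (t - d))
        ss <- sum(s); s2 <- sum(s * s); sys <- sum(y * s)
        # SSE(m, a) = syy + n m^2 + a^2 s2 - 2 m sy - 2 a sys + 2 m a ss
        sse_mat <- outer(
          n * mg^2 - 2 * mg * sy,
          ag^2 * s2 - 2 * ag * sys
        , "+") + outer(2 * mg, ag * ss) + syy
        idx <- arrayInd(which.min(sse_mat), dim(sse_mat))
        if (sse_mat[idx] < best_sse) {
          best_sse <- sse_mat[idx]
          best <- c(mg[idx[1]], ag[idx[2]], b, per, d)
        }
      }
    }
  }
  sse_fn <- function(p) {
    if (p[3] < 0 || p[4] <= 0) return(Inf)
    mu <- p[1] + p[2] * exp(-p[3] * t) * sin((2 * pi / p[4]) * (t - p[5]))
    sum((y - mu)^2)
  }
  pol <- stats::optim(best, sse_fn, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  pol <- stats::optim(pol$par, sse_fn, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(par = pol$par, sse = min(pol$value, best_sse))
}

# Dense-grid extremum of the model curve over a window.
oracle_grid_extrema <- function(m, a, b, c, d, window, step = 1e-4) {
  tt <- seq(window[1], window[2], by = step)
  yy <- oracle_curve(tt, m, a, b, c, d)
  list(
    t = tt, y = yy,
    argmax = tt[which.max(yy)], i_max = which.max(yy),
    argmin = tt[which.min(yy)], i_min = which.min(yy),
    n = length(tt)
  )
}

# Closed-form OLS via the normal equations (independent of stats::lm).
oracle_ols <- function(t, y, sigma = NULL) {
  X <- cbind(1, t)
  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, y)
  res <- y - X %*% beta
  s2 <- if (is.null(sigma)) sum(res^2) / (length(y) - 2) else sigma^2
  se <- sqrt(diag(xtx_inv) * s2)
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]))
}

# Standard study-condition spec used by several tests: 15-min sampling over
# ZT -4..6 h, 3 replicates, period 9.5 h, CV 0.1.
study_spec <- function(noise_cv = 0.1, ...) {
  rhythm_sim_spec(mesor = 1, amplitude = 0.5, decay_rate = 0.05,
                  period_hours = 9.5, phase_shift = 0, t_start = -4,
                  t_end = 6, dt = 0.25, n_replicates = 3,
                  noise_cv = noise_cv, ...)
}
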