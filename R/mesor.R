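# Internal: per-timepoint condition means on a validated shared grid.
condition_means <- function(data, cond_a, cond_b, condition, time, value) {
  cq <- enquo(condition); tq <- enquo(time); vq <- enquo(value)
  cond <- dplyr::pull(data, !!cq)
  if (!all(c(cond_a, cond_b) %in% cond)) {
    stop_field("condition", sprintf(
      "conditions '%s' and '%s' must both be present", cond_a, cond_b))
  }
  tt <- dplyr::pull(data, !!tq)
  yy <- dplyr::pull(data, !!vq)
  ma <- timepoint_means(tt[cond == cond_a], yy[cond == cond_a])
  mb <- timepoint_means(tt[cond == cond_b], yy[cond == cond_b])
  unmatched <- c(setdiff(ma$t, mb$t), setdiff(mb$t, ma$t))
  if (length(unmatched) > 0L) {
    stop_rf(sprintf(
      "conditions are not on the same time grid; unmatched timepoints: %s",
      paste(format(sort(unmatched)), collapse = ", ")),
      "rhythmfit_grid_mismatch", timepoints = sort(unmatched))
  }
  list(t = ma$t, a = ma$y, b = mb$y)
}

# Internal: the seeded coin-flip matrix shared by hybrid_resample() and
# mesor_null_test(). Stream order is iteration-major: iteration i consumes
# draws (i-1)*T+1 .. i*T, so the two functions agree for equal seeds.
hybrid_flips <- function(n_iter, n_t, seed) {
  set.seed(seed)
  matrix(runif(n_iter * n_t) < 0.5, nrow = n_iter, ncol = n_t, byrow = TRUE)
}

#' Condition-shuffled hybrid time series
#'
#' Builds randomized hybrid series from a two-condition experiment: at each
#' timepoint, independently with probability 1/2, the hybrid takes the
#' per-timepoint replicate mean of condition `cond_a` or of `cond_b`. These
#' hybrids form the null ensemble for the MESOR randomization test.
#'
#' @param data Long data frame with condition, time and value columns.
#' @param cond_a,cond_b Labels of the two conditions.
#' @param n_iter Number of hybrid series.
#' @param seed Integer seed; the coin-flip stream is iteration-major, so
#'   results are reproducible across machines.
#' @param condition,time,value Tidy-eval column names (defaults
#'   `condition`, `zt_hours`, `value`).
#' @return A tibble with columns `iteration`, `zt_hours`, `value`,
#'   `from_a` (logical: measurement taken from `cond_a`).
#' @examples
#' sim <- simulate_two_conditions(rhythm_sim_spec(), condition_effect(0.3))
#' hy <- hybrid_resample(sim, "A", "B", n_iter = 5, seed = 1)
#' @export
hybrid_resample <- function(data, cond_a, cond_b, n_iter = 1000, seed = 1L,
                            condition = condition, time = zt_hours,
                            value = value) {
  n_iter <- check_count(n_iter, "n_iter")
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  cm <- condition_means(data, cond_a, cond_b, {{ condition }}, {{ time }},
                        {{ value }})
  n_t <- length(cm$t)
  flips <- hybrid_flips(n_iter, n_t, seed)
  vals <- ifelse(flips, rep(cm$a, each = n_iter), rep(cm$b, each = n_iter))
  tibble(
    iteration = rep(seq_len(n_iter), times = n_t),
    zt_hours = rep(cm$t, each = n_iter),
    value = as.numeric(vals),
    from_a = as.logical(flips)
  ) |>
    dplyr::arrange(.data$iteration, .data$zt_hours)
}

#' MESOR randomization test for a condition effect
#'
#' Tests whether two conditions differ in rhythm-adjusted mean expression.
#' The damped sinusoid is fitted to each condition's per-timepoint means
#' and to `n_iter` condition-shuffled hybrid series (each hybrid takes, at
#' every timepoint independently, one condition's mean with probability
#' 1/2). The hybrid MESORs form an approximately normal null distribution;
#' a real condition effect places the two observed MESORs at its opposite
#' extremes. Hybrid fits are initialized at the pooled-data best fit (the
#' fit to the two conditions' averaged means), with a 3-start multi-start
#' fallback on divergence; non-convergent fits are excluded and counted.
#'
#' Empirical p-values use the add-one rule, one-sided per condition with
#' the side set by the observed MESOR's position relative to the null mean:
#' for an observed MESOR below the null mean,
#' `p = (1 + #\{null <= observed\}) / (n_converged + 1)`, and symmetrically
#' above. The observed fits never enter the null distribution and p is
#' always positive.
#'
#' @inheritParams hybrid_resample
#' @param max_failed_frac Error out if more than this fraction of hybrid
#'   fits diverge.
#' @return An object of class `mesor_randomization` with elements
#'   `null_mesors`, `n_failed`, `mesor_a`, `mesor_b`, `p_a`, `p_b`,
#'   `fit_a`, `fit_b`, `fit_pooled`, `summary` (mean, sd, quantiles of the
#'   null), plus the call settings.
#' @examples
#' sim <- simulate_two_conditions(
#'   rhythm_sim_spec(seed = 7), condition_effect(delta_mesor = 0.2),
#'   cond_a = "VEH", cond_b = "CORT"
#' )
#' rt <- mesor_null_test(sim, "VEH", "CORT", n_iter = 50, seed = 7)
#' tidy(rt)
#' @export
mesor_null_test <- function(data, cond_a, cond_b, n_iter = 1000, seed = 1L,
                            condition = condition, time = zt_hours,
                            value = value, max_failed_frac = 0.2) {
  n_iter <- check_count(n_iter, "n_iter")
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  cm <- condition_means(data, cond_a, cond_b, {{ condition }}, {{ time }},
                        {{ value }})
  n_t <- length(cm$t)

  df_a <- tibble(zt_hours = cm$t, value = cm$a)
  df_b <- tibble(zt_hours = cm$t, value = cm$b)
  df_pool <- tibble(zt_hours = cm$t, value = (cm$a + cm$b) / 2)
  fit_a <- fit_sinusoid(df_a)
  fit_b <- fit_sinusoid(df_b)
  fit_pooled <- fit_sinusoid(df_pool)
  init <- unlist(fit_pooled$params)

  flips <- hybrid_flips(n_iter, n_t, seed)
  null_mesors <- rep(NA_real_, n_iter)
  start_grid <- default_start_grid(120)
  for (i in seq_len(n_iter)) {
    y <- ifelse(flips[i, ], cm$a, cm$b)
    res <- fit_damped_core(cm$t, y, list(unname(init)))
    if (is.null(res$best)) {
      grid3 <- screen_starts(cm$t, y, start_grid, 3L)
      res <- fit_damped_core(cm$t, y, grid3)
    }
    if (!is.null(res$best)) {
      null_mesors[i] <- canonicalize_sinusoid(
        setNames(as.list(res$best$par), c("m", "a", "b", "c", "d")))$m
    }
  }
  n_failed <- sum(is.na(null_mesors))
  if (n_failed > max_failed_frac * n_iter) {
    stop_rf(sprintf(
      "%d of %d hybrid fits diverged (> %.0f%%); null distribution unusable",
      n_failed, n_iter, 100 * max_failed_frac),
      "rhythmfit_hybrid_divergence")
  }
  null_mesors <- null_mesors[!is.na(null_mesors)]
  nc <- length(null_mesors)
  null_mean <- mean(null_mesors)

  # extremity counts use a small tolerance so that a degenerate null
  # (identical conditions) counts the observed MESOR as tied, not beyond
  emp_p <- function(obs) {
    tol <- 1e-8 * max(abs(obs), abs(null_mean), 1)
    if (obs <= null_mean) {
      (1 + sum(null_mesors <= obs + tol)) / (nc + 1)
    } else {
      (1 + sum(null_mesors >= obs - tol)) / (nc + 1)
    }
  }
  mesor_a <- fit_a$params$m
  mesor_b <- fit_b$params$m

  structure(
    list(
      null_mesors = null_mesors, n_failed = n_failed, n_iter = n_iter,
      mesor_a = mesor_a, mesor_b = mesor_b,
      p_a = emp_p(mesor_a), p_b = emp_p(mesor_b),
      cond_a = cond_a, cond_b = cond_b, seed = seed,
      fit_a = fit_a, fit_b = fit_b, fit_pooled = fit_pooled,
      summary = list(
        mean = null_mean, sd = if (nc > 1) sd(null_mesors) else 0,
        quantiles = quantile(null_mesors,
                             c(0.025, 0.25, 0.5, 0.75, 0.975))
      )
    ),
    class = "mesor_randomization"
  )
}

#' @export
print.mesor_randomization <- function(x, ...) {
  cat("<mesor_randomization>\n")
  cat(sprintf("  %d hybrid series (%d converged, %d failed), seed %d\n",
              x$n_iter, length(x$null_mesors), x$n_failed, x$seed))
  cat(sprintf("  null MESOR: mean %.4g, sd %.4g\n",
              x$summary$mean, x$summary$sd))
  cat(sprintf("  %s MESOR %.4g (p = %.4g); %s MESOR %.4g (p = %.4g)\n",
              x$cond_a, x$mesor_a, x$p_a, x$cond_b, x$mesor_b, x$p_b))
  invisible(x)
}

#' @rdname mesor_null_test
#' @param x,object A `mesor_randomization`.
#' @param ... Unused.
#' @export
tidy.mesor_randomization <- function(x, ...) {
  tibble(
    condition = c(x$cond_a, x$cond_b),
    mesor = c(x$mesor_a, x$mesor_b),
    side = ifelse(c(x$mesor_a, x$mesor_b) <= x$summary$mean,
                  "lower", "upper"),
    p_value = c(x$p_a, x$p_b)
  )
}

#' @rdname mesor_null_test
#' @export
glance.mesor_randomization <- function(x, ...) {
  tibble(
    n_iter = x$n_iter, n_converged = length(x$null_mesors),
    n_failed = x$n_failed, null_mean = x$summary$mean,
    null_sd = x$summary$sd, p_a = x$p_a, p_b = x$p_b
  )
}

#' @rdname mesor_null_test
#' @export
autoplot.mesor_randomization <- function(object, ...) {
  df <- tibble(mesor = object$null_mesors)
  obs <- tibble(
    mesor = c(object$mesor_a, object$mesor_b),
    condition = c(object$cond_a, object$cond_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mesor)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      data = obs,
      ggplot2::aes(xintercept = .data$mesor, colour = .data$condition),
      linewidth = 1
    ) +
    ggplot2::labs(x = "MESOR of randomized hybrid series", y = "Count",
                  colour = NULL,
                  title = "Null MESOR distribution with observed conditions") +
    ggplot2::theme_minimal()
}

#' Paired t-test across timepoints
#'
#' Two-sided paired t-test of per-timepoint replicate means, pairing the two
#' conditions at each shared timepoint (`n_timepoints - 1` degrees of
#' freedom). `mean_diff` is `cond_b - cond_a`. A zero variance of the
#' differences is reported as an exact tie (`exact_tie = TRUE`): identical
#' series give `t = 0, p = 1`; a constant nonzero offset gives `t = +/-Inf,
#' p = 0` (the continuous limit).
#'
#' @inheritParams hybrid_resample
#' @return A tibble with `t_stat`, `df`, `p_value`, `mean_diff`,
#'   `n_timepoints`, `exact_tie`.
#' @examples
#' sim <- simulate_two_conditions(rhythm_sim_spec(), condition_effect(0.5))
#' paired_timepoint_test(sim, "A", "B")
#' @export
paired_timepoint_test <- function(data, cond_a, cond_b,
                                  condition = condition, time = zt_hours,
                                  value = value) {
  cm <- condition_means(data, cond_a, cond_b, {{ condition }}, {{ time }},
                        {{ value }})
  n <- length(cm$t)
  if (n < 2L) stop_rf("paired test needs at least 2 shared timepoints",
                      "rhythmfit_too_few_timepoints")
  d <- cm$b - cm$a
  md <- mean(d)
  s <- sd(d)
  # exact-tie detection up to floating-point noise in the differences
  if (s <= 1e-12 * max(abs(md), max(abs(d)), 1)) {
    if (md == 0) {
      return(tibble(t_stat = 0, df = n - 1L, p_value = 1, mean_diff = 0,
                    n_timepoints = n, exact_tie = TRUE))
    }
    return(tibble(t_stat = sign(md) * Inf, df = n - 1L, p_value = 0,
                  mean_diff = md, n_timepoints = n, exact_tie = TRUE))
  }
  tstat <- md / (s / sqrt(n))
  tibble(
    t_stat = tstat, df = n - 1L,
    p_value = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE),
    mean_diff = md, n_timepoints = n, exact_tie = FALSE
  )
}
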