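test_that("damped_sinusoid matches closed forms and hand arithmetic", {
  expect_equal(damped_sinusoid(5, m = 2, a = 0, b = 1, c = 1, d = 0), 2)
  expect_equal(damped_sinusoid(1, m = 2, a = 1, b = 0, c = pi / 2, d = 0), 3)
  # term-by-term: m=1, a=0.5, b=0.1, c=2*pi/9.5, d=-0.5, t=0:
  # exp(0) = 1; sin(c * 0.5) with c = 0.66138793...; value = 1 + 0.5*sin(0.33069...)
  hand <- 1 + 0.5 * 1 * sin((2 * pi / 9.5) * (0 - (-0.5)))
  expect_equal(
    damped_sinusoid(0, m = 1, a = 0.5, b = 0.1, c = 2 * pi / 9.5, d = -0.5),
    hand
  )
  # list form agrees with argument form
  p <- list(m = 1, a = 0.5, b = 0.1, c = 2 * pi / 9.5, d = -0.5)
  expect_equal(damped_sinusoid(c(-2, 0, 3), p),
               damped_sinusoid(c(-2, 0, 3), 1, 0.5, 0.1, 2 * pi / 9.5, -0.5))
})

test_that("canonicalization preserves the curve and lands in canonical form", {
  # sign-phase symmetry: a = -1, c = pi -> a = 1, d shifted by pi/c = 1
  p1 <- canonicalize_sinusoid(list(m = 0, a = -1, b = 0.2, c = pi, d = 0))
  expect_equal(p1$a, 1)
  expect_equal(p1$d, 1)
  # modulo period: period 2, d = 5 -> 1
  p2 <- canonicalize_sinusoid(list(m = 0, a = 1, b = 0, c = pi, d = 5))
  expect_equal(p2$d, 1)
  expect_error(canonicalize_sinusoid(list(m = 0, a = 1, b = 0, c = 0, d = 0)),
               class = "rhythmfit_zero_frequency")

  set.seed(11)
  tgrid <- seq(-4, 6, length.out = 201)
  for (i in 1:100) {
    p <- list(m = runif(1, -2, 2), a = runif(1, -3, 3), b = runif(1, 0, 0.5),
              c = runif(1, 0.3, 3) * sample(c(-1, 1), 1),
              d = runif(1, -20, 20))
    pc <- canonicalize_sinusoid(p)
    expect_gte(pc$a, 0)
    expect_gt(pc$c, 0)
    expect_true(pc$d >= 0 && pc$d < 2 * pi / pc$c)
    expect_lt(max(abs(damped_sinusoid(tgrid, p) - damped_sinusoid(tgrid, pc))),
              1e-9)
  }
})

test_that("noiseless data are recovered exactly over canonical draws", {
  set.seed(21)
  for (i in 1:8) {
    true <- list(m = runif(1, 0.5, 3), a = runif(1, 0.2, 1.5),
                 b = runif(1, 0, 0.3), c = 2 * pi / runif(1, 5, 12), d = 0)
    true$d <- runif(1, 0, 2 * pi / true$c)
    period <- 2 * pi / true$c
    tt <- seq(-4, -4 + 2.2 * period, length.out = 45)  # > 2 periods
    df <- tibble::tibble(zt_hours = tt,
                         value = oracle_curve(tt, true$m, true$a, true$b,
                                              true$c, true$d))
    fit <- fit_sinusoid(df)
    rel <- abs(unlist(fit$params) - unlist(true)) /
      pmax(abs(unlist(true)), 1e-8)
    expect_lt(max(rel), 1e-6)
    expect_lt(fit$sse, 1e-12)
    expect_true(fit$converged)
  }
})

test_that("flat data yield a near-zero amplitude and the data mean", {
  df <- tibble::tibble(zt_hours = seq(-4, 6, by = 0.5), value = 3.7)
  fit <- fit_sinusoid(df)
  expect_lt(fit$params$a, 1e-6)
  expect_equal(fit$params$m, 3.7, tolerance = 1e-8)
})

test_that("replicate means are the default fitting target", {
  spec <- study_spec(seed = 6)
  tc <- simulate_timecourse(spec)
  means <- dplyr::summarise(tc, value = mean(value), .by = zt_hours)
  fit_raw <- fit_sinusoid(tc)
  fit_means <- fit_sinusoid(means)
  expect_equal(unlist(fit_raw$params), unlist(fit_means$params),
               tolerance = 1e-9)
  expect_equal(fit_raw$n, 41)
})

test_that("fitting errors are informative", {
  expect_error(
    fit_sinusoid(tibble::tibble(zt_hours = 1:5, value = rnorm(5))),
    "6 distinct timepoints", class = "rhythmfit_too_few_timepoints"
  )
  expect_error(
    fit_sinusoid(tibble::tibble(zt_hours = 1:10,
                                value = c(rnorm(9), NA))),
    class = "rhythmfit_validation_error"
  )
})

test_that("model ANOVA matches hand arithmetic and the F distribution", {
  # F = ((10 - 2)/4) / (2/36) = 36 for n = 41
  an <- rhythmfit:::anova_from_sse(sse_null = 10, sse_model = 2, n = 41)
  expect_equal(an$f_stat, 36)
  # independent route: P(F > f) = pbeta(d2 / (d2 + d1 f), d2/2, d1/2)
  p_ind <- pbeta(36 / (36 + 4 * 36), 18, 2)
  expect_equal(an$p_value, p_ind, tolerance = 1e-10)
  expect_equal(an$p_value, 4.0370176e-12, tolerance = 1e-6)

  # model adds nothing -> F = 0, p = 1
  an0 <- rhythmfit:::anova_from_sse(5, 5, 41)
  expect_equal(an0$f_stat, 0)
  expect_equal(an0$p_value, 1)

  # exact fit flagged with p = 0
  spec <- study_spec(noise_cv = 0)
  fit <- fit_sinusoid(simulate_timecourse(spec))
  av <- model_anova(fit)
  expect_true(av$exact_fit)
  expect_equal(av$p_value, 0)
})

test_that("model ANOVA is approximately calibrated on flat-data null", {
  # Frequency and phase are estimated before the 4-df test, which makes the
  # F reference mildly anti-conservative; rejection should still sit near
  # the nominal 5% level.
  set.seed(7)
  t <- seq(-4, 6, by = 0.25)
  ps <- vapply(1:300, function(i) {
    y <- rnorm(41, 1, 0.06)
    suppressWarnings(
      fit_sinusoid(tibble::tibble(zt_hours = t, value = y))
    )$p_value
  }, numeric(1))
  rej <- mean(ps <= 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.12)
})

test_that("rhythm metrics give the analytic stationary points", {
  # undamped: peak at quarter period, nadir at three-quarter period
  rm0 <- rhythm_metrics(list(m = 1, a = 1, b = 0, c = 2 * pi / 24, d = 0),
                        window = c(0, 24))
  expect_equal(rm0$peak_time, 6)
  expect_equal(rm0$nadir_time, 18)
  expect_equal(rm0$peak_to_nadir, 12)
  expect_equal(rm0$period, 24)

  # period is definitional
  rm1 <- rhythm_metrics(list(m = 1, a = 1, b = 0, c = 2 * pi / 9.5, d = 0),
                        window = c(-4, 6))
  expect_equal(rm1$period, 9.5)

  # damped case against the dense-grid oracle
  p <- list(m = 1, a = 0.5, b = 0.1, c = 2 * pi / 9.5, d = 0)
  rm2 <- rhythm_metrics(p, window = c(-4, 6))
  gr <- oracle_grid_extrema(p$m, p$a, p$b, p$c, p$d, c(-4, 6))
  expect_lt(abs(rm2$peak_time - gr$argmax), 1e-3)
  # first nadir after the peak: dense grid over one period past the peak
  grn <- oracle_grid_extrema(p$m, p$a, p$b, p$c, p$d,
                             c(rm2$peak_time, rm2$peak_time + rm2$period))
  expect_lt(abs(rm2$nadir_time - grn$argmin), 1e-3)

  expect_error(rhythm_metrics(p, window = c(0, 5)),
               class = "rhythmfit_window_too_short")
})

test_that("tidy, glance and autoplot work on fits", {
  fit <- fit_sinusoid(simulate_timecourse(study_spec(noise_cv = 0)))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(gl$period_hours, 9.5, tolerance = 1e-6)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("fit JSON export carries the documented keys", {
  fit <- fit_sinusoid(simulate_timecourse(study_spec(seed = 4)))
  path <- withr::local_tempfile(fileext = ".json")
  out <- write_fit_json(fit, path)
  got <- jsonlite::read_json(path)
  expect_setequal(
    names(got),
    c("m", "a", "b", "c", "d", "period_hours", "peak_time_zt",
      "nadir_time_zt", "sse", "f_stat", "p_value", "converged")
  )
  expect_equal(got$m, fit$params$m)
})
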