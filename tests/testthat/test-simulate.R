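test_that("zero-noise simulation reproduces the model curve exactly", {
  spec <- study_spec(noise_cv = 0)
  tc <- simulate_timecourse(spec)
  mu <- oracle_curve(tc$zt_hours, 1, 0.5, 0.05, 2 * pi / 9.5, 0)
  expect_equal(tc$value, mu, tolerance = 0)
  expect_equal(nrow(tc), 41 * 3)
  expect_equal(length(unique(tc$zt_hours)), 41)

  flat <- simulate_timecourse(rhythm_sim_spec(mesor = 2, amplitude = 0,
                                              noise_cv = 0))
  expect_true(all(flat$value == 2))
})

test_that("lognormal noise has the stated mean and CV law", {
  # fixed-seed check of the spec'd example: per-timepoint replicate means
  # within 3 * CV / sqrt(3) of the curve at >= 95% of the 41 timepoints
  spec <- rhythm_sim_spec(mesor = 1, amplitude = 0.5, decay_rate = 0.05,
                          period_hours = 9.5, phase_shift = 0,
                          noise_cv = 0.1, seed = 1)
  tc <- simulate_timecourse(spec)
  mu <- oracle_curve(unique(tc$zt_hours), 1, 0.5, 0.05, 2 * pi / 9.5, 0)
  means <- tapply(tc$value, tc$zt_hours, mean)
  within <- abs(means - mu) <= 3 * 0.1 * mu / sqrt(3)
  expect_gte(mean(within), 0.95)

  # sample CV converges to noise_cv with many replicates
  big <- rhythm_sim_spec(t_start = 0, t_end = 1, dt = 0.5,
                         n_replicates = 10000, noise_cv = 0.1, seed = 2)
  tcb <- simulate_timecourse(big)
  cvs <- tapply(tcb$value, tcb$zt_hours,
                function(v) sd(v) / mean(v))
  expect_true(all(abs(cvs - 0.1) < 0.005))

  # linear-scale mean is unbiased (lognormal correction term)
  mub <- oracle_curve(unique(tcb$zt_hours), 1, 0.5, 0.05, 2 * pi / 9.5, 0)
  means_b <- tapply(tcb$value, tcb$zt_hours, mean)
  expect_true(all(abs(means_b / mub - 1) < 4 * 0.1 / sqrt(10000) * 3))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  spec <- study_spec(seed = 42)
  expect_identical(simulate_timecourse(spec), simulate_timecourse(spec))
  eff <- condition_effect(0.3, 0.5, 0.9)
  expect_identical(
    simulate_two_conditions(spec, eff, seed = 9),
    simulate_two_conditions(spec, eff, seed = 9)
  )
  ospec <- ocr_sim_spec(seed = 5)
  expect_identical(simulate_ocr(ospec), simulate_ocr(ospec))
})

test_that("condition effects shift MESOR, phase and amplitude as stated", {
  spec <- study_spec(noise_cv = 0)
  # pure MESOR shift: B - A = delta everywhere
  sim <- simulate_two_conditions(spec, condition_effect(delta_mesor = 0.5))
  a <- sim$value[sim$condition == "A"]
  b <- sim$value[sim$condition == "B"]
  expect_equal(b - a, rep(0.5, length(a)), tolerance = 1e-12)

  # 35-min phase delay moves the curve's argmax by 0.58 h (dense-grid oracle)
  delay <- 35 / 60
  sim2 <- simulate_two_conditions(spec,
                                  condition_effect(delta_phase = delay))
  peak_a <- oracle_grid_extrema(1, 0.5, 0.05, 2 * pi / 9.5, 0,
                                c(-4, 6), step = 1e-4)$argmax
  peak_b <- oracle_grid_extrema(1, 0.5, 0.05, 2 * pi / 9.5, delay,
                                c(-4, 6), step = 1e-4)$argmax
  expect_equal(peak_b - peak_a, delay, tolerance = 1e-3)
  mb <- tapply(sim2$value[sim2$condition == "B"],
               sim2$zt_hours[sim2$condition == "B"], mean)
  curve_b <- oracle_curve(as.numeric(names(mb)), 1, 0.5, 0.05,
                          2 * pi / 9.5, delay)
  expect_equal(as.numeric(mb), curve_b, tolerance = 1e-12)

  # null effect: same time grid and replicate count, different draws
  sim3 <- simulate_two_conditions(study_spec(), condition_effect())
  expect_identical(unique(sim3$zt_hours[sim3$condition == "A"]),
                   unique(sim3$zt_hours[sim3$condition == "B"]))
})

test_that("OCR simulation matches its linear law and OLS sampling theory", {
  exact <- simulate_ocr(ocr_sim_spec(intercept = 3, slope = 0.5,
                                     noise_sd = 0, n_wells = 1, dt = 1))
  expect_equal(exact$ocr, 3 + 0.5 * exact$t_minutes, tolerance = 1e-12)

  const <- simulate_ocr(ocr_sim_spec(intercept = 7, slope = 0,
                                     noise_sd = 0, n_wells = 1))
  expect_true(all(const$ocr == 7))

  # mean recovered intercept over 60 wells within 3 closed-form SEs of truth
  spec <- ocr_sim_spec(intercept = 150, slope = -0.2, noise_sd = 1,
                       n_wells = 60, n_timepoints = 12, dt = 8, seed = 3)
  ocr <- simulate_ocr(spec)
  fits <- fit_ocr_line(ocr)
  t1 <- (0:11) * 8
  k <- oracle_ols(t1, rnorm(12), sigma = 1)$se_intercept
  expect_lt(abs(mean(fits$intercept) - 150), 3 * k / sqrt(60))
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(rhythm_sim_spec(amplitude = -1), "amplitude",
               class = "rhythmfit_validation_error")
  expect_error(rhythm_sim_spec(decay_rate = -0.1), "decay_rate",
               class = "rhythmfit_validation_error")
  expect_error(rhythm_sim_spec(dt = 0), "dt",
               class = "rhythmfit_validation_error")
  expect_error(rhythm_sim_spec(n_replicates = 0), "n_replicates",
               class = "rhythmfit_validation_error")
  expect_error(rhythm_sim_spec(noise_cv = -0.2), "noise_cv",
               class = "rhythmfit_validation_error")
  expect_error(condition_effect(amplitude_scale = -2), "amplitude_scale",
               class = "rhythmfit_validation_error")
  expect_error(ocr_sim_spec(n_timepoints = 2), "n_timepoints",
               class = "rhythmfit_validation_error")
  # lognormal noise needs a positive curve
  expect_error(
    simulate_timecourse(rhythm_sim_spec(mesor = 0.2, amplitude = 0.5)),
    "positive", class = "rhythmfit_validation_error"
  )
})

test_that("sim specs round-trip losslessly through YAML configs", {
  spec <- rhythm_sim_spec(mesor = 1 / 3, amplitude = 0.5,
                          decay_rate = 0.123456789012345,
                          period_hours = 9.5, phase_shift = -0.7,
                          noise_cv = 0.1, seed = 17L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_spec(spec, path)
  expect_identical(read_sim_spec(path), spec)

  ospec <- ocr_sim_spec(intercept = 150.123, slope = -1 / 7, seed = 3L)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_sim_spec(ospec, path2)
  expect_identical(read_sim_spec(path2), ospec)
})

test_that("time-course and OCR tables round-trip through CSV", {
  tc <- simulate_timecourse(study_spec(), gene = "klf9", condition = "VEH")
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  back <- read_timecourse(path)
  expect_equal(as.data.frame(back), as.data.frame(tc))

  ocr <- simulate_ocr(ocr_sim_spec(n_wells = 2))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_ocr(ocr, path2)
  expect_equal(as.data.frame(read_ocr(path2)), as.data.frame(ocr))

  expect_error(read_timecourse(path2), class = "rhythmfit_validation_error")
})
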