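tc_cols <- c("gene", "condition", "zt_hours", "replicate", "value")
ocr_cols <- c("well", "genotype", "treatment", "t_minutes", "ocr")

#' Read and write long-format time-course tables
#'
#' CSV with columns `gene`, `condition`, `zt_hours`, `replicate`, `value`
#' (one row per measurement), the format produced by
#' [simulate_timecourse()] and consumed by [fit_sinusoid()] and
#' [mesor_null_test()].
#'
#' @param path File path.
#' @param data Data frame to write.
#' @return `read_timecourse()` returns a tibble; `write_timecourse()`
#'   returns `data` invisibly.
#' @export
read_timecourse <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(out, tc_cols, "time-course CSV")
  out
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(data, path) {
  check_columns(data, tc_cols, "time-course data")
  readr::write_csv(data, path)
  invisible(data)
}

#' Read and write OCR series tables
#'
#' CSV with columns `well`, `genotype`, `treatment`, `t_minutes`, `ocr`.
#'
#' @inheritParams read_timecourse
#' @export
read_ocr <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(out, ocr_cols, "OCR CSV")
  out
}

#' @rdname read_ocr
#' @export
write_ocr <- function(data, path) {
  check_columns(data, ocr_cols, "OCR data")
  readr::write_csv(data, path)
  invisible(data)
}

#' Write a damped-sinusoid fit as JSON
#'
#' Serializes the fitted constants and fit statistics (keys `m`, `a`, `b`,
#' `c`, `d`, `period_hours`, `peak_time_zt`, `nadir_time_zt`, `sse`,
#' `f_stat`, `p_value`, `converged`).
#'
#' @param fit A `cosinor_fit`.
#' @param path Output path.
#' @param window Metrics window in hours; defaults to the fitted data range
#'   widened to one period if needed.
#' @return The list written, invisibly.
#' @export
write_fit_json <- function(fit, path, window = NULL) {
  stopifnot(inherits(fit, "cosinor_fit"))
  p <- fit$params
  period <- 2 * pi / p$c
  if (is.null(window)) {
    window <- range(fit$data$t)
    if (diff(window) < period) window[2] <- window[1] + period
  }
  metrics <- tryCatch(rhythm_metrics(fit, window), error = function(e) NULL)
  out <- list(
    m = p$m, a = p$a, b = p$b, c = p$c, d = p$d,
    period_hours = period,
    peak_time_zt = if (is.null(metrics)) NA else metrics$peak_time,
    nadir_time_zt = if (is.null(metrics)) NA else metrics$nadir_time,
    sse = fit$sse, f_stat = fit$f_stat, p_value = fit$p_value,
    converged = fit$converged
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}

#' Write a MESOR randomization result as JSON
#'
#' Includes the full null MESOR vector so the null histogram can be
#' re-plotted, plus the observed MESORs and empirical p-values.
#'
#' @param result A `mesor_randomization`.
#' @param path Output path.
#' @return The list written, invisibly.
#' @export
write_randomization_json <- function(result, path) {
  stopifnot(inherits(result, "mesor_randomization"))
  out <- list(
    cond_a = result$cond_a, cond_b = result$cond_b,
    mesor_a = result$mesor_a, mesor_b = result$mesor_b,
    p_a = result$p_a, p_b = result$p_b,
    n_iter = result$n_iter, n_failed = result$n_failed,
    seed = result$seed,
    null_mean = result$summary$mean, null_sd = result$summary$sd,
    null_mesors = result$null_mesors
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}

# Numeric fields survive YAML via 17-significant-digit strings, so a write
# followed by a read reproduces the spec bit-for-bit.
num_out <- function(x) sprintf("%.17g", x)

#' Save and restore simulation specs as YAML
#'
#' Round-trips a [rhythm_sim_spec()] or [ocr_sim_spec()] through a YAML
#' config file losslessly (numeric fields are stored at full double
#' precision).
#'
#' @param spec A `rhythm_sim_spec` or `ocr_sim_spec`.
#' @param path File path.
#' @return `write_sim_spec()` returns `spec` invisibly; `read_sim_spec()`
#'   returns the re-validated spec object.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_sim_spec(rhythm_sim_spec(mesor = 1/3), path)
#' read_sim_spec(path)$mesor == 1/3
#' @export
write_sim_spec <- function(spec, path) {
  kind <- if (inherits(spec, "rhythm_sim_spec")) "rhythm" else
    if (inherits(spec, "ocr_sim_spec")) "ocr" else
      stop_field("spec", "must be a rhythm_sim_spec or ocr_sim_spec")
  vals <- unclass(spec)
  out <- lapply(vals, function(v) if (is.numeric(v)) num_out(v) else v)
  out <- c(list(kind = kind), out)
  yaml::write_yaml(out, path)
  invisible(spec)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  kind <- raw$kind %||% stop_field("kind", "config lacks a 'kind' field")
  raw$kind <- NULL
  num <- function(x) as.numeric(x)
  if (kind == "rhythm") {
    rhythm_sim_spec(
      mesor = num(raw$mesor), amplitude = num(raw$amplitude),
      decay_rate = num(raw$decay_rate),
      angular_frequency = num(raw$angular_frequency),
      phase_shift = num(raw$phase_shift),
      t_start = num(raw$t_start), t_end = num(raw$t_end),
      dt = num(raw$dt), n_replicates = num(raw$n_replicates),
      noise_cv = num(raw$noise_cv), noise_model = raw$noise_model,
      seed = num(raw$seed)
    )
  } else if (kind == "ocr") {
    ocr_sim_spec(
      intercept = num(raw$intercept), slope = num(raw$slope),
      n_timepoints = num(raw$n_timepoints), dt = num(raw$dt),
      n_wells = num(raw$n_wells), noise_sd = num(raw$noise_sd),
      seed = num(raw$seed)
    )
  } else {
    stop_field("kind", sprintf("unknown config kind '%s'", kind))
  }
}
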