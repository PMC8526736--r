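#' Signal a validation error that names the offending field
#'
#' @param field Name of the invalid field or column.
#' @param msg Human-readable description of the violation.
#' @noRd
stop_field <- function(field, msg) {
  abort(
    message = sprintf("Invalid `%s`: %s", field, msg),
    class = c("rhythmfit_validation_error", "rhythmfit_error"),
    field = field
  )
}

stop_rf <- function(msg, class, ...) {
  abort(message = msg, class = c(class, "rhythmfit_error"), ...)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_field(field, sprintf(
      "must be in %s%s, %s%s but is %g",
      if (allow_lower) "[" else "(", format(lower),
      format(upper), if (allow_upper) "]" else ")", x
    ))
  }
  invisible(x)
}

check_count <- function(x, field, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    stop_field(field, "must be a single whole number")
  }
  if (x < lower) stop_field(field, sprintf("must be >= %d", lower))
  invisible(as.integer(x))
}

check_columns <- function(data, cols, what = "data") {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop_field(missing_cols[1L],
               sprintf("column missing from %s (needs %s)",
                       what, paste(cols, collapse = ", ")))
  }
  invisible(data)
}

#' Sidak multiple-comparison adjustment
#'
#' Adjusts p-values for `k` comparisons with `p_adj = 1 - (1 - p)^k`.
#' With `k = 1` the adjustment is the identity; adjusted values are clamped
#' to (0, 1] and are never smaller than the input.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param k Number of comparisons in the family (default: `length(p)`).
#' @return Numeric vector of adjusted p-values.
#' @examples
#' sidak_adjust(c(0.01, 0.04), k = 2)
#' @export
sidak_adjust <- function(p, k = length(p)) {
  if (!is.numeric(p) || any(!is.na(p) & (p < 0 | p > 1))) {
    stop_field("p", "p-values must lie in [0, 1]")
  }
  check_count(k, "k")
  # 1 - (1 - p)^k computed as -expm1(k * log1p(-p)) so tiny p do not
  # underflow to an adjusted p of exactly 0
  out <- ifelse(p >= 1, 1, -expm1(k * log1p(-p)))
  pmin(1, out)
}

# Collapse replicate values to per-timepoint means; returns sorted tibble(t, y)
timepoint_means <- function(t, y) {
  keep <- is.finite(t) & is.finite(y)
  if (!all(keep)) stop_field("value", "all times and values must be finite")
  agg <- tapply(y, t, mean)
  tt <- as.numeric(names(agg))
  ord <- order(tt)
  tibble(t = tt[ord], y = as.numeric(agg)[ord])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
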