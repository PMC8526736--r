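#' Drop the first measurement of each OCR series
#'
#' The first measurement cycle of an extracellular-flux run is typically
#' inconsistent and is excluded before analysis. The earliest timepoint of
#' each well's series is removed; by default times are then rebased so that
#' `t = 0` is the first retained measurement (the fitted intercept then
#' means "basal rate at run start after exclusion").
#'
#' @param data Data frame with time and value columns, one series per well.
#' @param time,value Tidy-eval column names (defaults `t_minutes`, `ocr`).
#' @param well Character vector of columns that identify one series
#'   (default: whichever of `well`, `genotype`, `treatment` are present);
#'   use `character(0)` to treat the whole table as a single series.
#' @param rebase_time Shift each series so the first retained time is 0.
#' @return The data frame minus one row per series.
#' @examples
#' ocr <- simulate_ocr(ocr_sim_spec(n_wells = 2))
#' nrow(ocr) - nrow(exclude_first_point(ocr))  # 2
#' @export
exclude_first_point <- function(data, time = t_minutes, value = ocr,
                                well = NULL, rebase_time = TRUE) {
  tq <- enquo(time)
  by <- well %||% intersect(c("well", "genotype", "treatment"), names(data))
  by <- intersect(by, names(data))
  grouped <- if (length(by) > 0L) {
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by)))
  } else {
    data
  }
  out <- grouped |>
    dplyr::group_modify(function(df, key) {
      tt <- dplyr::pull(df, !!tq)
      if (length(tt) < 4L) {
        stop_rf("each series needs >= 4 points before exclusion",
                "rhythmfit_too_few_timepoints")
      }
      if (anyDuplicated(tt)) {
        stop_field(as_name(tq), "times must be unique within a series")
      }
      df <- df[order(tt), , drop = FALSE][-1L, , drop = FALSE]
      if (rebase_time) {
        df <- dplyr::mutate(df, !!as_name(tq) := !!tq - min(!!tq))
      }
      df
    }) |>
    dplyr::ungroup()
  # group_modify moves the key column first; restore the input order
  dplyr::select(out, dplyr::all_of(names(data)))
}

#' Ordinary least-squares line fits for OCR series
#'
#' Fits `ocr = intercept + slope * t` per series, returning the slope (rate
#' of change of OCR over time), the Y-intercept (indicative of basal
#' metabolic rate) and their standard errors from the closed-form OLS
#' solution.
#'
#' @inheritParams exclude_first_point
#' @param by Character vector of grouping columns (default `"well"` when
#'   present, plus any of `genotype`/`treatment` present); use `NULL` to
#'   fit one line to the whole table.
#' @return A tibble with one row per group: grouping columns, `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `sigma`, `n`.
#' @examples
#' ocr <- simulate_ocr(ocr_sim_spec(noise_sd = 0, n_wells = 1))
#' fit_ocr_line(ocr)
#' @export
fit_ocr_line <- function(data, time = t_minutes, value = ocr, by = NULL) {
  tq <- enquo(time); vq <- enquo(value)
  if (is.null(by)) {
    by <- intersect(c("well", "genotype", "treatment"), names(data))
  }
  by <- intersect(by, names(data))
  one_fit <- function(df) {
    tt <- dplyr::pull(df, !!tq)
    yy <- dplyr::pull(df, !!vq)
    if (length(tt) < 3L) {
      stop_rf("each series needs >= 3 points for a line fit",
              "rhythmfit_too_few_timepoints")
    }
    if (length(unique(tt)) < 2L) {
      stop_field(as_name(tq), "all times equal; slope undefined")
    }
    fit <- lm(yy ~ tt)
    sm <- summary(fit)
    tibble(
      slope = coef(fit)[["tt"]], intercept = coef(fit)[["(Intercept)"]],
      se_slope = sm$coefficients["tt", "Std. Error"],
      se_intercept = sm$coefficients["(Intercept)", "Std. Error"],
      sigma = sm$sigma, n = length(tt)
    )
  }
  if (length(by) == 0L) return(one_fit(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ one_fit(.x)) |>
    dplyr::ungroup()
}

#' Average replicate OCR series within groups
#'
#' Collapses well-level series to the per-timepoint mean within each
#' `genotype` x `treatment` group (the averaged-then-fit path: one line is
#' then fitted to each group's averaged time course).
#'
#' @inheritParams fit_ocr_line
#' @param by Grouping columns (default genotype and treatment).
#' @return A tibble with grouping columns, the time column and the averaged
#'   value column.
#' @export
ocr_average_series <- function(data, time = t_minutes, value = ocr,
                               by = c("genotype", "treatment")) {
  tq <- enquo(time); vq <- enquo(value)
  by <- intersect(by, names(data))
  data |>
    dplyr::summarise(
      !!as_name(vq) := mean(!!vq),
      .by = dplyr::all_of(c(by, as_name(tq)))
    )
}

#' Two-factor comparison of OCR intercepts with Sidak-adjusted contrasts
#'
#' Two-way ANOVA (Type II sums of squares) of replicate-level basal-rate
#' intercepts on genotype, treatment and their interaction, followed by
#' pairwise cell contrasts — each genotype pair within every treatment and
#' each treatment pair within every genotype — adjusted with the Sidak
#' formula `p_adj = 1 - (1 - p)^k`, `k` being the total number of
#' contrasts.
#'
#' @param data Data frame of per-replicate intercepts.
#' @param value Tidy-eval column of intercepts (default `intercept`).
#' @param genotype,treatment Tidy-eval factor columns.
#' @return An object of class `ocr_comparison`: `anova` (tibble: effect,
#'   df, sum_sq, f_stat, p_value), `contrasts` (tibble with raw and
#'   Sidak-adjusted p), and the underlying `model`.
#' @examples
#' fits <- dplyr::bind_rows(
#'   fit_ocr_line(simulate_ocr(ocr_sim_spec(seed = 1), "WT", "VEH")),
#'   fit_ocr_line(simulate_ocr(ocr_sim_spec(seed = 2, intercept = 140),
#'                             "mut", "VEH"))
#' )
#' @export
compare_intercepts <- function(data, value = intercept,
                               genotype = genotype, treatment = treatment) {
  vq <- enquo(value); gq <- enquo(genotype); tq <- enquo(treatment)
  df <- tibble(
    y = dplyr::pull(data, !!vq),
    genotype = factor(dplyr::pull(data, !!gq)),
    treatment = factor(dplyr::pull(data, !!tq))
  )
  cells <- dplyr::count(df, .data$genotype, .data$treatment)
  full_cells <- nlevels(df$genotype) * nlevels(df$treatment)
  if (nrow(cells) < full_cells || any(cells$n < 2L)) {
    stop_rf("every genotype x treatment cell needs >= 2 intercepts",
            "rhythmfit_empty_cell")
  }
  model <- lm(y ~ genotype * treatment, data = df)
  av <- car::Anova(model, type = 2)
  av_tb <- tibble(
    effect = rownames(av), df = av$Df, sum_sq = av$`Sum Sq`,
    f_stat = av$`F value`, p_value = av$`Pr(>F)`
  ) |>
    dplyr::filter(.data$effect != "Residuals")

  emm_g <- emmeans::emmeans(model, ~ genotype | treatment)
  emm_t <- emmeans::emmeans(model, ~ treatment | genotype)
  ct <- dplyr::bind_rows(
    as.data.frame(emmeans::contrast(emm_g, "pairwise", adjust = "none")),
    as.data.frame(emmeans::contrast(emm_t, "pairwise", adjust = "none"))
  )
  names(ct)[2] <- "within"
  ct <- as_tibble(ct)
  ct$p_adj <- sidak_adjust(ct$p.value, k = nrow(ct))
  names(ct)[names(ct) == "p.value"] <- "p_value"

  structure(
    list(anova = av_tb, contrasts = ct, model = model, n_cells = nrow(cells)),
    class = "ocr_comparison"
  )
}

#' @export
print.ocr_comparison <- function(x, ...) {
  cat("<ocr_comparison> two-factor ANOVA of basal-rate intercepts\n")
  print(x$anova)
  cat(sprintf("Pairwise contrasts (Sidak, k = %d):\n", nrow(x$contrasts)))
  print(x$contrasts[c("contrast", "within", "estimate", "p_value", "p_adj")])
  invisible(x)
}

#' @rdname compare_intercepts
#' @param x An `ocr_comparison`.
#' @param ... Unused.
#' @export
tidy.ocr_comparison <- function(x, ...) {
  x$anova
}

#' @rdname compare_intercepts
#' @param object An `ocr_comparison`.
#' @export
glance.ocr_comparison <- function(object, ...) {
  sm <- summary(object$model)
  tibble(
    r_squared = sm$r.squared, sigma = sm$sigma,
    df_residual = object$model$df.residual,
    n = length(object$model$residuals), n_cells = object$n_cells
  )
}
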