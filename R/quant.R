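# Wide count tables: one gene id column, remaining columns are samples.
split_count_table <- function(counts, gene_col) {
  check_columns(counts, gene_col, "count table")
  sample_cols <- setdiff(names(counts), gene_col)
  if (length(sample_cols) == 0L) {
    stop_field("counts", "count table needs at least one sample column")
  }
  mat <- as.matrix(counts[sample_cols])
  if (!is.numeric(mat)) stop_field("counts", "sample columns must be numeric")
  rownames(mat) <- as.character(counts[[gene_col]])
  mat
}

#' Reference-gene normalization of a count table
#'
#' Scales each sample by
#' `(global mean of per-sample reference geometric means) / (that sample's
#' reference geometric mean)`, where the reference summary is the geometric
#' mean over the designated reference genes (the convention of
#' count-panel normalizers such as nSolver). After normalization every
#' sample has the same reference geometric mean, and the operation is
#' idempotent.
#'
#' @param counts Wide data frame: one gene id column (`gene` by default),
#'   remaining columns one sample each, values nonnegative counts.
#' @param reference_genes Character vector of reference gene ids (e.g.
#'   `c("actb2", "rpl13a", "eif5a")`); must be present and strictly
#'   positive in every sample.
#' @param gene_col Name of the gene id column.
#' @return A tibble shaped like `counts` with scaled sample columns and an
#'   attribute `scale_factors` (tibble: sample, ref_geomean, factor).
#' @examples
#' cm <- tibble::tibble(gene = c("ref", "g1"), s1 = c(4, 10), s2 = c(16, 10))
#' normalize_to_references(cm, "ref")
#' @export
normalize_to_references <- function(counts, reference_genes,
                                    gene_col = "gene") {
  mat <- split_count_table(counts, gene_col)
  if (any(mat < 0)) stop_field("counts", "counts must be nonnegative")
  if (length(reference_genes) == 0L) {
    stop_field("reference_genes", "must name at least one gene")
  }
  missing_refs <- setdiff(reference_genes, rownames(mat))
  if (length(missing_refs) > 0L) {
    stop_field("reference_genes", sprintf(
      "not present in the count table: %s",
      paste(missing_refs, collapse = ", ")))
  }
  ref <- mat[reference_genes, , drop = FALSE]
  zero <- which(ref <= 0, arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    stop_field("counts", sprintf(
      "reference gene '%s' has count <= 0 in sample '%s'",
      rownames(ref)[zero[1, 1]], colnames(ref)[zero[1, 2]]))
  }
  geo <- exp(colMeans(log(ref)))
  factors <- mean(geo) / geo
  out <- counts
  for (j in seq_along(factors)) {
    s <- names(factors)[j]
    out[[s]] <- counts[[s]] * factors[[j]]
  }
  out <- as_tibble(out)
  attr(out, "scale_factors") <- tibble(
    sample = names(factors), ref_geomean = unname(geo),
    factor = unname(factors)
  )
  out
}

#' Per-gene Z-scaling of log2 counts
#'
#' For each gene (row): `z = (log2(count) - mean(log2)) / sd(log2)`, with
#' the sample (n - 1) standard deviation, so every row has mean 0 and SD 1.
#' This removes differences in absolute expression level before heat-map
#' rendering. Genes constant across samples (SD 0 on the log scale) are
#' returned as all-zero rows and flagged (attribute `constant_genes`) with
#' a warning, keeping the matrix rectangular.
#'
#' @inheritParams normalize_to_references
#' @return A tibble shaped like `counts` holding Z-scores, with attribute
#'   `constant_genes`.
#' @examples
#' cm <- tibble::tibble(gene = "g1", s1 = 2, s2 = 8)
#' z_scale_by_gene(cm)  # -0.707, +0.707
#' @export
z_scale_by_gene <- function(counts, gene_col = "gene") {
  mat <- split_count_table(counts, gene_col)
  if (any(mat <= 0)) {
    stop_field("counts", "counts must be > 0 for log2 scaling")
  }
  lg <- log2(mat)
  mu <- rowMeans(lg)
  s <- apply(lg, 1L, sd)
  const <- s == 0
  if (any(const)) {
    warn(sprintf("%d constant gene(s) returned as all-zero rows: %s",
                 sum(const),
                 paste(rownames(mat)[const], collapse = ", ")))
  }
  z <- (lg - mu) / ifelse(const, 1, s)
  z[const, ] <- 0
  out <- counts
  out[colnames(mat)] <- as.data.frame(z)
  out <- as_tibble(out)
  attr(out, "constant_genes") <- rownames(mat)[const]
  out
}

#' Condition log2 expression ratios by gene and timepoint
#'
#' Computes `log2(value_b / value_a)` for each gene at each matched
#' timepoint, after collapsing replicates to means within gene, condition
#' and timepoint. This is the matrix behind treated/control ratio heat
#' maps.
#'
#' @param counts Wide count table (see [normalize_to_references()]).
#' @param sample_info Data frame mapping sample columns to annotations;
#'   needs columns `sample`, `condition`, `zt_hours`.
#' @param cond_a,cond_b Denominator and numerator condition labels.
#' @param gene_col Name of the gene id column in `counts`.
#' @return A tibble with columns `gene`, `zt_hours`, `log2_ratio` (ratio of
#'   `cond_b` over `cond_a`).
#' @export
condition_log2_ratio <- function(counts, sample_info, cond_a, cond_b,
                                 gene_col = "gene") {
  check_columns(sample_info, c("sample", "condition", "zt_hours"),
                "sample_info")
  mat <- split_count_table(counts, gene_col)
  unknown <- setdiff(sample_info$sample, colnames(mat))
  if (length(unknown) > 0L) {
    stop_field("sample", sprintf("not in the count table: %s",
                                 paste(unknown, collapse = ", ")))
  }
  long <- tibble(
    gene = rep(rownames(mat), times = ncol(mat)),
    sample = rep(colnames(mat), each = nrow(mat)),
    count = as.numeric(mat)
  ) |>
    dplyr::inner_join(as_tibble(sample_info), by = "sample") |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    dplyr::summarise(
      count = mean(.data$count),
      .by = c("gene", "condition", "zt_hours")
    )
  wide <- tidyr::pivot_wider(long, names_from = "condition",
                             values_from = "count")
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% names(wide) || anyNA(wide[[cc]])) {
      bad <- if (!cc %in% names(wide)) unique(wide$zt_hours) else
        wide$zt_hours[is.na(wide[[cc]])]
      stop_rf(sprintf(
        "condition '%s' missing at timepoint(s): %s", cc,
        paste(format(sort(unique(bad))), collapse = ", ")),
        "rhythmfit_grid_mismatch")
    }
  }
  if (any(wide[[cond_a]] == 0)) {
    stop_field(cond_a, "zero denominator value; log2 ratio undefined")
  }
  tibble(
    gene = wide$gene, zt_hours = wide$zt_hours,
    log2_ratio = log2(wide[[cond_b]] / wide[[cond_a]])
  ) |>
    dplyr::arrange(.data$gene, .data$zt_hours)
}

#' Efficiency-corrected relative expression from Cq values
#'
#' Standard delta-Ct quantification:
#' `relative expression = efficiency^-(Cq_target - Cq_reference)`, with
#' amplification efficiency in fold per cycle (2 = perfect doubling).
#'
#' @param ct_target,ct_reference Numeric Cq/Ct vectors (recycled).
#' @param efficiency Fold amplification per cycle, in (1, 2].
#' @return Numeric vector of relative expression values.
#' @examples
#' relative_expression(20, 20)        # 1
#' relative_expression(19, 20)        # 2
#' relative_expression(23.32, 20)     # ~0.100
#' @export
relative_expression <- function(ct_target, ct_reference, efficiency = 2) {
  check_number(efficiency, "efficiency", lower = 1, upper = 2,
               allow_lower = FALSE)
  if (!is.numeric(ct_target) || !is.numeric(ct_reference)) {
    stop_field("ct_target", "Cq values must be numeric")
  }
  efficiency^(-(ct_target - ct_reference))
}
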