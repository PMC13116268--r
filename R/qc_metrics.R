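# Dataset quality control: transcript quality mixture, transcript-to-cell
# assignment rates, spatial densities, and two-group comparisons of any of
# these metrics (unpaired Student's t, mean +/- SEM).

#' Compute quality-control metrics for one sample
#'
#' Reports the high/low transcript-quality split at a quality-value
#' threshold, the fraction of transcripts assigned to a cell, the fraction
#' of segmented cells with no assigned transcript, and the spatial densities
#' (transcripts per µm², cells per mm²). The normalization area is the
#' `tissue_roi` polygon when the sample carries one, else the convex hull of
#' the cell centroids.
#'
#' @param sample a [spatial_sample()] with at least one transcript and one
#'   cell.
#' @param qv_threshold quality value separating high from low quality
#'   transcripts. Default 20 (the platform's conventional Q20 cutoff).
#' @return One-row data frame: `sample_id, condition, n_transcripts, n_cells,
#'   frac_high_quality, frac_low_quality, frac_transcripts_in_cells,
#'   frac_cells_no_transcripts, transcripts_per_um2, cells_per_mm2, area_um2,
#'   qv_threshold`.
#' @export
compute_qc <- function(sample, qv_threshold = 20) {
  tr <- sample$transcripts
  ce <- sample$cells
  if (!nrow(tr)) stop("compute_qc: sample has zero transcripts")
  if (!nrow(ce)) stop("compute_qc: sample has zero cells")
  n_tr <- nrow(tr)
  frac_high <- sum(tr$qv >= qv_threshold) / n_tr
  assigned <- tr$cell_id != "unassigned"
  frac_in_cells <- sum(assigned) / n_tr
  with_tx <- unique(tr$cell_id[assigned])
  frac_empty <- sum(!(ce$cell_id %in% with_tx)) / nrow(ce)
  if (!is.null(sample$tissue_roi)) {
    area <- polygon_area(sample$tissue_roi$vertices)
  } else {
    area <- convex_hull_area(cbind(ce$x, ce$y))
    if (area <= 0) {
      stop("compute_qc: degenerate cell-centroid hull and no tissue_roi; ",
           "cannot derive a normalization area")
    }
  }
  data.frame(
    sample_id = sample$sample_id,
    condition = sample$condition,
    n_transcripts = n_tr,
    n_cells = nrow(ce),
    frac_high_quality = frac_high,
    frac_low_quality = 1 - frac_high,
    frac_transcripts_in_cells = frac_in_cells,
    frac_cells_no_transcripts = frac_empty,
    transcripts_per_um2 = n_tr / area,
    cells_per_mm2 = nrow(ce) / (area / 1e6),  # 1 mm² = 1e6 µm²
    area_um2 = area,
    qv_threshold = qv_threshold,
    stringsAsFactors = FALSE)
}

# Unpaired two-sample t. Equal-variance pooled form by default ("Student's
# t-test"); Welch via var_equal = FALSE. Zero pooled variance returns t = 0,
# p = 1 with a warning so degenerate fixtures do not crash pipelines.
.two_sample_t <- function(a, b, var_equal = TRUE) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("t-test needs n >= 2 in both groups")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("zero variance in both groups; reporting t = 0, p = 1")
    return(list(t = 0, p = 1, df = na + nb - 2))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Compare one QC metric between two groups of samples
#'
#' Unpaired two-sided Student's t-test (equal variance; Welch available) on
#' per-sample metric values, reported as mean ± SEM per group with the
#' fold change of group B over group A.
#'
#' @param reports_a,reports_b data frames of per-sample QC reports (rows from
#'   [compute_qc()], or any table carrying `metric` as a column), at least 2
#'   rows each.
#' @param metric column name to compare.
#' @param var_equal use the pooled-variance Student form (default) or Welch.
#' @return One-row data frame: `metric, group_a, group_b, mean_a, mean_b,
#'   sem_a, sem_b, fold_change, t_statistic, p_value, n_a, n_b`.
#' @export
compare_metric <- function(reports_a, reports_b, metric, var_equal = TRUE) {
  for (df in list(reports_a, reports_b)) {
    if (!metric %in% colnames(df)) {
      stop("schema error: metric column '", metric, "' not found")
    }
  }
  a <- reports_a[[metric]]
  b <- reports_b[[metric]]
  if (length(a) < 2 || length(b) < 2) {
    stop("compare_metric needs >= 2 samples per group")
  }
  tt <- .two_sample_t(a, b, var_equal = var_equal)
  ga <- if ("condition" %in% colnames(reports_a)) reports_a$condition[1] else "A"
  gb <- if ("condition" %in% colnames(reports_b)) reports_b$condition[1] else "B"
  data.frame(
    metric = metric, group_a = ga, group_b = gb,
    mean_a = mean(a), mean_b = mean(b),
    sem_a = stats::sd(a) / sqrt(length(a)),
    sem_b = stats::sd(b) / sqrt(length(b)),
    fold_change = if (mean(a) > 0) mean(b) / mean(a) else NaN,
    t_statistic = tt$t, p_value = tt$p,
    n_a = length(a), n_b = length(b),
    stringsAsFactors = FALSE)
}
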