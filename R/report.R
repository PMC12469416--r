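## Study-style aggregation: per-subject rows, mean/[min-max] summaries,
## signed percent differences between model and manual measurements, and the
## paired Cohen's dz effect size.

#' Signed percent difference of a model measurement from a manual one
#'
#' `100 * (model - manual) / manual`. Positive values are model
#' overestimates.
#'
#' @param manual reference (manual-segmentation) quantity, must be > 0.
#' @param model model-derived quantity.
#' @param digits display rounding (default 1 decimal); use `NULL` for the
#'   raw value.
#' @return percent difference (vectorized).
#' @export
percent_difference <- function(manual, model, digits = 1) {
  if (any(manual <= 0)) stopf("'manual' must be strictly positive")
  out <- 100 * (model - manual) / manual
  if (!is.null(digits)) out <- round(out, digits) else out
}

#' Paired Cohen's dz effect size
#'
#' `dz = mean(d) / sd(d)` with `d_i = model_i - manual_i` and the sample
#' (n-1) standard deviation. Requires n >= 2 paired values and non-constant
#' differences; constant differences have no defined dz (sd = 0) and error.
#' An optional normal-approximation 95% CI (`dz +/- 1.96 * sqrt(1/n +
#' dz^2/(2n))`) is available behind `ci = TRUE`; it is a generic
#' approximation, not validated against the study's (unstated) CI method.
#'
#' @param manual,model equal-length paired measurement vectors.
#' @param ci logical; also return the approximate 95% CI.
#' @return dz, or a list with `dz` and `ci` when `ci = TRUE`.
#' @export
cohens_dz <- function(manual, model, ci = FALSE) {
  if (length(manual) != length(model))
    stopf("'manual' and 'model' must have equal length")
  n <- length(manual)
  if (n < 2L) stopf("Cohen's dz needs at least 2 pairs")
  d <- model - manual
  s <- stats::sd(d)
  if (s == 0) stopf("Cohen's dz undefined: paired differences are constant")
  dz <- mean(d) / s
  if (!ci) return(dz)
  half <- 1.96 * sqrt(1 / n + dz^2 / (2 * n))
  list(dz = dz, ci = c(dz - half, dz + half))
}

#' Mean/[min-max] summary of per-subject rows
#'
#' The summary row of a study table: per-column arithmetic mean and attained
#' range. Means are exact (rounding is display-only via `format_study_cell`).
#'
#' @param rows data.frame of per-subject numeric columns (non-numeric
#'   columns are carried through as `NA` summaries).
#' @return list with `mean`, `min`, `max` (named numeric vectors over the
#'   numeric columns) and `n`.
#' @export
summarize_rows <- function(rows) {
  if (NROW(rows) < 1L) stopf("cannot summarize zero rows")
  num <- vapply(rows, is.numeric, TRUE)
  m <- vapply(rows[num], mean, 0)
  list(mean = m,
       min = vapply(rows[num], min, 0),
       max = vapply(rows[num], max, 0),
       n = NROW(rows))
}

#' Format a value the way the study tables print it
#'
#' DSC/precision/recall and volumes: 2 decimals; HD: 2 decimals (mm);
#' lengths and percentages: 1 decimal.
#'
#' @param x numeric value(s).
#' @param kind one of `"dsc"`, `"hd"`, `"volume"`, `"length"`, `"percent"`.
#' @return character vector.
#' @export
format_study_cell <- function(x, kind = c("dsc", "hd", "volume", "length",
                                          "percent")) {
  kind <- match.arg(kind)
  digits <- switch(kind, dsc = 2L, hd = 2L, volume = 2L, length = 1L,
                   percent = 1L)
  formatC(round(x, digits), format = "f", digits = digits)
}

#' Build a study table with its summary row
#'
#' @param rows per-subject data.frame.
#' @return list of class `study_table`: `rows`, `summary`
#'   (see [summarize_rows()]).
#' @export
study_table <- function(rows) {
  structure(list(rows = rows, summary = summarize_rows(rows)),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  print(x$rows)
  s <- x$summary
  cat("Mean [range]:\n")
  for (nm in names(s$mean))
    cat(sprintf("  %-12s %.4g [%.4g-%.4g]\n", nm, s$mean[nm], s$min[nm],
                s$max[nm]))
  invisible(x)
}

#' Reference validation tables of the source study
#'
#' Per-participant published values for the seven held-out subjects:
#' segmentation metrics for the thoracic volume and spine, and the paired
#' manual-vs-model volume (L) and 3D spinal length (cm) comparisons. These
#' are inputs for reproducing every derivable summary statistic (means,
#' ranges, percent differences, effect sizes); the package recomputes those
#' rather than restating them.
#'
#' @return named list of data.frames: `thorax_metrics`, `spine_metrics`,
#'   `volume_comparison`, `length_comparison`.
#' @export
reference_tables <- function() {
  thorax <- data.frame(
    participant = 1:7,
    volume_L = c(10.10, 6.03, 2.42, 2.68, 3.02, 4.93, 2.42),
    dsc = c(0.89, 0.94, 0.87, 0.91, 0.94, 0.94, 0.90),
    hd = c(54.38, 27.19, 179.41, 25.72, 25.50, 25.50, 25.55),
    hd95 = c(27.19, 1.77, 25.50, 3.33, 2.36, 1.67, 25.50),
    precision = c(0.83, 0.95, 0.78, 0.93, 0.94, 0.96, 0.89),
    recall = c(0.96, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00))
  spine <- data.frame(
    participant = 1:7,
    length_cm = c(30.6, 28.4, 22.8, 17.6, 19.6, 21.5, 20.2),
    dsc = c(0.79, 0.85, 0.83, 0.87, 0.84, 0.86, 0.88),
    hd = c(55.43, 27.25, 26.04, 8.33, 13.44, 25.77, 25.61),
    hd95 = c(27.56, 4.51, 4.71, 3.33, 4.71, 25.50, 3.33),
    precision = c(0.68, 0.74, 0.71, 0.77, 0.72, 0.76, 0.78),
    recall = c(0.96, 1.00, 0.99, 1.00, 1.00, 1.00, 1.00))
  volume <- data.frame(
    participant = 1:7,
    manual_L = c(8.79, 5.77, 1.87, 2.49, 2.83, 4.76, 2.16),
    model_L = c(10.10, 6.03, 2.42, 2.68, 3.02, 4.93, 2.42),
    pct_diff = c(14.9, 4.5, 29.4, 7.1, 6.7, 3.6, 12.0))
  length <- data.frame(
    participant = 1:7,
    manual_cm = c(24.6, 25.0, 19.1, 17.4, 20.0, 20.6, 16.7),
    model_cm = c(30.6, 28.4, 22.8, 17.6, 19.6, 21.5, 20.2),
    pct_diff = c(24.4, 13.6, 19.4, 1.1, -2.0, 4.4, 20.1))
  list(thorax_metrics = thorax, spine_metrics = spine,
       volume_comparison = volume, length_comparison = length)
}

#' Recompute every derivable study statistic from the per-participant cells
#'
#' Means and ranges of the metric tables, per-participant and mean percent
#' differences, and paired Cohen's dz for volume and length. The mean percent
#' difference is the arithmetic mean of the per-subject signed percentages
#' (the table's own `pct_diff` column when present, else recomputed with
#' [percent_difference()]).
#'
#' @param tables table list as from [reference_tables()]; any compatible
#'   per-subject tables work.
#' @return named list of recomputed statistics.
#' @export
study_statistics <- function(tables = reference_tables()) {
  th <- summarize_rows(tables$thorax_metrics[-1])
  sp <- summarize_rows(tables$spine_metrics[-1])
  vol <- tables$volume_comparison
  len <- tables$length_comparison
  vol_pct <- vol$pct_diff %||% percent_difference(vol$manual_L, vol$model_L)
  len_pct <- len$pct_diff %||% percent_difference(len$manual_cm, len$model_cm)
  list(thorax = th, spine = sp,
       volume_pct_diff = vol_pct,
       length_pct_diff = len_pct,
       mean_volume_pct_diff = mean(vol_pct),
       mean_length_pct_diff = mean(len_pct),
       max_pct_diff = max(c(vol_pct, len_pct)),
       dz_volume = cohens_dz(vol$manual_L, vol$model_L),
       dz_length = cohens_dz(len$manual_cm, len$model_cm))
}
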