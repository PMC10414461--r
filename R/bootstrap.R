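#' Quartile assignment with explicit cutpoints
#'
#' Cutpoints are the 25/50/75th percentiles (linear interpolation, the R
#' default quantile definition). Values are assigned to right-closed
#' intervals: Q1 = [min, c25], Q2 = (c25, c50], Q3 = (c50, c75],
#' Q4 = (c75, max], so values tied exactly at a cutpoint all fall in the
#' lower quartile and the extremes are included.
#'
#' @param values numeric vector with at least 4 distinct values.
#' @return list with `labels` (factor Q1..Q4, same length as `values`) and
#'   `cutpoints` (named c25/c50/c75).
#' @export
quartile_assign <- function(values) {
  if (anyNA(values)) stopf("values must not contain NA")
  if (length(unique(values)) < 4) {
    stopf("need at least 4 distinct values for quartiles")
  }
  cut_pts <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  labels <- cut(values, breaks = c(-Inf, cut_pts, Inf),
                labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  list(labels = labels,
       cutpoints = stats::setNames(cut_pts, c("c25", "c50", "c75")))
}

#' Percentile-bootstrap confidence interval for the median
#'
#' Point estimate is the sample median; the CI is the percentile interval
#' of `n_boot` seeded resamples with replacement (the convention of the
#' source analysis: 10,000 resamples, 95% level).
#'
#' @param values nonempty numeric vector.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; identical seeds reproduce the interval.
#' @return list `estimate`, `ci` (length-2), `n_boot`, `level`.
#' @export
bootstrap_median <- function(values, n_boot = 10000, level = 0.95,
                             seed = NULL) {
  boot_stat(values, stats::median, n_boot, level, seed)
}

#' Share of penalized hospital-years with bootstrap CI
#'
#' A hospital-year is penalized when its ERR exceeds 1 (strictly). Returns
#' the stratum share and a percentile-bootstrap CI, on the proportion
#' scale.
#'
#' @param err numeric vector of ERRs.
#' @inheritParams bootstrap_median
#' @return list `estimate`, `ci`, `n_boot`, `level`.
#' @export
pct_penalized <- function(err, n_boot = 10000, level = 0.95, seed = NULL) {
  boot_stat(as.numeric(err > 1), mean, n_boot, level, seed)
}

boot_stat <- function(values, stat, n_boot, level, seed) {
  if (!length(values)) stopf("empty vector")
  if (n_boot < 1) stopf("n_boot must be >= 1")
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  n <- length(values)
  est <- stat(values)
  reps <- run_seeded(seed, function() {
    vapply(seq_len(n_boot),
           function(b) stat(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  ci <- unname(stats::quantile(reps, c((1 - level) / 2, (1 + level) / 2),
                               type = 7))
  list(estimate = est, ci = ci, n_boot = n_boot, level = level)
}

#' Quartile-stratified ERR summaries
#'
#' Stratifies hospital-years into within-year quartiles of a panel column
#' (localization index or SCA %Black) and reports the median ERR and the
#' percent of hospitals penalized per quartile, each with a percentile
#' bootstrap CI — the per-year quartile tables of the analysis.
#'
#' @param panel from [build_panel()].
#' @param by stratifier column, `"li"` or `"pct_black"`.
#' @param per_year stratify within year (default) or over the pooled panel.
#' @param n_boot,level,seed bootstrap settings (see [bootstrap_median()]).
#' @return data frame per (year, quartile): `median_err` with
#'   `median_lo`/`median_hi`, `pct_penalized` (percent) with
#'   `pct_lo`/`pct_hi`, and `n`.
#' @export
quartile_summary <- function(panel, by = c("li", "pct_black"),
                             per_year = TRUE, n_boot = 10000, level = 0.95,
                             seed = NULL) {
  by <- match.arg(by)
  run_seeded(seed, function() {
    chunks <- if (per_year) split(panel, panel$year) else list(all = panel)
    out <- do.call(rbind, lapply(chunks, function(ch) {
      qa <- quartile_assign(ch[[by]])
      do.call(rbind, lapply(levels(qa$labels), function(q) {
        e <- ch$err[qa$labels == q]
        bm <- bootstrap_median(e, n_boot, level, seed = NULL)
        bp <- pct_penalized(e, n_boot, level, seed = NULL)
        data.frame(
          year = if (per_year) ch$year[1] else NA_integer_,
          stratifier = by, quartile = q, n = length(e),
          median_err = bm$estimate, median_lo = bm$ci[1], median_hi = bm$ci[2],
          pct_penalized = 100 * bp$estimate,
          pct_lo = 100 * bp$ci[1], pct_hi = 100 * bp$ci[2]
        )
      }))
    }))
    rownames(out) <- NULL
    out
  })
}
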