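#' Read a hospital-year ERR table
#'
#' @param path CSV with columns `hospital_id`, `zcta`, `year`, `err`.
#' @return data frame with the parsed columns plus `penalized = err > 1`
#'   (strict inequality: an ERR of exactly 1 is not penalized).
#' @export
read_err <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("hospital_id", "zcta", "year", "err") %in% names(df))) {
    stopf("ERR CSV must have columns hospital_id, zcta, year, err")
  }
  err <- suppressWarnings(as.numeric(df$err))
  bad <- which(is.na(err) | err <= 0)
  if (length(bad)) {
    stopf("nonpositive or malformed ERR on line(s) %s of %s",
          paste(utils::head(bad + 1L, 10), collapse = ", "), path)
  }
  data.frame(
    hospital_id = df$hospital_id,
    zcta = pad_zcta(df$zcta),
    year = as.integer(df$year),
    err = err,
    penalized = err > 1
  )
}

#' Aggregate ZCTA-level covariates to SCA level
#'
#' SCA covariate values are population-weighted means of the member ZCTAs'
#' proportions (unweighted means available via `weighted = FALSE`).
#'
#' @param zcta_covariates data frame with columns `zcta`, `population`,
#'   `pct_black`, `pct_hispanic`, `pct_poverty`, `pct_private` (proportions
#'   in `[0, 1]`).
#' @param partition an [sca_partition].
#' @param weighted population-weighted (default) or plain means.
#' @param strict error (default) or drop-with-message when a partition ZCTA
#'   has no covariate row.
#' @return data frame `sca_id`, `pct_black`, `pct_hispanic`, `pct_poverty`,
#'   `pct_private`.
#' @export
aggregate_covariates <- function(zcta_covariates, partition, weighted = TRUE,
                                 strict = TRUE) {
  lab <- partition_labels(partition)
  vars <- c("pct_black", "pct_hispanic", "pct_poverty", "pct_private")
  if (!all(c("zcta", "population", vars) %in% names(zcta_covariates))) {
    stopf("covariate table must have columns zcta, population, %s",
          paste(vars, collapse = ", "))
  }
  miss <- setdiff(names(lab), zcta_covariates$zcta)
  if (length(miss)) {
    if (strict) {
      stopf("no covariates for ZCTA(s): %s",
            paste(utils::head(miss, 10), collapse = ", "))
    }
    msgf("aggregate_covariates: %d partition ZCTA(s) lack covariates and are dropped",
         length(miss))
    lab <- lab[!(names(lab) %in% miss)]
  }
  cv <- zcta_covariates[zcta_covariates$zcta %in% names(lab), , drop = FALSE]
  for (v in vars) {
    if (any(cv[[v]] < 0 | cv[[v]] > 1)) {
      stopf("%s must be a proportion in [0, 1]", v)
    }
  }
  sca <- unname(lab[cv$zcta])
  w <- if (weighted) cv$population else rep(1, nrow(cv))
  out <- data.frame(sca_id = sort(unique(sca)))
  for (v in vars) {
    num <- rowsum(cv[[v]] * w, sca)
    den <- rowsum(w, sca)
    out[[v]] <- (num / den)[match(out$sca_id, as.integer(rownames(num))), 1L]
  }
  out
}

#' Assemble the longitudinal hospital-year panel
#'
#' Inner-joins ERR records to yearly SCA assignments, localization metrics
#' and SCA covariates, drops hospital-years whose SCA has an undefined LI
#' (logged), and applies the eligibility rule that a hospital must
#' contribute at least `min_years` repeated measures.
#'
#' @param err_records from [read_err()] or the generator.
#' @param assignments data frame `hospital_id`, `year`, `sca_id` (e.g. from
#'   [assign_hospitals()] applied per-year, with a `year` column added), and
#'   optionally `algorithm`.
#' @param sca_metrics from [localization_index()] (needs `sca_id`, `year`,
#'   `li`).
#' @param covariates from [aggregate_covariates()]; either one row per
#'   `sca_id` (time-constant) or with an additional `year` column.
#' @param min_years eligibility threshold on repeated measures (default 2,
#'   the minimum for a longitudinal model).
#' @return panel data frame `hospital_id`, `year`, `algorithm`, `sca_id`,
#'   `err`, `li`, `pct_black`, `pct_hispanic`, `pct_poverty`, `pct_private`,
#'   `penalized`.
#' @export
build_panel <- function(err_records, assignments, sca_metrics, covariates,
                        min_years = 2) {
  alg <- assignments$algorithm %||% sca_metrics$algorithm %||% "unknown"
  pan <- merge(err_records[, c("hospital_id", "year", "err")],
               assignments[, c("hospital_id", "year", "sca_id")],
               by = c("hospital_id", "year"))
  pan <- merge(pan, sca_metrics[, c("sca_id", "year", "li")],
               by = c("sca_id", "year"))
  if (!nrow(pan)) stopf("panel join is empty: no (hospital, year) matched an SCA")
  na_li <- is.na(pan$li)
  if (any(na_li)) {
    msgf("build_panel: dropped %d hospital-year(s) in SCAs with undefined LI",
         sum(na_li))
    pan <- pan[!na_li, , drop = FALSE]
  }
  by <- intersect(c("sca_id", "year"), names(covariates))
  pan <- merge(pan, covariates, by = by)
  if (!nrow(pan)) stopf("panel join is empty after covariate merge")
  if (anyDuplicated(pan[, c("hospital_id", "year")])) {
    stopf("duplicate (hospital, year) rows after join")
  }
  keep <- names(which(table(pan$hospital_id) >= min_years))
  dropped <- length(unique(pan$hospital_id)) - length(keep)
  if (dropped > 0) {
    msgf("build_panel: excluded %d hospital(s) with fewer than %d years",
         dropped, min_years)
  }
  pan <- pan[pan$hospital_id %in% keep, , drop = FALSE]
  if (!nrow(pan)) stopf("no hospital meets the %d-year eligibility rule", min_years)
  pan$algorithm <- alg[1]
  pan$penalized <- pan$err > 1
  pan <- pan[order(pan$hospital_id, pan$year), ]
  rownames(pan) <- NULL
  pan[, c("hospital_id", "year", "algorithm", "sca_id", "err", "li",
          "pct_black", "pct_hispanic", "pct_poverty", "pct_private",
          "penalized")]
}

#' Per-year descriptive summary of the panel
#'
#' @param panel from [build_panel()].
#' @return data frame per year: `n`, `pct_penalized` (percent of
#'   hospital-years with ERR > 1), `mean_err`, `sd_err` (`NA` when n = 1).
#' @export
summarize_panel <- function(panel) {
  if (!nrow(panel)) stopf("empty panel")
  years <- sort(unique(panel$year))
  out <- do.call(rbind, lapply(years, function(y) {
    e <- panel$err[panel$year == y]
    data.frame(year = y, n = length(e),
               pct_penalized = 100 * mean(e > 1),
               mean_err = mean(e),
               sd_err = if (length(e) > 1) stats::sd(e) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
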