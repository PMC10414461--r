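#' Quantiles of year-over-year localization-index changes
#'
#' Pools the differences in LI between consecutive observed years (gap of
#' exactly one year) across all hospitals, drops exact zeros, and reports
#' the 25/50/75th percentiles separately for the negative and positive
#' differences. The labels follow the magnitude convention: `-q1` is the
#' smallest negative change in magnitude (the 75th percentile of the
#' negative group), `-q3` the largest; `+q1`..`+q3` are the 25/50/75th
#' percentiles of the positive group. Percentiles use Hazen (midpoint)
#' linear interpolation.
#'
#' @param panel from [build_panel()]; needs `hospital_id`, `year`, `li`.
#' @return list with `negative` (named `-q3`, `-q2`, `-q1`, increasing) and
#'   `positive` (named `+q1`, `+q2`, `+q3`, increasing).
#' @export
li_change_quantiles <- function(panel) {
  pan <- panel[order(panel$hospital_id, panel$year), ]
  sameh <- pan$hospital_id[-1] == pan$hospital_id[-nrow(pan)]
  consec <- diff(pan$year) == 1L
  d <- diff(pan$li)[sameh & consec]
  if (!length(d)) stopf("no consecutive-year LI differences in the panel")
  neg <- d[d < 0]
  pos <- d[d > 0]
  if (!length(neg)) stopf("no negative LI differences (negative group empty)")
  if (!length(pos)) stopf("no positive LI differences (positive group empty)")
  qn <- stats::quantile(neg, c(0.25, 0.5, 0.75), names = FALSE, type = 5)
  qp <- stats::quantile(pos, c(0.25, 0.5, 0.75), names = FALSE, type = 5)
  list(negative = stats::setNames(qn, c("-q3", "-q2", "-q1")),
       positive = stats::setNames(qp, c("+q1", "+q2", "+q3")))
}

#' Predicted ERR under a localization-index shift
#'
#' Marginal (population-level) linear predictions of the fitted GEE at
#' `li + shift` with all other covariates at their observed values. The
#' model is linear, so every prediction moves by exactly
#' `beta_li * shift` relative to the unshifted fitted values — this affine
#' identity is what makes the prediction tables desk-checkable.
#'
#' @param fit a [fit_gee()] whose covariates include `"li"`.
#' @param panel panel rows to predict for.
#' @param shift LI shift to apply (scalar, may be negative).
#' @return numeric vector of predicted ERRs, one per panel row.
#' @export
predict_shifted <- function(fit, panel, shift = 0) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!"li" %in% fit$covariates) stopf("fit does not include the li term")
  miss <- setdiff(fit$covariates, names(panel))
  if (length(miss)) stopf("panel lacks column(s): %s", paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(panel[, fit$covariates, drop = FALSE]))
  X[, match("li", fit$covariates) + 1L] <- panel$li + shift
  drop(X %*% fit$beta)
}

#' Shifted median under the affine prediction identity
#'
#' Because predictions are affine in LI, the median predicted ERR after a
#' shift `s` equals the baseline median plus `beta_li * s` exactly. This
#' helper applies that identity to a known baseline median — e.g. to verify
#' a published prediction table row from its printed baseline, printed LI
#' coefficient, and printed shift.
#'
#' @param baseline_median median predicted ERR at shift 0.
#' @param beta_li LI coefficient.
#' @param shift LI shift.
#' @return shifted median predicted ERR.
#' @export
shifted_median <- function(baseline_median, beta_li, shift) {
  baseline_median + beta_li * shift
}

#' Counterfactual prediction table over %Black strata and LI shifts
#'
#' Stratifies the panel into quartiles of the SCA %Black (boundaries
#' computed over distinct SCA-year rows) and, for each stratum and each LI
#' shift in \{-q3, -q2, -q1, 0, +q1, +q2, +q3\}, reports the median
#' predicted ERR and the share of predictions above 1, with percentile
#' bootstrap CIs over the shifted predictions. An empty stratum yields a
#' flagged row (`n = 0`, `NA` values), never a silently dropped one.
#'
#' @param fit adjusted-model [fit_gee()].
#' @param panel from [build_panel()].
#' @param quantiles from [li_change_quantiles()]; computed from `panel` if
#'   omitted.
#' @param n_boot,level,seed bootstrap settings.
#' @return data frame per (black_quartile, shift): `shift_label`, `shift`,
#'   `n`, `median_err` + CI, `pct_penalized` (proportion) + CI.
#' @export
counterfactual_table <- function(fit, panel, quantiles = NULL,
                                 n_boot = 10000, level = 0.95, seed = NULL) {
  if (is.null(quantiles)) quantiles <- li_change_quantiles(panel)
  shifts <- c(quantiles$negative, "0" = 0, quantiles$positive)
  sca_rows <- unique(panel[, c("sca_id", "year", "pct_black")])
  qa <- quartile_assign(sca_rows$pct_black)
  strat <- qa$labels[match(paste(panel$sca_id, panel$year),
                           paste(sca_rows$sca_id, sca_rows$year))]
  run_seeded(seed, function() {
    out <- do.call(rbind, lapply(levels(strat), function(q) {
      rows <- panel[strat == q, , drop = FALSE]
      do.call(rbind, lapply(seq_along(shifts), function(k) {
        if (!nrow(rows)) {
          return(data.frame(black_quartile = q, shift_label = names(shifts)[k],
                            shift = unname(shifts[k]), n = 0L,
                            median_err = NA_real_, median_lo = NA_real_,
                            median_hi = NA_real_, pct_penalized = NA_real_,
                            pct_lo = NA_real_, pct_hi = NA_real_))
        }
        pred <- predict_shifted(fit, rows, shifts[k])
        bm <- bootstrap_median(pred, n_boot, level, seed = NULL)
        bp <- pct_penalized(pred, n_boot, level, seed = NULL)
        data.frame(black_quartile = q, shift_label = names(shifts)[k],
                   shift = unname(shifts[k]), n = length(pred),
                   median_err = bm$estimate, median_lo = bm$ci[1],
                   median_hi = bm$ci[2],
                   pct_penalized = bp$estimate, pct_lo = bp$ci[1],
                   pct_hi = bp$ci[2])
      }))
    }))
    rownames(out) <- NULL
    attr(out, "black_cutpoints") <- qa$cutpoints
    out
  })
}
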