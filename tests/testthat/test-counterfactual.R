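# panel with a planted strong negative LI effect and no noise, so the
# affine prediction identities are exact
noiseless_panel <- function() {
  cfg <- synthetic_config(n_scas = 8, zctas_per_sca = 4, hospitals_per_sca = 2,
                          beta_li = -0.5, sigma_b = 0, sigma_e = 0, seed = 61)
  gen <- generate_flows(cfg)
  li <- localization_index(gen$flows, gen$partition)
  generate_panel(cfg, gen$partition, li, gen$hospitals)$panel
}

test_that("LI-change quantiles match the hand percentile computation", {
  d <- c(-0.2, -0.1, -0.05, 0.1, 0.2, 0.3)
  pan <- data.frame(hospital_id = "A", year = 2011:2017,
                    li = cumsum(c(0.5, d)))
  q <- li_change_quantiles(pan)
  expect_equal(unname(q$negative), c(-0.175, -0.1, -0.0625))
  expect_equal(names(q$negative), c("-q3", "-q2", "-q1"))
  expect_true(all(diff(unname(q$negative)) >= 0) && all(q$negative < 0))
  expect_true(all(diff(unname(q$positive)) >= 0) && all(q$positive > 0))

  # zeros are excluded from both sign groups
  pan0 <- data.frame(hospital_id = "A", year = 2011:2018,
                     li = cumsum(c(0.5, 0, d)))
  expect_equal(li_change_quantiles(pan0), q)

  # constant LI: both groups empty -> error naming the group
  flat <- data.frame(hospital_id = "A", year = 2012:2015, li = 0.5)
  expect_error(li_change_quantiles(flat), "negative")

  # sort-and-index oracle on a larger pooled set
  pan2 <- withr::with_seed(71, data.frame(
    hospital_id = rep(sprintf("H%02d", 1:20), each = 5),
    year = rep(2012:2016, 20), li = stats::runif(100)))
  q2 <- li_change_quantiles(pan2)
  d2 <- unlist(tapply(pan2$li, pan2$hospital_id, diff))
  hazen <- function(x, p) {
    x <- sort(x); h <- length(x) * p + 0.5
    hf <- floor(pmin(pmax(h, 1), length(x)))
    lo <- x[hf]; hi <- x[pmin(hf + 1, length(x))]
    lo + (h - hf) * (hi - lo)
  }
  expect_equal(unname(q2$negative), unname(hazen(d2[d2 < 0], c(.25, .5, .75))))
  expect_equal(unname(q2$positive), unname(hazen(d2[d2 > 0], c(.25, .5, .75))))
})

test_that("shifted predictions obey the affine identity", {
  pan <- noiseless_panel()
  fit <- fit_gee(pan)
  base <- predict_shifted(fit, pan, 0)
  # shift 0 reproduces the fitted values, here the observed noiseless ERR
  expect_equal(base, pan$err, tolerance = 1e-8)
  for (s in c(-0.167, 0.019, 0.179)) {
    expect_equal(predict_shifted(fit, pan, s),
                 base + fit$beta[["li"]] * s, tolerance = 1e-12)
    expect_equal(stats::median(predict_shifted(fit, pan, s)),
                 stats::median(base) + fit$beta[["li"]] * s,
                 tolerance = 1e-12)
  }
  expect_equal(shifted_median(0.995, -0.0474, 0.179),
               0.995 - 0.0474 * 0.179)
})

test_that("counterfactual table is exact under linearity and flags strata", {
  pan <- noiseless_panel()
  fit <- fit_gee(pan)
  q <- list(negative = c("-q3" = -0.15, "-q2" = -0.06, "-q1" = -0.02),
            positive = c("+q1" = 0.02, "+q2" = 0.07, "+q3" = 0.18))
  ct <- counterfactual_table(fit, pan, quantiles = q, n_boot = 200, seed = 3)
  expect_equal(nrow(ct), 28) # 4 strata x 7 shifts
  beta_li <- fit$beta[["li"]]
  for (qq in unique(ct$black_quartile)) {
    sub <- ct[ct$black_quartile == qq, ]
    base <- sub$median_err[sub$shift_label == "0"]
    expect_equal(sub$median_err, base + beta_li * sub$shift, tolerance = 1e-10)
    # negative beta_li: median non-increasing and penalties non-increasing
    ord <- order(sub$shift)
    expect_true(all(diff(sub$median_err[ord]) <= 1e-12))
    expect_true(all(diff(sub$pct_penalized[ord]) <= 1e-12))
  }
  # brute-force recomputation of one stratum cell
  sca_rows <- unique(pan[, c("sca_id", "year", "pct_black")])
  qa <- quartile_assign(sca_rows$pct_black)
  strat <- qa$labels[match(paste(pan$sca_id, pan$year),
                           paste(sca_rows$sca_id, sca_rows$year))]
  rows <- pan[strat == "Q2", ]
  pred <- cbind(1, rows$li + 0.18, rows$pct_black, rows$pct_poverty,
                rows$pct_private, rows$pct_hispanic) %*% fit$beta
  expect_equal(ct$median_err[ct$black_quartile == "Q2" &
                             ct$shift_label == "+q3"],
               stats::median(pred))
  expect_equal(ct$pct_penalized[ct$black_quartile == "Q2" &
                                ct$shift_label == "+q3"],
               mean(pred > 1))

  # a stratum where every prediction is penalized has a degenerate CI
  pan_hi <- pan
  pan_hi$err <- pan_hi$err + 1
  fit_hi <- fit_gee(pan_hi)
  ct_hi <- counterfactual_table(fit_hi, pan_hi, quantiles = q,
                                n_boot = 100, seed = 4)
  expect_true(any(ct_hi$pct_penalized == 1 & ct_hi$pct_lo == 1 &
                  ct_hi$pct_hi == 1))
})
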