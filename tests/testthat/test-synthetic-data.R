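test_that("generator is a deterministic function of the seed", {
  a <- generate_flows(small_config(seed = 11))
  b <- generate_flows(small_config(seed = 11))
  c <- generate_flows(small_config(seed = 12))
  expect_identical(a$flows, b$flows)
  expect_identical(a$partition$labels, b$partition$labels)
  expect_false(identical(a$flows, c$flows))

  li <- localization_index(a$flows, a$partition)
  p1 <- generate_panel(small_config(seed = 11), a$partition, li, a$hospitals)
  p2 <- generate_panel(small_config(seed = 11), a$partition, li, a$hospitals)
  expect_identical(p1$panel, p2$panel)
})

test_that("flows respect the planted layout and conservation", {
  cfg <- small_config(seed = 3)
  g <- generate_flows(cfg)
  expect_true(all(g$flows$count >= 1))
  expect_setequal(unique(g$flows$year), cfg$years)
  # every ZCTA belongs to exactly one planted SCA
  expect_length(g$partition$labels, cfg$n_scas * cfg$zctas_per_sca)
  expect_equal(sort(unique(unname(g$partition$labels))), 0:(cfg$n_scas - 1))
  # hospitals sit in their own ZCTA inside their planted SCA
  expect_true(all(g$partition$labels[g$hospitals$zcta] == g$hospitals$sca_id))
  # conservation: network weight equals the year's discharge total
  for (y in cfg$years[1:2]) {
    net <- build_network(g$flows, y)
    expect_equal(network_summary(net)$total_weight,
                 sum(g$flows$count[g$flows$year == y]))
  }
})

test_that("no cross-border flow means every SCA is fully localized", {
  cfg <- synthetic_config(n_scas = 3, zctas_per_sca = 5, hospitals_per_sca = 2,
                          within_rate = 10, between_rate = 0, seed = 5)
  g <- generate_flows(cfg)
  li <- localization_index(g$flows, g$partition)
  expect_true(all(li$li == 1))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(within_rate = 1, between_rate = 2), "within_rate")
  expect_error(synthetic_config(hospitals_per_sca = 0), "hospital")
  expect_error(synthetic_config(hospitals_per_sca = 5, zctas_per_sca = 3),
               "exceed")
  expect_error(synthetic_config(sigma_b = -1), "sigma")
  expect_error(synthetic_config(covariate_ranges = list(pct_black = c(0, 2))),
               "pct_black|range")
})

test_that("noiseless panel reproduces the linear predictor exactly", {
  cfg <- synthetic_config(n_scas = 8, zctas_per_sca = 4, hospitals_per_sca = 2,
                          sigma_b = 0, sigma_e = 0, seed = 21)
  g <- generate_flows(cfg)
  li <- localization_index(g$flows, g$partition)
  pan <- generate_panel(cfg, g$partition, li, g$hospitals)$panel
  lp <- cfg$beta0 + cfg$beta_li * pan$li + cfg$beta_black * pan$pct_black +
    cfg$beta_poverty * pan$pct_poverty + cfg$beta_private * pan$pct_private +
    cfg$beta_hispanic * pan$pct_hispanic
  expect_equal(pan$err, lp, tolerance = 1e-12)
  # and the GEE recovers every coefficient to machine precision
  fit <- fit_gee(pan)
  planted <- c(cfg$beta0, cfg$beta_li, cfg$beta_black, cfg$beta_poverty,
               cfg$beta_private, cfg$beta_hispanic)
  expect_equal(unname(fit$beta), planted, tolerance = 1e-8)
})

test_that("planted variance components give the implied exchangeable correlation", {
  cfg <- synthetic_config(n_scas = 200, zctas_per_sca = 2,
                          hospitals_per_sca = 2, sigma_b = 0.05,
                          sigma_e = 0.05, seed = 9)
  expect_equal(cfg$rho, 0.5)
  lay <- expand.grid(sca_id = 0:199, year = cfg$years)
  lay$li <- withr::with_seed(1, runif(nrow(lay), 0.3, 0.9))
  g <- generate_flows(cfg)
  pan <- generate_panel(cfg, g$partition, lay, g$hospitals)$panel
  resid <- pan$err - (cfg$beta0 + cfg$beta_li * pan$li +
    cfg$beta_black * pan$pct_black + cfg$beta_poverty * pan$pct_poverty +
    cfg$beta_private * pan$pct_private + cfg$beta_hispanic * pan$pct_hispanic)
  # moment estimate of the within-hospital correlation of the true residuals
  sig2 <- mean(resid^2)
  cross <- sum(tapply(resid, pan$hospital_id,
                      function(r) (sum(r)^2 - sum(r^2)) / 2))
  npairs <- sum(tapply(resid, pan$hospital_id,
                       function(r) length(r) * (length(r) - 1) / 2))
  expect_equal(cross / npairs / sig2, 0.5, tolerance = 0.05)
})

test_that("written synthetic dataset round-trips through the readers", {
  cfg <- small_config(seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  flows <- read_flows(paths$flows)
  gen <- generate_flows(cfg)
  expect_equal(flows, gen$flows)
  cw <- read_crosswalk(paths$crosswalk)
  expect_identical(unname(cw), names(cw)) # identity crosswalk
  errs <- read_err(paths$err)
  expect_true(all(errs$err > 0))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$beta$li, cfg$beta_li)
  expect_equal(truth$rho, 0.5)
})
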