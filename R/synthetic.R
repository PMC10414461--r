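#' Configuration for the synthetic discharge / readmission generator
#'
#' The generator emulates the three restricted inputs of the analysis —
#' origin-destination ED discharge flows, hospital-year excess readmission
#' ratios (ERR), and area-level covariates — with known planted structure:
#' ZCTAs are grouped into `n_scas` true shared care areas, discharge counts
#' between a residence ZCTA and a hospital are Poisson with mean
#' `within_rate` inside a planted SCA and `between_rate` across SCAs, and
#' ERR follows the linear model
#' \deqn{ERR_{it} = \beta_0 + \beta_{LI} LI_{s(i),t} + \beta_{Black} Black_s
#'   + \beta_{Pov} Pov_s + \beta_{Priv} Priv_s + \beta_{Hisp} Hisp_s +
#'   b_i + e_{it}}
#' with hospital random intercepts \eqn{b_i \sim N(0, \sigma_b^2)} and
#' residuals \eqn{e_{it} \sim N(0, \sigma_e^2)}, implying an exchangeable
#' within-hospital correlation \eqn{\rho = \sigma_b^2/(\sigma_b^2 +
#' \sigma_e^2)}.
#'
#' Defaults mirror the study conditions: 300 hospitals (30 SCAs x 10)
#' observed over 2012-2017 and the adjusted-model coefficients
#' (\eqn{\beta_{LI} = -0.0474}, \eqn{\beta_{Black} = 0.4128}, ...), with
#' \eqn{\sigma_b = \sigma_e = 0.05} so \eqn{\rho = 0.5}.
#'
#' @param n_scas number of planted SCAs.
#' @param zctas_per_sca ZCTAs per SCA.
#' @param hospitals_per_sca hospitals per SCA; hospitals occupy the first
#'   `hospitals_per_sca` ZCTAs of their SCA (a ZCTA can be both a residence
#'   and a hospital location). Must be at least 1: an SCA without hospitals
#'   has no localization index downstream.
#' @param years integer vector of years.
#' @param within_rate,between_rate expected discharges per (residence,
#'   hospital) ZCTA pair inside vs. across planted SCAs;
#'   `within_rate > between_rate >= 0`.
#' @param beta0,beta_li,beta_black,beta_poverty,beta_private,beta_hispanic
#'   coefficients of the ERR-generating linear model.
#' @param sigma_b,sigma_e hospital random-intercept and residual standard
#'   deviations (both `>= 0`).
#' @param covariate_ranges named list of `c(min, max)` proportions for
#'   `pct_black`, `pct_hispanic`, `pct_poverty`, `pct_private`; each SCA
#'   draws its value uniformly once.
#' @param seed integer seed; all generator output is a deterministic
#'   function of the configuration.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_scas = 30, zctas_per_sca = 10,
                             hospitals_per_sca = 10,
                             years = 2012:2017,
                             within_rate = 20, between_rate = 0.5,
                             beta0 = 1.1054, beta_li = -0.0474,
                             beta_black = 0.4128, beta_poverty = -0.0208,
                             beta_private = -0.1317, beta_hispanic = 0.0278,
                             sigma_b = 0.05, sigma_e = 0.05,
                             covariate_ranges = list(
                               pct_black = c(0.002, 0.176),
                               pct_hispanic = c(0.10, 0.60),
                               pct_poverty = c(0.05, 0.30),
                               pct_private = c(0.30, 0.80)
                             ),
                             seed = 1L) {
  if (n_scas < 1 || zctas_per_sca < 1) stopf("counts must be >= 1")
  if (hospitals_per_sca < 1) {
    stopf("each SCA needs at least one hospital (LI undefined otherwise)")
  }
  if (hospitals_per_sca > zctas_per_sca) {
    stopf("hospitals_per_sca cannot exceed zctas_per_sca")
  }
  if (!(within_rate > between_rate) || between_rate < 0) {
    stopf("need within_rate > between_rate >= 0")
  }
  if (sigma_b < 0 || sigma_e < 0) stopf("sigma_b and sigma_e must be >= 0")
  needed <- c("pct_black", "pct_hispanic", "pct_poverty", "pct_private")
  if (!all(needed %in% names(covariate_ranges))) {
    stopf("covariate_ranges must name %s", paste(needed, collapse = ", "))
  }
  for (nm in needed) {
    r <- covariate_ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 1) {
      stopf("covariate range for %s must be c(min, max) within [0, 1]", nm)
    }
  }
  rho <- if (sigma_b == 0 && sigma_e == 0) 0 else sigma_b^2 / (sigma_b^2 + sigma_e^2)
  structure(
    list(n_scas = as.integer(n_scas), zctas_per_sca = as.integer(zctas_per_sca),
         hospitals_per_sca = as.integer(hospitals_per_sca),
         years = as.integer(years),
         within_rate = within_rate, between_rate = between_rate,
         beta0 = beta0, beta_li = beta_li, beta_black = beta_black,
         beta_poverty = beta_poverty, beta_private = beta_private,
         beta_hispanic = beta_hispanic,
         sigma_b = sigma_b, sigma_e = sigma_e, rho = rho,
         covariate_ranges = covariate_ranges, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# ZCTA codes, planted labels and hospital roster implied by a config.
synthetic_layout <- function(config) {
  n_zctas <- config$n_scas * config$zctas_per_sca
  zctas <- pad_zcta(90000L + seq_len(n_zctas))
  sca <- rep(seq_len(config$n_scas) - 1L, each = config$zctas_per_sca)
  hosp_pos <- as.vector(vapply(seq_len(config$n_scas), function(s) {
    (s - 1L) * config$zctas_per_sca + seq_len(config$hospitals_per_sca)
  }, integer(config$hospitals_per_sca)))
  hospitals <- data.frame(
    hospital_id = sprintf("H%04d", seq_along(hosp_pos)),
    zcta = zctas[hosp_pos],
    sca_id = sca[hosp_pos]
  )
  labels <- sca
  names(labels) <- zctas
  list(zctas = zctas, labels = labels, hospitals = hospitals)
}

#' Generate discharge flows with planted SCA structure
#'
#' Draws one Poisson count per (year, residence ZCTA, hospital); pairs whose
#' draw is zero are omitted from the table (they carry no discharges).
#'
#' @param config a [synthetic_config()].
#' @return list with `flows` (data frame `year`, `origin_zcta`,
#'   `hospital_id`, `hospital_zcta`, `count`), `partition` (the planted
#'   [sca_partition]), and `hospitals` (roster `hospital_id`, `zcta`,
#'   `sca_id`).
#' @export
generate_flows <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lay <- synthetic_layout(config)
  n_z <- length(lay$zctas)
  n_h <- nrow(lay$hospitals)
  oi <- rep(seq_len(n_z), times = n_h)
  hi <- rep(seq_len(n_h), each = n_z)
  same <- lay$labels[oi] == lay$hospitals$sca_id[hi]
  rate <- ifelse(same, config$within_rate, config$between_rate)
  flows <- run_seeded(config$seed, function() {
    do.call(rbind, lapply(config$years, function(y) {
      cnt <- stats::rpois(length(rate), rate)
      keep <- cnt > 0L
      data.frame(
        year = rep.int(y, sum(keep)),
        origin_zcta = lay$zctas[oi[keep]],
        hospital_id = lay$hospitals$hospital_id[hi[keep]],
        hospital_zcta = lay$hospitals$zcta[hi[keep]],
        count = cnt[keep]
      )
    }))
  })
  partition <- sca_partition(lay$labels, year = NA_integer_,
                             algorithm = "planted", relabel = FALSE)
  list(flows = flows, partition = partition, hospitals = lay$hospitals)
}

#' Generate the hospital-year ERR panel from realized localization
#'
#' The ERR model uses the localization index actually realized by the
#' generated flows (supplied by the caller, normally from
#' [localization_index()]), never a shortcut, so that downstream recovery
#' tests are honest.
#'
#' @param config a [synthetic_config()].
#' @param partition planted (or detected) [sca_partition] used to place
#'   hospitals.
#' @param li_by_sca_year data frame with columns `sca_id`, `year`, `li`.
#' @param hospitals roster as produced by [generate_flows()]; defaults to
#'   the layout implied by `config`.
#' @param seed seed for covariate and noise draws; defaults to
#'   `config$seed + 1` so flow and panel draws come from distinct streams
#'   while remaining a pure function of the configuration.
#' @return list with `panel` (data frame `hospital_id`, `zcta`, `year`,
#'   `sca_id`, `err`, `li`, `pct_black`, `pct_hispanic`, `pct_poverty`,
#'   `pct_private`) and `covariates` (per-SCA draws).
#' @export
generate_panel <- function(config, partition, li_by_sca_year,
                           hospitals = NULL, seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(hospitals)) hospitals <- synthetic_layout(config)$hospitals
  assign <- assign_hospitals(hospitals, partition)
  need <- expand.grid(sca_id = unique(assign$sca_id), year = config$years,
                      KEEP.OUT.ATTRS = FALSE)
  key <- paste(li_by_sca_year$sca_id, li_by_sca_year$year)
  hit <- match(paste(need$sca_id, need$year), key)
  if (anyNA(hit)) {
    stopf("li_by_sca_year lacks %d (sca_id, year) combination(s) required by the partition",
          sum(is.na(hit)))
  }
  run_seeded(seed, function() {
    covs <- data.frame(sca_id = sort(unique(partition_labels(partition))))
    for (nm in names(config$covariate_ranges)) {
      r <- config$covariate_ranges[[nm]]
      covs[[nm]] <- stats::runif(nrow(covs), r[1], r[2])
    }
    b <- stats::rnorm(nrow(assign), 0, config$sigma_b)
    names(b) <- assign$hospital_id
    rows <- merge(assign, data.frame(year = config$years))
    rows$li <- li_by_sca_year$li[match(paste(rows$sca_id, rows$year), key)]
    rows <- merge(rows, covs, by = "sca_id", sort = FALSE)
    rows <- rows[order(rows$hospital_id, rows$year), ]
    e <- stats::rnorm(nrow(rows), 0, config$sigma_e)
    rows$err <- config$beta0 + config$beta_li * rows$li +
      config$beta_black * rows$pct_black +
      config$beta_poverty * rows$pct_poverty +
      config$beta_private * rows$pct_private +
      config$beta_hispanic * rows$pct_hispanic +
      b[rows$hospital_id] + e
    rownames(rows) <- NULL
    list(panel = rows[, c("hospital_id", "zcta", "year", "sca_id", "err", "li",
                          "pct_black", "pct_hispanic", "pct_poverty",
                          "pct_private")],
         covariates = covs)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Runs the full generator — flows, planted partition, realized localization
#' index, ERR panel — and writes the four input CSVs the pipeline consumes
#' (`flows.csv`, `err.csv`, `covariates.csv` at ZCTA level with population,
#' `crosswalk.csv`, here the identity zip-to-ZCTA map) plus `truth.json`
#' recording the planted partition, coefficients, and correlation for
#' recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_synthetic_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_flows(config)
  li <- localization_index(gen$flows, gen$partition)
  pan <- generate_panel(config, gen$partition, li, gen$hospitals)
  lab <- partition_labels(gen$partition)
  pop <- run_seeded(config$seed + 2L, function() {
    sample(1000:50000, length(lab), replace = TRUE)
  })
  cov_zcta <- data.frame(zcta = names(lab), sca_id = unname(lab),
                         population = pop)
  cov_zcta <- merge(cov_zcta, pan$covariates, by = "sca_id", sort = FALSE)
  cov_zcta <- cov_zcta[, c("zcta", "population", "pct_black", "pct_hispanic",
                           "pct_poverty", "pct_private")]
  paths <- list(
    flows = file.path(dir, "flows.csv"),
    err = file.path(dir, "err.csv"),
    covariates = file.path(dir, "covariates.csv"),
    crosswalk = file.path(dir, "crosswalk.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(gen$flows, paths$flows, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    pan$panel[, c("hospital_id", "zcta", "year", "err")],
    paths$err, row.names = FALSE, quote = FALSE
  )
  utils::write.csv(cov_zcta, paths$covariates, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(zip = names(lab), zcta = names(lab)),
                   paths$crosswalk, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(
      partition = as.list(stats::setNames(as.integer(lab), names(lab))),
      beta = list(intercept = config$beta0, li = config$beta_li,
                  pct_black = config$beta_black,
                  pct_poverty = config$beta_poverty,
                  pct_private = config$beta_private,
                  pct_hispanic = config$beta_hispanic),
      rho = config$rho,
      seed = config$seed
    ),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
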