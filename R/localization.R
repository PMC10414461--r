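#' Localization index and flow summaries per SCA
#'
#' For each SCA and year, the localization index (LI) is the proportion of
#' the SCA residents' discharges that occur at hospitals inside the same
#' SCA: \deqn{LI(s) = \frac{\sum \{count: origin \in s, hospital \in s\}}
#' {\sum \{count: origin \in s\}}.} A high LI marks a homogeneous SCA with
#' localized care; self-loop flows (patient and hospital in the same ZCTA)
#' are internal by construction. An SCA whose residents record no
#' discharges carries `li = NA` and is excluded from downstream panels.
#'
#' @param flows flow data frame (columns `year`, `origin_zcta`,
#'   `hospital_id`, `hospital_zcta`, `count`); may span several years.
#' @param partition an [sca_partition] covering every ZCTA in `flows`.
#' @param admission_based if `TRUE`, compute the admission-based variant
#'   (denominator = discharges at the SCA's hospitals) instead of the
#'   default residence-based index.
#' @return data frame with one row per (year, sca_id): `year`, `algorithm`,
#'   `sca_id`, `li`, `resident_discharges`, `internal_discharges`,
#'   `n_zctas`, `n_hospitals`.
#' @export
localization_index <- function(flows, partition, admission_based = FALSE) {
  lab <- partition_labels(partition)
  miss <- setdiff(unique(c(flows$origin_zcta, flows$hospital_zcta)), names(lab))
  if (length(miss)) {
    stopf("ZCTA(s) in flows but absent from partition: %s",
          paste(utils::head(miss, 10), collapse = ", "))
  }
  os <- unname(lab[flows$origin_zcta])
  hs <- unname(lab[flows$hospital_zcta])
  denom_sca <- if (admission_based) hs else os
  scas <- sort(unique(lab))
  out <- expand.grid(sca_id = scas, year = sort(unique(flows$year)),
                     KEEP.OUT.ATTRS = FALSE)
  key <- paste(denom_sca, flows$year)
  denom <- rowsum(flows$count, key)
  internal <- rowsum(flows$count * (os == hs), key)
  okey <- paste(out$sca_id, out$year)
  out$resident_discharges <- as.integer(denom[match(okey, rownames(denom)), 1L])
  out$internal_discharges <- as.integer(internal[match(okey, rownames(internal)), 1L])
  out$resident_discharges[is.na(out$resident_discharges)] <- 0L
  out$internal_discharges[is.na(out$internal_discharges)] <- 0L
  out$li <- ifelse(out$resident_discharges > 0,
                   out$internal_discharges / out$resident_discharges, NA_real_)
  nz <- table(lab)
  out$n_zctas <- as.integer(nz[as.character(out$sca_id)])
  hosp <- unique(flows[, c("hospital_id", "hospital_zcta")])
  nh <- table(unname(lab[hosp$hospital_zcta]))
  out$n_hospitals <- as.integer(nh[as.character(out$sca_id)])
  out$n_hospitals[is.na(out$n_hospitals)] <- 0L
  alg <- if (inherits(partition, "sca_partition")) partition$algorithm else "unknown"
  out$algorithm <- alg
  out[, c("year", "algorithm", "sca_id", "li", "resident_discharges",
          "internal_discharges", "n_zctas", "n_hospitals")]
}

#' Assign hospitals to SCAs via their ZCTA
#'
#' Each hospital inherits the SCA of the ZCTA it sits in.
#'
#' @param hospitals data frame with columns `hospital_id`, `zcta`.
#' @param partition an [sca_partition].
#' @param strict error (default) or drop-with-message when a hospital's
#'   ZCTA is not in the partition.
#' @return data frame `hospital_id`, `zcta`, `sca_id`.
#' @export
assign_hospitals <- function(hospitals, partition, strict = TRUE) {
  lab <- partition_labels(partition)
  miss <- !(hospitals$zcta %in% names(lab))
  if (any(miss)) {
    if (strict) {
      stopf("hospital(s) in ZCTAs absent from partition: %s",
            paste(hospitals$hospital_id[miss], collapse = ", "))
    }
    msgf("assign_hospitals: dropped %d hospital(s) outside the partition",
         sum(miss))
    hospitals <- hospitals[!miss, , drop = FALSE]
  }
  data.frame(hospital_id = hospitals$hospital_id,
             zcta = hospitals$zcta,
             sca_id = unname(lab[hospitals$zcta]))
}
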