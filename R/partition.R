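#' Shared care area partitions
#'
#' A partition assigns every ZCTA of a discharge network to exactly one
#' shared care area (SCA). Labels are small integers `0..K-1`; the object
#' additionally records the year of the network and the detection algorithm
#' that produced it.
#'
#' @param labels named integer vector mapping ZCTA code to SCA label.
#' @param year integer year of the underlying network (or `NA`).
#' @param algorithm character tag, e.g. `"louvain"`, `"slpa"`, `"mapeq"`,
#'   `"planted"`.
#' @param relabel relabel to `0..K-1` in order of first appearance
#'   (default `TRUE`).
#' @return An object of class `sca_partition`.
#' @export
sca_partition <- function(labels, year = NA_integer_, algorithm = "unknown",
                          relabel = TRUE) {
  if (is.null(names(labels)) || anyNA(names(labels)) || any(names(labels) == "")) {
    stopf("partition labels must be a named vector (names = ZCTA codes)")
  }
  if (anyDuplicated(names(labels))) {
    stopf("duplicate ZCTA in partition: %s",
          paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  }
  if (anyNA(labels)) stopf("partition labels must not contain NA")
  obj <- structure(
    list(labels = labels, year = as.integer(year), algorithm = algorithm),
    class = "sca_partition"
  )
  if (relabel) relabel_partition(obj) else obj
}

#' Relabel a partition to consecutive integers
#'
#' Maps labels to `0..K-1` in order of first appearance. Idempotent: the
#' equivalence classes are unchanged.
#'
#' @param partition an [sca_partition] or a named label vector.
#' @return Same type as the input, with canonical labels.
#' @export
relabel_partition <- function(partition) {
  lab <- partition_labels(partition)
  new <- match(lab, unique(lab)) - 1L
  names(new) <- names(lab)
  if (inherits(partition, "sca_partition")) {
    partition$labels <- new
    partition
  } else {
    new
  }
}

# Extract the named label vector from either representation.
partition_labels <- function(partition) {
  lab <- if (inherits(partition, "sca_partition")) partition$labels else partition
  if (is.null(names(lab))) stopf("partition must carry ZCTA names")
  lab
}

#' @export
print.sca_partition <- function(x, ...) {
  cat(sprintf("<sca_partition> %d ZCTAs in %d SCAs (algorithm=%s, year=%s)\n",
              length(x$labels), length(unique(x$labels)), x$algorithm,
              ifelse(is.na(x$year), "NA", x$year)))
  invisible(x)
}

#' Write / read a partition as CSV
#'
#' The on-disk format is a two-column CSV `zcta, sca_id`; year and algorithm
#' travel in the file name or the caller's bookkeeping. Externally supplied
#' partitions (e.g. from other detection software) can be read with
#' [read_partition()] and used everywhere an internally detected one can.
#'
#' @param partition an [sca_partition].
#' @param path file path.
#' @return `write_partition` returns `path` invisibly; `read_partition`
#'   returns an [sca_partition].
#' @export
write_partition <- function(partition, path) {
  lab <- partition_labels(partition)
  utils::write.csv(
    data.frame(zcta = names(lab), sca_id = unname(lab)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_partition
#' @param year,algorithm metadata attached to the partition read back.
#' @export
read_partition <- function(path, year = NA_integer_, algorithm = "external") {
  df <- utils::read.csv(path, colClasses = c(zcta = "character"))
  if (!all(c("zcta", "sca_id") %in% names(df))) {
    stopf("partition CSV must have columns zcta, sca_id")
  }
  lab <- as.integer(df$sca_id)
  names(lab) <- pad_zcta(df$zcta)
  sca_partition(lab, year = year, algorithm = algorithm, relabel = FALSE)
}
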