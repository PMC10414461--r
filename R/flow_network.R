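#' Read an origin-destination discharge flow table
#'
#' Parses a CSV of aggregated emergency-department discharge counts between
#' patient-residence zip codes / ZCTAs and hospital locations, one row per
#' (year, origin, hospital). Required columns: `year`, `origin_zcta` (or
#' `origin_zip`), `hospital_id`, `hospital_zcta` (or `hospital_zip`),
#' `count`. Codes are zero-padded to 5 characters on input.
#'
#' @param path CSV file path.
#' @return data frame with columns `year`, `origin_zcta`, `hospital_id`,
#'   `hospital_zcta`, `count`.
#' @export
read_flows <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  orig_col <- intersect(c("origin_zcta", "origin_zip", "origin"), names(df))[1]
  hosp_col <- intersect(c("hospital_zcta", "hospital_zip"), names(df))[1]
  if (is.na(orig_col) || is.na(hosp_col) ||
      !all(c("year", "hospital_id", "count") %in% names(df))) {
    stopf("flows CSV must have columns year, origin_zcta/zip, hospital_id, hospital_zcta/zip, count")
  }
  count <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(count) | count < 0 | count != floor(count))
  if (length(bad)) {
    stopf("malformed count on line(s) %s of %s (must be a nonnegative integer)",
          paste(utils::head(bad + 1L, 10), collapse = ", "), path)
  }
  year <- suppressWarnings(as.integer(df$year))
  badyr <- which(is.na(year))
  if (length(badyr)) {
    stopf("malformed year on line(s) %s of %s",
          paste(utils::head(badyr + 1L, 10), collapse = ", "), path)
  }
  data.frame(
    year = year,
    origin_zcta = pad_zcta(df[[orig_col]]),
    hospital_id = df$hospital_id,
    hospital_zcta = pad_zcta(df[[hosp_col]]),
    count = as.integer(count)
  )
}

#' Read a zip-to-ZCTA crosswalk
#'
#' @param path CSV with columns `zip`, `zcta`.
#' @return named character vector mapping zip code to ZCTA code.
#' @export
read_crosswalk <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("zip", "zcta") %in% names(df))) {
    stopf("crosswalk CSV must have columns zip, zcta")
  }
  zip <- pad_zcta(df$zip)
  if (anyDuplicated(zip)) {
    dup <- unique(zip[duplicated(zip)])
    stopf("crosswalk maps zip(s) %s more than once", paste(dup, collapse = ", "))
  }
  stats::setNames(pad_zcta(df$zcta), zip)
}

#' Convert flow-record zip codes to ZCTAs
#'
#' Replaces both origin and hospital codes by their ZCTA under a
#' many-to-one crosswalk and re-aggregates records that become identical.
#' Total discharge count is conserved (strict mode) or reduced exactly by
#' the dropped records (lenient mode, logged).
#'
#' @param records flow data frame as from [read_flows()].
#' @param crosswalk named vector from [read_crosswalk()].
#' @param strict if `TRUE` (default) any zip missing from the crosswalk is an
#'   error listing the offending zips; if `FALSE` such records are dropped
#'   with a message.
#' @return aggregated flow data frame in ZCTA space.
#' @export
apply_crosswalk <- function(records, crosswalk, strict = TRUE) {
  unknown <- setdiff(unique(c(records$origin_zcta, records$hospital_zcta)),
                     names(crosswalk))
  if (length(unknown)) {
    if (strict) {
      stopf("zip code(s) not in crosswalk: %s", paste(unknown, collapse = ", "))
    }
    keep <- !(records$origin_zcta %in% unknown | records$hospital_zcta %in% unknown)
    msgf("apply_crosswalk: dropped %d record(s) with unmapped zips", sum(!keep))
    records <- records[keep, , drop = FALSE]
  }
  records$origin_zcta <- unname(crosswalk[records$origin_zcta])
  records$hospital_zcta <- unname(crosswalk[records$hospital_zcta])
  aggregate_flows(records)
}

# Sum duplicate (year, origin, hospital_id, hospital_zcta) rows.
aggregate_flows <- function(records) {
  key <- paste(records$year, records$origin_zcta, records$hospital_id,
               records$hospital_zcta, sep = "\r")
  agg <- rowsum(records$count, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    year = as.integer(vapply(parts, `[`, "", 1L)),
    origin_zcta = vapply(parts, `[`, "", 2L),
    hospital_id = vapply(parts, `[`, "", 3L),
    hospital_zcta = vapply(parts, `[`, "", 4L),
    count = as.integer(agg[, 1L])
  )
  rownames(out) <- NULL
  out
}

#' Build the yearly hospital-patient discharge network
#'
#' Nodes are ZCTAs of patient residences or hospitals; the (undirected) edge
#' weight between two ZCTAs is the total number of ED discharges between
#' them in the given year. Flows whose origin equals the hospital ZCTA
#' become self-loops. Total edge weight (self-loops counted once) equals the
#' total discharge count of the year, so discharge conservation can be
#' audited at every stage.
#'
#' @param records flow data frame.
#' @param year integer year to select.
#' @param directed keep flow orientation (origin -> hospital ZCTA) instead of
#'   aggregating across direction. The detection algorithms here operate on
#'   the undirected network; the directed variant is exposed for inspection
#'   only.
#' @return an [igraph][igraph::igraph-package] graph with vertex attribute
#'   `name` (ZCTA), edge attribute `weight`, and graph attribute `year`.
#' @export
build_network <- function(records, year, directed = FALSE) {
  rec <- records[records$year == year, , drop = FALSE]
  if (!nrow(rec)) stopf("no flow records for year %s", year)
  rec <- rec[rec$count > 0, , drop = FALSE]
  u <- rec$origin_zcta
  v <- rec$hospital_zcta
  if (!directed) {
    swap <- u > v
    tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  }
  key <- paste(u, v, sep = "\r")
  agg <- rowsum(rec$count, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, "", 1L),
    to = vapply(parts, `[`, "", 2L),
    weight = as.numeric(agg[, 1L])
  )
  nodes <- sort(unique(c(rec$origin_zcta, rec$hospital_zcta)))
  g <- igraph::graph_from_data_frame(edges, directed = directed,
                                     vertices = data.frame(name = nodes))
  g <- igraph::set_graph_attr(g, "year", as.integer(year))
  g
}

#' Summarize a discharge network
#'
#' @param network graph from [build_network()].
#' @return list with `year`, `n_nodes`, `n_edges`, `total_weight`
#'   (self-loops counted once).
#' @export
network_summary <- function(network) {
  list(
    year = igraph::graph_attr(network, "year"),
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    total_weight = sum(igraph::E(network)$weight)
  )
}

#' Write / read a network in GraphML
#'
#' @param network graph from [build_network()].
#' @param path file path (`.graphml`).
#' @export
write_network <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::E(g)$weight)) stopf("GraphML network lacks edge weights")
  g
}

# --- internal compact representation used by the detection algorithms ------
# adjacency lists over integer node ids; self-loop weights kept separately.
# strength k counts self-loops twice (the usual modularity/map-equation
# convention); W is the total weight with self-loops counted once.
net_internal <- function(network) {
  nm <- igraph::V(network)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(network)))
  n <- length(nm)
  ed <- igraph::as_data_frame(network, what = "edges")
  fi <- match(ed$from, nm)
  ti <- match(ed$to, nm)
  w <- as.numeric(ed$weight)
  loop <- fi == ti
  self_w <- numeric(n)
  if (any(loop)) {
    sw <- rowsum(w[loop], fi[loop])
    self_w[as.integer(rownames(sw))] <- sw[, 1L]
  }
  a <- fi[!loop]; b <- ti[!loop]; ew <- w[!loop]
  ends <- c(a, b)
  other <- c(b, a)
  wts <- c(ew, ew)
  ord <- order(ends)
  ends <- ends[ord]; other <- other[ord]; wts <- wts[ord]
  nb_idx <- vector("list", n)
  nb_w <- vector("list", n)
  if (length(ends)) {
    grp <- split(seq_along(ends), factor(ends, levels = seq_len(n)))
    for (i in seq_len(n)) {
      ix <- grp[[i]]
      nb_idx[[i]] <- other[ix]
      nb_w[[i]] <- wts[ix]
    }
  } else {
    for (i in seq_len(n)) { nb_idx[[i]] <- integer(0); nb_w[[i]] <- numeric(0) }
  }
  k <- vapply(nb_w, sum, 0) + 2 * self_w
  list(n = n, names = nm, nb_idx = nb_idx, nb_w = nb_w,
       self_w = self_w, k = k, W = sum(ew) + sum(self_w))
}
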