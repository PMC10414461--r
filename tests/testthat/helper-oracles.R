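# Independent oracles and fixture builders used across the suite. These
# deliberately take naive routes (dense matrices, double loops, explicit
# entropies) so they share no code with the implementation they check.

# Build an undirected weighted igraph from an edge table.
make_graph <- function(from, to, weight, year = 2012L) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(c(from, to))))
  )
  igraph::set_graph_attr(g, "year", year)
}

# Dense adjacency with the strength convention: loops contribute twice on
# the diagonal, so rowSums(A) is node strength and sum(A)/2 total weight.
dense_adjacency <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  A <- matrix(0, n, n, dimnames = list(nm, nm))
  ed <- igraph::as_data_frame(g, what = "edges")
  for (e in seq_len(nrow(ed))) {
    i <- ed$from[e]; j <- ed$to[e]; w <- ed$weight[e]
    if (i == j) {
      A[i, i] <- A[i, i] + 2 * w
    } else {
      A[i, j] <- A[i, j] + w
      A[j, i] <- A[j, i] + w
    }
  }
  A
}

# Naive double-loop modularity.
naive_modularity <- function(g, labels, gamma = 1) {
  A <- dense_adjacency(g)
  lab <- labels[rownames(A)]
  W <- sum(A) / 2
  q <- 0
  for (c in unique(lab)) {
    inc <- lab == c
    w_c <- sum(A[inc, inc, drop = FALSE]) / 2
    s_c <- sum(A[inc, , drop = FALSE])
    q <- q + w_c / W - gamma * (s_c / (2 * W))^2
  }
  q
}

# Naive two-level map-equation codelength via explicit entropies.
naive_codelength <- function(g, labels) {
  A <- dense_adjacency(g)
  lab <- labels[rownames(A)]
  tot <- sum(A)
  p <- rowSums(A) / tot
  H <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  mods <- unique(lab)
  q_m <- vapply(mods, function(c) {
    inc <- lab == c
    sum(A[inc, !inc, drop = FALSE]) / tot
  }, numeric(1))
  q <- sum(q_m)
  L <- if (q > 0) q * H(q_m / q) else 0
  for (k in seq_along(mods)) {
    inc <- lab == mods[k]
    tot_m <- q_m[k] + sum(p[inc])
    if (tot_m > 0) L <- L + tot_m * H(c(q_m[k], p[inc]) / tot_m)
  }
  L
}

# All set partitions of n elements as restricted-growth assignment vectors.
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(assign, kmax) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (c in seq_len(kmax + 1L)) rec(c(assign, c), max(kmax, c))
  }
  rec(integer(0), 0L)
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small planted-structure config used by many tests.
small_config <- function(seed = 7, ...) {
  synthetic_config(n_scas = 4, zctas_per_sca = 10, hospitals_per_sca = 3,
                   within_rate = 20, between_rate = 0.5, seed = seed, ...)
}

# Random flow table over arbitrary labels (for LI brute-force checks).
random_flow_table <- function(n_records, n_zctas, seed) {
  withr::with_seed(seed, {
    z <- formatC(seq_len(n_zctas), width = 5, flag = "0")
    data.frame(
      year = sample(2012:2013, n_records, replace = TRUE),
      origin_zcta = sample(z, n_records, replace = TRUE),
      hospital_id = paste0("H", sample(5, n_records, replace = TRUE)),
      hospital_zcta = sample(z, n_records, replace = TRUE),
      count = sample(0:20, n_records, replace = TRUE)
    )
  })
}

# Brute-force localization index by explicit row loops.
naive_li <- function(flows, labels) {
  years <- sort(unique(flows$year))
  res <- list()
  for (y in years) {
    fy <- flows[flows$year == y, ]
    for (s in sort(unique(labels))) {
      denom <- 0; inter <- 0
      for (r in seq_len(nrow(fy))) {
        if (labels[fy$origin_zcta[r]] == s) {
          denom <- denom + fy$count[r]
          if (labels[fy$hospital_zcta[r]] == s) inter <- inter + fy$count[r]
        }
      }
      res[[length(res) + 1L]] <- data.frame(
        year = y, sca_id = s,
        li = if (denom > 0) inter / denom else NA_real_
      )
    }
  }
  do.call(rbind, res)
}

# statsmodels GEE reference (independent oracle); NULL if python is absent.
gee_oracle <- function(panel, covariates, outcome = "err",
                       cluster = "hospital_id") {
  script <- system.file("oracle", "gee_oracle.py", package = "sharedcare")
  csv <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".json")
  utils::write.csv(panel, csv, row.names = FALSE)
  status <- suppressWarnings(system2(
    "python", c(script, csv, outcome, cluster,
                paste(covariates, collapse = ","), out),
    stdout = FALSE, stderr = FALSE
  ))
  if (!identical(status, 0L) || !file.exists(out)) return(NULL)
  jsonlite::read_json(out, simplifyVector = TRUE)
}
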