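#' Louvain community detection on a discharge network
#'
#' Multi-level greedy maximization of weighted modularity
#' ([modularity_weighted()]). Nodes are visited in a seeded shuffled order;
#' a node moves to the neighboring community with the largest strictly
#' positive modularity gain (ties among best candidates broken by seeded
#' uniform choice, with staying put preferred when it is among the best).
#' When a pass produces no move, communities are aggregated into super-nodes
#' and the procedure repeats until no level improves modularity. Modularity
#' is monotone non-decreasing over accepted moves and levels.
#'
#' @param network graph from [build_network()].
#' @param resolution resolution parameter \eqn{\gamma > 0}; 1 recovers
#'   classical modularity, large values drive the partition toward
#'   singletons.
#' @param seed integer seed controlling visit order and tie-breaks.
#' @return an [sca_partition] with attribute `"modularity"`.
#' @export
louvain <- function(network, resolution = 1, seed = NULL) {
  if (resolution <= 0) stopf("resolution must be > 0")
  net <- net_internal(network)
  if (net$n == 0) stopf("empty network")
  run_seeded(seed, function() {
    membership <- seq_len(net$n)
    cur <- net
    repeat {
      res <- louvain_level(cur, resolution)
      if (!res$moved) break
      membership <- res$comm[membership]
      cur <- aggregate_net(cur, res$comm)
    }
    labels <- membership - 1L
    names(labels) <- net$names
    p <- sca_partition(labels,
                       year = igraph::graph_attr(network, "year") %||% NA_integer_,
                       algorithm = "louvain")
    attr(p, "modularity") <- modularity_internal(net, partition_index(net, p),
                                                 resolution)
    p
  })
}

# One local-moving phase; returns compacted community index per node.
louvain_level <- function(net, gamma) {
  n <- net$n
  comm <- seq_len(n)
  tot <- net$k            # community total strength
  W <- net$W
  moved_any <- FALSE
  eps <- 1e-12
  repeat {
    moved <- 0L
    for (i in sample.int(n)) {
      ci <- comm[i]
      ki <- net$k[i]
      nb <- net$nb_idx[[i]]
      # weight from i to each candidate community
      if (length(nb)) {
        k_in <- rowsum(net$nb_w[[i]], comm[nb])
        cand <- as.integer(rownames(k_in))
        k_in <- k_in[, 1L]
      } else {
        cand <- integer(0)
        k_in <- numeric(0)
      }
      if (!(ci %in% cand)) {
        cand <- c(cand, ci)
        k_in <- c(k_in, 0)
      }
      tot[ci] <- tot[ci] - ki
      gain <- k_in / W - gamma * tot[cand] * ki / (2 * W^2)
      best <- max(gain)
      top <- cand[gain >= best - eps]
      if (ci %in% top) {
        tot[ci] <- tot[ci] + ki
      } else {
        new <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
        comm[i] <- new
        tot[new] <- tot[new] + ki
        moved <- moved + 1L
      }
    }
    if (moved == 0L) break
    moved_any <- TRUE
  }
  comm <- match(comm, unique(comm))
  list(comm = comm, moved = moved_any, K = max(comm))
}

# Collapse communities into super-nodes; internal weight becomes self-loops.
aggregate_net <- function(net, comm) {
  K <- max(comm)
  self_w <- rowsum_vec(net$self_w, comm, K)
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (i in seq_len(net$n)) {
    nb <- net$nb_idx[[i]]
    if (!length(nb)) next
    keep <- nb > i          # each undirected edge once
    if (!any(keep)) next
    ef <- c(ef, rep.int(comm[i], sum(keep)))
    et <- c(et, comm[nb[keep]])
    ew <- c(ew, net$nb_w[[i]][keep])
  }
  loop <- ef == et
  if (any(loop)) {
    sw <- rowsum(ew[loop], ef[loop])
    self_w[as.integer(rownames(sw))] <- self_w[as.integer(rownames(sw))] + sw[, 1L]
    ef <- ef[!loop]; et <- et[!loop]; ew <- ew[!loop]
  }
  nb_idx <- vector("list", K)
  nb_w <- vector("list", K)
  if (length(ef)) {
    a <- pmin(ef, et); b <- pmax(ef, et)
    agg <- rowsum(ew, paste(a, b))
    ab <- strsplit(rownames(agg), " ", fixed = TRUE)
    a <- as.integer(vapply(ab, `[`, "", 1L))
    b <- as.integer(vapply(ab, `[`, "", 2L))
    w <- agg[, 1L]
    for (e in seq_along(a)) {
      nb_idx[[a[e]]] <- c(nb_idx[[a[e]]], b[e]); nb_w[[a[e]]] <- c(nb_w[[a[e]]], w[e])
      nb_idx[[b[e]]] <- c(nb_idx[[b[e]]], a[e]); nb_w[[b[e]]] <- c(nb_w[[b[e]]], w[e])
    }
  }
  for (i in seq_len(K)) {
    if (is.null(nb_idx[[i]])) { nb_idx[[i]] <- integer(0); nb_w[[i]] <- numeric(0) }
  }
  k <- vapply(nb_w, sum, 0) + 2 * self_w
  list(n = K, names = as.character(seq_len(K)), nb_idx = nb_idx, nb_w = nb_w,
       self_w = self_w, k = k, W = net$W)
}
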