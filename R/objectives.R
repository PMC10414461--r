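#' Weighted modularity of a partition
#'
#' Computes \eqn{Q = \sum_c \left[ w_c/W - \gamma (s_c/2W)^2 \right]} where
#' \eqn{w_c} is the internal weight of community c (self-loops included),
#' \eqn{s_c} its total node strength (self-loops counted twice), W the total
#' edge weight of the network, and \eqn{\gamma} the resolution parameter.
#'
#' @param network graph from [build_network()].
#' @param partition an [sca_partition] or named label vector covering every
#'   node of the network.
#' @param resolution resolution parameter \eqn{\gamma > 0} (default 1, the
#'   classical Newman-Girvan objective).
#' @return modularity value (scalar).
#' @export
modularity_weighted <- function(network, partition, resolution = 1) {
  net <- net_internal(network)
  comm <- partition_index(net, partition)
  modularity_internal(net, comm, resolution)
}

# partition (named labels) -> integer community index 1..K aligned with net
partition_index <- function(net, partition) {
  lab <- partition_labels(partition)
  missing <- setdiff(net$names, names(lab))
  if (length(missing)) {
    stopf("node(s) missing from partition: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  }
  match(lab[net$names], unique(lab[net$names]))
}

modularity_internal <- function(net, comm, resolution) {
  K <- max(comm)
  s_c <- rowsum_vec(net$k, comm, K)
  w_c <- internal_weight(net, comm, K)
  sum(w_c / net$W - resolution * (s_c / (2 * net$W))^2)
}

# internal weight per community: non-loop edges with both ends inside
# (counted once) plus self-loops.
internal_weight <- function(net, comm, K) {
  w_c <- rowsum_vec(net$self_w, comm, K)
  for (i in seq_len(net$n)) {
    nb <- net$nb_idx[[i]]
    if (!length(nb)) next
    same <- comm[nb] == comm[i]
    # each undirected edge visited from both ends -> weight/2
    w_c[comm[i]] <- w_c[comm[i]] + sum(net$nb_w[[i]][same]) / 2
  }
  w_c
}

rowsum_vec <- function(x, g, K) {
  out <- numeric(K)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Two-level map-equation codelength of a partition
#'
#' The expected per-step description length, in bits, of a random walk on
#' the weighted undirected network under a two-level codebook:
#' \deqn{L(M) = q H(Q) + \sum_m (q_m + p_m) H(P_m)}
#' with node visit rates proportional to strength (\eqn{p_\alpha =
#' k_\alpha/2W}), module exit rates \eqn{q_m} proportional to the module's
#' boundary weight, and no teleportation. A single-module partition has
#' codelength equal to the entropy of the node visit rates.
#'
#' @inheritParams modularity_weighted
#' @return codelength in bits (scalar).
#' @export
map_codelength <- function(network, partition) {
  net <- net_internal(network)
  comm <- partition_index(net, partition)
  codelength_internal(net, comm)
}

codelength_internal <- function(net, comm) {
  K <- max(comm)
  m2 <- 2 * net$W
  p <- net$k / m2
  S_c <- rowsum_vec(net$k, comm, K)
  int_c <- internal_weight(net, comm, K)
  q_m <- (S_c - 2 * int_c) / m2       # boundary weight fraction per module
  p_m <- S_c / m2
  q <- sum(q_m)
  plogp(q) - 2 * sum(plogp(q_m)) + sum(plogp(q_m + p_m)) - sum(plogp(p))
}
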