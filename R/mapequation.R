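#' Two-level map-equation community detection
#'
#' Greedy Louvain-style search minimizing the two-level map-equation
#' codelength ([map_codelength()]): nodes are visited in seeded shuffled
#' passes, each node moves to the neighboring module that most decreases the
#' codelength, only strictly improving moves are accepted (so the
#' codelength is monotone non-increasing), and modules are aggregated into
#' super-nodes between levels until no move improves. Visit rates are
#' strength-proportional (undirected random walk, no teleportation).
#' Disconnected components never merge (merging them cannot decrease the
#' codelength); an isolated node forms its own SCA.
#'
#' @param network graph from [build_network()].
#' @param seed integer seed controlling visit order.
#' @return an [sca_partition] with attribute `"codelength"` (bits).
#' @export
mapeq_two_level <- function(network, seed = NULL) {
  net <- net_internal(network)
  if (net$n == 0) stopf("empty network")
  run_seeded(seed, function() {
    membership <- seq_len(net$n)
    cur <- net
    repeat {
      res <- mapeq_level(cur)
      if (!res$moved) break
      membership <- res$comm[membership]
      cur <- aggregate_net(cur, res$comm)
    }
    labels <- membership - 1L
    names(labels) <- net$names
    p <- sca_partition(labels,
                       year = igraph::graph_attr(network, "year") %||% NA_integer_,
                       algorithm = "mapeq")
    attr(p, "codelength") <- codelength_internal(net, partition_index(net, p))
    p
  })
}

mapeq_level <- function(net) {
  n <- net$n
  comm <- seq_len(n)
  m2 <- 2 * net$W
  S <- net$k                       # module total strength
  Int <- net$self_w                # module internal weight (abs units)
  qm <- (S - 2 * Int) / m2
  q <- sum(qm)
  term <- function(q_m, p_m) -2 * plogp(q_m) + plogp(q_m + p_m)
  eps <- 1e-12
  moved_any <- FALSE
  repeat {
    moved <- 0L
    for (i in sample.int(n)) {
      nb <- net$nb_idx[[i]]
      if (!length(nb)) next
      ci <- comm[i]
      ki <- net$k[i]
      si <- net$self_w[i]
      k_to <- rowsum(net$nb_w[[i]], comm[nb])
      cands <- as.integer(rownames(k_to))
      kvals <- k_to[, 1L]
      kia <- if (ci %in% cands) kvals[match(ci, cands)] else 0
      # module a after removing i
      Sa <- S[ci] - ki
      Ia <- Int[ci] - kia - si
      qa <- (Sa - 2 * Ia) / m2
      base_a <- term(qm[ci], S[ci] / m2)
      sel <- cands != ci
      candv <- cands[sel]
      kib <- kvals[sel]
      if (!length(candv)) next
      best_d <- 0
      best_m <- ci
      best_state <- NULL
      for (j in seq_along(candv)) {
        b <- candv[j]
        Sb <- S[b] + ki
        Ib <- Int[b] + kib[j] + si
        qb <- (Sb - 2 * Ib) / m2
        qnew <- q - qm[ci] - qm[b] + qa + qb
        d <- (plogp(qnew) - plogp(q)) +
          (term(qa, Sa / m2) - base_a) +
          (term(qb, Sb / m2) - term(qm[b], S[b] / m2))
        if (d < best_d - eps) {
          best_d <- d
          best_m <- b
          best_state <- list(Sb = Sb, Ib = Ib, qb = qb, qnew = qnew)
        }
      }
      if (best_m != ci) {
        S[ci] <- Sa; Int[ci] <- Ia; qm[ci] <- qa
        S[best_m] <- best_state$Sb; Int[best_m] <- best_state$Ib
        qm[best_m] <- best_state$qb
        q <- best_state$qnew
        comm[i] <- best_m
        moved <- moved + 1L
      }
    }
    if (moved == 0L) break
    moved_any <- TRUE
  }
  comm <- match(comm, unique(comm))
  list(comm = comm, moved = moved_any, K = max(comm))
}
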