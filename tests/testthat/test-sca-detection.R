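# A small planted two-block graph used by the brute-force checks: all
# within-block pairs weight 5, all between-block pairs weight 1.
two_block_graph <- function(n_per_block = 4) {
  nodes <- sprintf("%05d", seq_len(2 * n_per_block))
  block <- rep(1:2, each = n_per_block)
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
      w <- c(w, if (block[i] == block[j]) 5 else 1)
    }
  }
  list(graph = make_graph(from, to, w), block = stats::setNames(block, nodes))
}

two_cliques_graph <- function(k = 4) {
  nodes <- sprintf("%05d", seq_len(2 * k))
  from <- character(0); to <- character(0)
  for (b in 0:1) {
    ix <- nodes[b * k + seq_len(k)]
    for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
      from <- c(from, ix[i]); to <- c(to, ix[j])
    }
  }
  make_graph(from, to, rep(1, length(from)))
}

test_that("modularity matches closed forms and the naive double loop", {
  g2 <- two_cliques_graph(4)
  one <- stats::setNames(rep(0L, 8), igraph::V(g2)$name)
  expect_equal(modularity_weighted(g2, one), 0)
  split <- stats::setNames(rep(0:1, each = 4), igraph::V(g2)$name)
  expect_equal(modularity_weighted(g2, split), 0.5)

  # random weighted graph + random partition vs naive summation
  for (s in 1:5) {
    tbl <- random_flow_table(60, 20, seed = s)
    tbl <- tbl[tbl$count > 0, ]
    g <- build_network(tbl, 2012)
    lab <- withr::with_seed(s, stats::setNames(
      sample(0:3, igraph::vcount(g), replace = TRUE), igraph::V(g)$name))
    expect_equal(modularity_weighted(g, lab, resolution = 1.3),
                 naive_modularity(g, lab, gamma = 1.3))
  }
})

test_that("map codelength matches explicit entropies and the one-module limit", {
  g2 <- two_cliques_graph(4)
  one <- stats::setNames(rep(0L, 8), igraph::V(g2)$name)
  # q = 0: codelength is the entropy of the node visit rates
  k <- igraph::strength(g2)
  p <- k / sum(k)
  expect_equal(map_codelength(g2, one), -sum(p * log2(p)))
  split <- stats::setNames(rep(0:1, each = 4), igraph::V(g2)$name)
  expect_lt(map_codelength(g2, split), map_codelength(g2, one))

  for (s in 1:5) {
    tbl <- random_flow_table(60, 15, seed = 10 + s)
    tbl <- tbl[tbl$count > 0, ]
    g <- build_network(tbl, 2012)
    lab <- withr::with_seed(s, stats::setNames(
      sample(0:2, igraph::vcount(g), replace = TRUE), igraph::V(g)$name))
    expect_equal(map_codelength(g, lab), naive_codelength(g, lab))
  }
})

test_that("Louvain attains the exhaustive modularity maximum on 8 nodes", {
  tb <- two_block_graph(4)
  parts <- enumerate_partitions(8)
  nodes <- igraph::V(tb$graph)$name
  best <- max(vapply(parts, function(a) {
    naive_modularity(tb$graph, stats::setNames(a, nodes))
  }, numeric(1)))
  p <- louvain(tb$graph, seed = 1)
  expect_equal(attr(p, "modularity"), best, tolerance = 1e-12)
  expect_equal(ari(p$labels[nodes], tb$block), 1)
})

test_that("map-equation search attains the exhaustive codelength minimum", {
  tb <- two_block_graph(4)
  parts <- enumerate_partitions(8)
  nodes <- igraph::V(tb$graph)$name
  lens <- vapply(parts, function(a) {
    naive_codelength(tb$graph, stats::setNames(a, nodes))
  }, numeric(1))
  p <- mapeq_two_level(tb$graph, seed = 1)
  expect_equal(attr(p, "codelength"), min(lens), tolerance = 1e-12)
  # the search lands on the same partition the exhaustive argmin selects
  expect_equal(ari(p$labels[nodes], parts[[which.min(lens)]]), 1)
})

test_that("all three algorithms split disconnected cliques identically", {
  g <- two_cliques_graph(5)
  truth <- rep(0:1, each = 5)
  for (s in c(1, 7)) {
    for (alg in c("louvain", "slpa", "mapeq")) {
      p <- detect_scas(g, alg, seed = s)
      expect_equal(ari(p$labels[igraph::V(g)$name], truth), 1,
                   info = paste(alg, "seed", s))
    }
  }
})

test_that("huge resolution drives Louvain to singletons", {
  g <- two_cliques_graph(4)
  p <- louvain(g, resolution = 1e6, seed = 3)
  expect_equal(length(unique(p$labels)), igraph::vcount(g))
})

test_that("detection is seed deterministic and Louvain agrees with igraph", {
  gen <- generate_flows(small_config(seed = 19))
  net <- build_network(gen$flows, 2014)
  for (alg in c("louvain", "slpa", "mapeq")) {
    p1 <- detect_scas(net, alg, seed = 42)
    p2 <- detect_scas(net, alg, seed = 42)
    expect_identical(p1$labels, p2$labels, info = alg)
  }
  # independent cross-check of the modularity route
  ours <- louvain(net, seed = 5)
  ig <- igraph::cluster_louvain(igraph::simplify(net, remove.loops = FALSE))
  expect_gte(attr(ours, "modularity") + 1e-9,
             modularity_weighted(net, stats::setNames(
               igraph::membership(ig)[igraph::V(net)$name] - 1,
               igraph::V(net)$name)) - 0.02)
  expect_equal(ari(ours$labels, igraph::membership(ig)[names(ours$labels)]), 1)
})

test_that("SLPA planted-partition recovery averages ARI >= 0.9 over seeds", {
  gen <- generate_flows(small_config(seed = 23))
  net <- build_network(gen$flows, 2012)
  truth <- gen$partition$labels
  aris <- vapply(1:20, function(s) {
    p <- slpa(net, seed = s)
    ari(p$labels[names(truth)], truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("threshold 1 keeps a single dominant label per node", {
  gen <- generate_flows(small_config(seed = 29))
  net <- build_network(gen$flows, 2012)
  p <- slpa(net, threshold = 1, seed = 2)
  expect_true(all(p$labels %in% 0:(igraph::vcount(net) - 1)))
  expect_length(p$labels, igraph::vcount(net))
})

test_that("relabeling canonicalizes and preserves class structure", {
  lab <- c(a = 7L, b = 7L, c = 2L)
  expect_identical(relabel_partition(lab), c(a = 0L, b = 0L, c = 1L))
  expect_identical(relabel_partition(relabel_partition(lab)),
                   relabel_partition(lab))
  for (s in 1:5) {
    raw <- withr::with_seed(s, stats::setNames(
      sample(c(3L, 9L, 40L), 30, replace = TRUE), paste0("z", 1:30)))
    can <- relabel_partition(raw)
    expect_equal(ari(raw, can), 1)
    expect_equal(sort(unique(unname(can))), seq_along(unique(raw)) - 1L)
  }
})

test_that("partition CSV round-trips", {
  gen <- generate_flows(small_config(seed = 31))
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition(gen$partition, path)
  back <- read_partition(path)
  expect_identical(back$labels[names(gen$partition$labels)],
                   gen$partition$labels)
})
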