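#' Delineate shared care areas on a discharge network
#'
#' Dispatcher over the three implemented community detection algorithms.
#'
#' @param network graph from [build_network()].
#' @param algorithm `"louvain"` (modularity maximization), `"slpa"`
#'   (speaker-listener label propagation), or `"mapeq"` (two-level map
#'   equation).
#' @param resolution Louvain resolution (default 1).
#' @param iterations,threshold SLPA rounds and post-processing threshold.
#' @param seed integer seed.
#' @return an [sca_partition].
#' @export
detect_scas <- function(network, algorithm = c("louvain", "slpa", "mapeq"),
                        resolution = 1, iterations = 100, threshold = 0.5,
                        seed = NULL) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    louvain = louvain(network, resolution = resolution, seed = seed),
    slpa = slpa(network, iterations = iterations, threshold = threshold,
                seed = seed),
    mapeq = mapeq_two_level(network, seed = seed)
  )
}
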