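# Small study configurations used across tests; sized for speed, not power.

smallConfig <- function(seed = 1L, ...) {
  args <- list(nGenes = 150L, degFraction = 0.3, nModulesPerCondition = 2L,
               moduleSizeRange = c(5L, 8L), nSamplesPerGroup = 5L,
               intraModuleEdgeProb = 0.9, backgroundEdgeProb = 0.02,
               nPlantedCrosstalkPairs = 1L, crosstalkEdgesPerPair = 5L,
               nRegulatorsPerClass = 4L, targetsPerRegulator = 10L,
               nPlantedPivots = 2L, rngSeed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(syntheticConfig, args)
}

# Brute-force oracle for the overlap test: enumerate all C(N, M) draws of the
# second set against a fixed first set {1..n} and count overlaps >= m.
enumOverlapP <- function(N, M, n, m) {
  if (m == 0) return(1)
  draws <- combn(N, M)
  mean(apply(draws, 2, function(d) sum(d <= n)) >= m)
}

# Named clique graph helper.
namedClique <- function(n, prefix) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
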