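#' Generate a synthetic interaction network with planted modules and crosstalk
#'
#' Builds an undirected simple graph over the configured gene universe:
#' an Erdos-Renyi background at `backgroundEdgeProb`, densified within every
#' planted module (both conditions) at `intraModuleEdgeProb`, plus — for each
#' of `nPlantedCrosstalkPairs` cross-condition module pairs chosen
#' deterministically from the planted modules — exactly
#' `crosstalkEdgesPerPair` extra edges between the two modules' exclusive gene
#' sets. The chosen pairs are recorded in the returned ground truth.
#'
#' Crosstalk edges are restricted to module-exclusive genes so that the
#' overlap signal (shared genes) and the crosstalk signal (inter-module edges)
#' of a pair stay independently plantable.
#'
#' @param config a [SyntheticConfig-class].
#' @param truth a [GroundTruth-class] holding planted modules for (typically
#'   two) conditions, from [generateExpression()].
#' @return list with elements `network` (an [igraph::igraph] with vertex
#'   names = gene ids) and `truth` (updated with the planted crosstalk pairs).
#' @examples
#' cfg <- syntheticConfig(nGenes = 150, degFraction = 0.4,
#'                        nModulesPerCondition = 2, moduleSizeRange = c(5, 8),
#'                        nPlantedCrosstalkPairs = 1, crosstalkEdgesPerPair = 4,
#'                        rngSeed = 3)
#' tr <- generateExpression(cfg, "UC")$truth
#' tr <- generateExpression(cfg, "CRC", truth = tr)$truth
#' net <- generateNetwork(cfg, tr)
#' igraph::vcount(net$network)
#' @export
generateNetwork <- function(config, truth) {
  stopifnot(is(config, "SyntheticConfig"), is(truth, "GroundTruth"))
  conds <- names(truth@modules)
  genes <- geneIds(config@nGenes)

  res <- withSeed(deriveSeed(config@rngSeed, "network"), {
    g <- igraph::sample_gnp(config@nGenes, config@backgroundEdgeProb,
                            directed = FALSE)
    igraph::V(g)$name <- genes

    # densify planted modules
    for (cond in conds) {
      for (mod in truth@modules[[cond]]) {
        pairs <- t(combn(mod, 2L))
        keep <- runif(nrow(pairs)) < config@intraModuleEdgeProb
        if (any(keep)) {
          g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
        }
      }
    }
    g <- igraph::simplify(g)

    # choose planted crosstalk pairs across the first two conditions
    ctp <- truth@crosstalkPairs[0, ]
    if (config@nPlantedCrosstalkPairs > 0L) {
      if (length(conds) < 2L)
        stop("planting crosstalk pairs requires planted modules for two conditions")
      condA <- conds[1]; condB <- conds[2]
      idsA <- names(truth@modules[[condA]])
      idsB <- names(truth@modules[[condB]])
      allPairs <- expand.grid(moduleA = idsA, moduleB = idsB,
                              stringsAsFactors = FALSE)
      if (nrow(allPairs) < config@nPlantedCrosstalkPairs)
        stop(sprintf("cannot plant %d crosstalk pairs from %d available module pairs",
                     config@nPlantedCrosstalkPairs, nrow(allPairs)))
      sel <- allPairs[sample(nrow(allPairs), config@nPlantedCrosstalkPairs), ,
                      drop = FALSE]
      for (i in seq_len(nrow(sel))) {
        gA <- truth@modules[[condA]][[sel$moduleA[i]]]
        gB <- truth@modules[[condB]][[sel$moduleB[i]]]
        exA <- setdiff(gA, gB)
        exB <- setdiff(gB, gA)
        cand <- crossPairs(exA, exB)
        present <- edgeKeys(cand[, 1], cand[, 2]) %in%
          edgeKeys(igraph::as_edgelist(g)[, 1], igraph::as_edgelist(g)[, 2])
        cand <- cand[!present, , drop = FALSE]
        if (nrow(cand) < config@crosstalkEdgesPerPair)
          stop(sprintf(
            "crosstalk pair %s-%s: requested %d extra edges but only %d free pairs between exclusive sets",
            sel$moduleA[i], sel$moduleB[i], config@crosstalkEdgesPerPair,
            nrow(cand)))
        pick <- cand[sample(nrow(cand), config@crosstalkEdgesPerPair), ,
                     drop = FALSE]
        g <- igraph::add_edges(g, t(pick))
      }
      ctp <- data.frame(conditionA = condA, moduleA = sel$moduleA,
                        conditionB = condB, moduleB = sel$moduleB,
                        stringsAsFactors = FALSE)
    }
    g <- igraph::simplify(g)
    list(g = g, ctp = ctp)
  })

  # sanity: planted modules should be at least as dense as the background
  if (config@intraModuleEdgeProb > config@backgroundEdgeProb) {
    bg <- igraph::edge_density(res$g)
    for (cond in conds) for (mod in truth@modules[[cond]]) {
      d <- igraph::edge_density(igraph::induced_subgraph(res$g, mod))
      if (!is.nan(d) && d < bg)
        warning(sprintf("planted module in '%s' sparser (%.3f) than background (%.3f)",
                        cond, d, bg))
    }
  }

  truth@crosstalkPairs <- res$ctp
  list(network = res$g, truth = truth)
}
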