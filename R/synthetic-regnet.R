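#' Generate synthetic bipartite regulator-target networks
#'
#' Simulates the four regulator classes the pipeline integrates — transcription
#' factors (`TF`), `miRNA`, `virus_protein` and `virus_miRNA` — with
#' `nRegulatorsPerClass` regulators each. `nPlantedPivots` regulators (spread
#' round-robin over the classes) are planted as pivots of the planted
#' crosstalk module pairs: each receives at least `max(2, ceiling(0.5 x
#' module size))` targets inside each module of its pair, topped up with
#' uniform decoy targets to `targetsPerRegulator`. All other regulators draw
#' `targetsPerRegulator` targets uniformly from the gene universe. Each edge
#' carries an evidence tag (`validated` for planted in-module regulations,
#' otherwise sampled), which downstream statistics ignore.
#'
#' @param config a [SyntheticConfig-class].
#' @param truth a [GroundTruth-class] with planted crosstalk pairs (from
#'   [generateNetwork()]); required when `nPlantedPivots > 0`.
#' @return list with elements `regnet` (data.frame with columns `regulator`,
#'   `target`, `class`, `evidence`; no duplicate regulator-target pairs) and
#'   `truth` (updated with the planted pivots).
#' @export
generateRegnet <- function(config, truth) {
  stopifnot(is(config, "SyntheticConfig"), is(truth, "GroundTruth"))
  if (config@nPlantedPivots > 0L && nrow(truth@crosstalkPairs) == 0L)
    stop("planting pivots requires planted crosstalk pairs in the ground truth")

  classes <- c("TF", "miRNA", "virus_protein", "virus_miRNA")
  prefix <- c(TF = "TF", miRNA = "miR", virus_protein = "vp",
              virus_miRNA = "vmiR")
  genes <- geneIds(config@nGenes)

  res <- withSeed(deriveSeed(config@rngSeed, "regnet"), {
    regs <- data.frame(
      regulator = unlist(lapply(classes, function(cl)
        sprintf("%s%02d", prefix[[cl]], seq_len(config@nRegulatorsPerClass)))),
      class = rep(classes, each = config@nRegulatorsPerClass),
      stringsAsFactors = FALSE
    )
    nPiv <- config@nPlantedPivots
    pivotIdx <- integer(0)
    if (nPiv > 0L) {
      # round-robin over classes: first regulator of each class, then second, ...
      ord <- order(rep(seq_len(config@nRegulatorsPerClass), times = length(classes)))
      pivotIdx <- seq_len(nrow(regs))[ord][seq_len(nPiv)]
    }
    pairIdx <- if (nPiv > 0L)
      rep(seq_len(nrow(truth@crosstalkPairs)), length.out = nPiv) else integer(0)

    edges <- vector("list", nrow(regs))
    pivots <- truth@pivots[0, ]
    for (i in seq_len(nrow(regs))) {
      k <- match(i, pivotIdx)
      if (!is.na(k)) {
        pr <- truth@crosstalkPairs[pairIdx[k], ]
        gA <- truth@modules[[pr$conditionA]][[pr$moduleA]]
        gB <- truth@modules[[pr$conditionB]][[pr$moduleB]]
        nA <- max(2L, ceiling(0.5 * length(gA)))
        nB <- max(2L, ceiling(0.5 * length(gB)))
        inMod <- unique(c(sample(gA, nA), sample(gB, nB)))
        nFill <- max(0L, config@targetsPerRegulator - length(inMod))
        fill <- sample(setdiff(genes, inMod), nFill)
        edges[[i]] <- data.frame(
          regulator = regs$regulator[i],
          target = c(inMod, fill),
          class = regs$class[i],
          evidence = c(rep("validated", length(inMod)),
                       sample(c("validated", "predicted"), nFill, replace = TRUE)),
          stringsAsFactors = FALSE)
        pivots <- rbind(pivots, data.frame(
          regulator = regs$regulator[i], class = regs$class[i],
          conditionA = pr$conditionA, moduleA = pr$moduleA,
          conditionB = pr$conditionB, moduleB = pr$moduleB,
          stringsAsFactors = FALSE))
      } else {
        tg <- sample(genes, min(config@targetsPerRegulator, length(genes)))
        edges[[i]] <- data.frame(
          regulator = regs$regulator[i], target = tg, class = regs$class[i],
          evidence = sample(c("validated", "predicted"), length(tg),
                            replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    list(regnet = do.call(rbind, edges), pivots = pivots)
  })

  rn <- res$regnet[!duplicated(res$regnet[, c("regulator", "target")]), ]
  rownames(rn) <- NULL
  truth@pivots <- res$pivots
  list(regnet = rn, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [generateExpression()] for both conditions,
#' [generateNetwork()] and [generateRegnet()] under one configuration.
#'
#' @param config a [SyntheticConfig-class].
#' @param conditions two condition labels (default `c("UC", "CRC")`).
#' @return list with elements `expression` (named list per condition of
#'   SummarizedExperiment lists), `network` (igraph), `regnet` (data.frame)
#'   and `truth` ([GroundTruth-class]).
#' @examples
#' study <- generateSyntheticStudy(syntheticConfig(nGenes = 200,
#'   degFraction = 0.4, nModulesPerCondition = 2, moduleSizeRange = c(5, 8),
#'   nPlantedCrosstalkPairs = 1, nPlantedPivots = 2, rngSeed = 11))
#' study$truth
#' @export
generateSyntheticStudy <- function(config, conditions = c("UC", "CRC")) {
  stopifnot(length(conditions) == 2L, !anyDuplicated(conditions))
  exprs <- list()
  truth <- NULL
  for (cond in conditions) {
    gen <- generateExpression(config, cond, truth = truth)
    exprs[[cond]] <- gen$datasets
    truth <- gen$truth
  }
  net <- generateNetwork(config, truth)
  reg <- generateRegnet(config, net$truth)
  list(expression = exprs, network = net$network, regnet = reg$regnet,
       truth = reg$truth)
}
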