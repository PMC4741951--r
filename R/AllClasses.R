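#' @import methods
#' @importFrom stats median p.adjust pt rnorm runif sd var
#' @importFrom utils combn head write.table read.delim packageVersion
NULL

#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the planted-ground-truth generator: expression design
#' (number of genes, datasets per condition, samples per group, standardized
#' effect size, DEG fraction), network design (modules per condition, module
#' size range, intra-module and background edge probabilities, planted
#' crosstalk pairs and edges), regulator design (regulators per class, targets
#' per regulator, planted pivots) and the RNG seed.
#'
#' @slot nGenes number of genes in the universe.
#' @slot nDatasetsPerCondition independent expression datasets per condition.
#' @slot nSamplesPerGroup samples in each of the disease and normal groups.
#' @slot effectSize standardized mean shift (units of the noise SD) applied to
#'   planted DEG genes in the disease group.
#' @slot degFraction fraction of genes planted as differentially expressed.
#' @slot nModulesPerCondition number of dense modules planted per condition.
#' @slot moduleSizeRange integer vector (min, max) of module sizes; min >= 3.
#' @slot intraModuleEdgeProb edge probability within a planted module.
#' @slot backgroundEdgeProb Erdos-Renyi background edge probability.
#' @slot nPlantedCrosstalkPairs number of cross-condition module pairs that
#'   receive extra inter-module edges.
#' @slot crosstalkEdgesPerPair exact number of extra edges added between the
#'   exclusive gene sets of each planted crosstalk pair.
#' @slot nRegulatorsPerClass regulators simulated per class (TF, miRNA,
#'   virus_protein, virus_miRNA).
#' @slot targetsPerRegulator nominal target-list size per regulator.
#' @slot nPlantedPivots number of regulators planted as pivots of crosstalk
#'   pairs.
#' @slot rngSeed integer seed driving all generator randomness.
#'
#' @seealso [syntheticConfig()] for the validated constructor.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nGenes = "integer",
    nDatasetsPerCondition = "integer",
    nSamplesPerGroup = "integer",
    effectSize = "numeric",
    degFraction = "numeric",
    nModulesPerCondition = "integer",
    moduleSizeRange = "integer",
    intraModuleEdgeProb = "numeric",
    backgroundEdgeProb = "numeric",
    nPlantedCrosstalkPairs = "integer",
    crosstalkEdgesPerPair = "integer",
    nRegulatorsPerClass = "integer",
    targetsPerRegulator = "integer",
    nPlantedPivots = "integer",
    rngSeed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msgs <- character(0)
  chkPos <- function(x, name, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min)
      sprintf("%s must be a single integer >= %d (got %s)", name, min,
              paste(x, collapse = ","))
    else NULL
  }
  chkProb <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      sprintf("%s must lie in [0, 1] (got %s)", name, format(x))
    else NULL
  }
  msgs <- c(msgs,
    chkPos(object@nGenes, "nGenes", 1L),
    chkPos(object@nDatasetsPerCondition, "nDatasetsPerCondition", 1L),
    chkPos(object@nSamplesPerGroup, "nSamplesPerGroup", 2L),
    chkPos(object@nModulesPerCondition, "nModulesPerCondition", 0L),
    chkPos(object@nPlantedCrosstalkPairs, "nPlantedCrosstalkPairs", 0L),
    chkPos(object@crosstalkEdgesPerPair, "crosstalkEdgesPerPair", 0L),
    chkPos(object@nRegulatorsPerClass, "nRegulatorsPerClass", 0L),
    chkPos(object@targetsPerRegulator, "targetsPerRegulator", 1L),
    chkPos(object@nPlantedPivots, "nPlantedPivots", 0L),
    chkProb(object@degFraction, "degFraction"),
    chkProb(object@intraModuleEdgeProb, "intraModuleEdgeProb"),
    chkProb(object@backgroundEdgeProb, "backgroundEdgeProb")
  )
  if (length(object@moduleSizeRange) != 2L ||
      any(is.na(object@moduleSizeRange)) ||
      object@moduleSizeRange[1] > object@moduleSizeRange[2])
    msgs <- c(msgs, "moduleSizeRange must be an increasing pair (min, max)")
  else if (object@moduleSizeRange[1] < 3L)
    msgs <- c(msgs, sprintf("moduleSizeRange min must be >= 3 (got %d)",
                            object@moduleSizeRange[1]))
  else {
    maxModuleGenes <- object@nModulesPerCondition * object@moduleSizeRange[2]
    nDeg <- floor(object@degFraction * object@nGenes)
    if (maxModuleGenes > nDeg)
      msgs <- c(msgs, sprintf(
        "degFraction x nGenes (= %d planted DEGs) cannot cover %d x %d = %d module genes",
        nDeg, object@nModulesPerCondition, object@moduleSizeRange[2], maxModuleGenes))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a validated synthetic-study configuration
#'
#' Defaults describe the reference synthetic study: two datasets per condition
#' of 10 disease vs 10 normal samples over 1000 genes, a standardized effect of
#' 2 on 15% planted DEGs, four planted modules per condition of 8-15 genes at
#' intra-module edge probability 0.9 over an Erdos-Renyi background of 0.02,
#' two planted crosstalk pairs with 8 extra inter-module edges each, and 15
#' regulators per class (20 targets each) of which 5 are planted pivots.
#'
#' @param nGenes,nDatasetsPerCondition,nSamplesPerGroup,effectSize,degFraction
#'   expression design; see [SyntheticConfig-class].
#' @param nModulesPerCondition,moduleSizeRange,intraModuleEdgeProb,backgroundEdgeProb
#'   network design.
#' @param nPlantedCrosstalkPairs,crosstalkEdgesPerPair planted crosstalk design.
#' @param nRegulatorsPerClass,targetsPerRegulator,nPlantedPivots regulator design.
#' @param rngSeed integer seed.
#' @return A validated [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(nGenes = 200, nModulesPerCondition = 2,
#'                        degFraction = 0.2, rngSeed = 7)
#' cfg
#' @export
syntheticConfig <- function(nGenes = 1000L,
                            nDatasetsPerCondition = 2L,
                            nSamplesPerGroup = 10L,
                            effectSize = 2,
                            degFraction = 0.15,
                            nModulesPerCondition = 4L,
                            moduleSizeRange = c(8L, 15L),
                            intraModuleEdgeProb = 0.9,
                            backgroundEdgeProb = 0.02,
                            nPlantedCrosstalkPairs = 2L,
                            crosstalkEdgesPerPair = 8L,
                            nRegulatorsPerClass = 15L,
                            targetsPerRegulator = 20L,
                            nPlantedPivots = 5L,
                            rngSeed = 1L) {
  obj <- new("SyntheticConfig",
    nGenes = as.integer(nGenes),
    nDatasetsPerCondition = as.integer(nDatasetsPerCondition),
    nSamplesPerGroup = as.integer(nSamplesPerGroup),
    effectSize = as.numeric(effectSize),
    degFraction = as.numeric(degFraction),
    nModulesPerCondition = as.integer(nModulesPerCondition),
    moduleSizeRange = as.integer(moduleSizeRange),
    intraModuleEdgeProb = as.numeric(intraModuleEdgeProb),
    backgroundEdgeProb = as.numeric(backgroundEdgeProb),
    nPlantedCrosstalkPairs = as.integer(nPlantedCrosstalkPairs),
    crosstalkEdgesPerPair = as.integer(crosstalkEdgesPerPair),
    nRegulatorsPerClass = as.integer(nRegulatorsPerClass),
    targetsPerRegulator = as.integer(targetsPerRegulator),
    nPlantedPivots = as.integer(nPlantedPivots),
    rngSeed = as.integer(rngSeed)
  )
  msg <- validObject(obj, test = TRUE)
  if (!isTRUE(msg)) stop("invalid SyntheticConfig: ",
                         paste(msg, collapse = "; "), call. = FALSE)
  obj
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat(sprintf("  genes: %d, datasets/condition: %d, samples/group: %d\n",
              object@nGenes, object@nDatasetsPerCondition, object@nSamplesPerGroup))
  cat(sprintf("  effect size: %g SD on %.0f%% planted DEGs\n",
              object@effectSize, 100 * object@degFraction))
  cat(sprintf("  modules/condition: %d (size %d-%d), p(intra)=%g, p(background)=%g\n",
              object@nModulesPerCondition, object@moduleSizeRange[1],
              object@moduleSizeRange[2], object@intraModuleEdgeProb,
              object@backgroundEdgeProb))
  cat(sprintf("  crosstalk pairs: %d x %d edges; regulators: 4 x %d, pivots: %d\n",
              object@nPlantedCrosstalkPairs, object@crosstalkEdgesPerPair,
              object@nRegulatorsPerClass, object@nPlantedPivots))
  cat(sprintf("  seed: %d\n", object@rngSeed))
})

#' Planted ground truth of a synthetic study
#'
#' Records what the generator planted so downstream stages can be scored
#' against it: the planted DEG genes per condition, the planted module gene
#' sets per condition, the planted crosstalk module pairs, and the planted
#' pivot regulators with the module pair each one regulates.
#'
#' @slot degGenes named list (one element per condition) of gene-id vectors.
#' @slot modules named list (per condition) of named lists of gene-id vectors.
#' @slot crosstalkPairs data.frame with columns conditionA, moduleA,
#'   conditionB, moduleB.
#' @slot pivots data.frame with columns regulator, class, conditionA, moduleA,
#'   conditionB, moduleB.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    degGenes = "list",
    modules = "list",
    crosstalkPairs = "data.frame",
    pivots = "data.frame"
  ),
  prototype(
    degGenes = list(),
    modules = list(),
    crosstalkPairs = data.frame(conditionA = character(0), moduleA = character(0),
                                conditionB = character(0), moduleB = character(0),
                                stringsAsFactors = FALSE),
    pivots = data.frame(regulator = character(0), class = character(0),
                        conditionA = character(0), moduleA = character(0),
                        conditionB = character(0), moduleB = character(0),
                        stringsAsFactors = FALSE)
  )
)

setValidity("GroundTruth", function(object) {
  msgs <- character(0)
  for (cond in names(object@modules)) {
    if (!cond %in% names(object@degGenes)) {
      msgs <- c(msgs, sprintf("modules for condition '%s' lack a DEG set", cond))
      next
    }
    for (mid in names(object@modules[[cond]])) {
      extra <- setdiff(object@modules[[cond]][[mid]], object@degGenes[[cond]])
      if (length(extra))
        msgs <- c(msgs, sprintf(
          "module %s/%s contains non-DEG genes: %s", cond, mid,
          paste(head(extra, 3), collapse = ",")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth\n")
  for (cond in names(object@degGenes))
    cat(sprintf("  %s: %d planted DEGs, %d planted modules\n", cond,
                length(object@degGenes[[cond]]),
                length(object@modules[[cond]])))
  cat(sprintf("  planted crosstalk pairs: %d; planted pivots: %d\n",
              nrow(object@crosstalkPairs), nrow(object@pivots)))
})

#' @describeIn GroundTruth-class planted DEG gene ids of one condition.
#' @param truth a [GroundTruth-class] object.
#' @param condition condition label.
#' @export
plantedDegGenes <- function(truth, condition) {
  stopifnot(is(truth, "GroundTruth"))
  if (!condition %in% names(truth@degGenes))
    stop("no planted DEGs recorded for condition '", condition, "'")
  truth@degGenes[[condition]]
}

#' @describeIn GroundTruth-class planted module gene sets of one condition
#'   (named list).
#' @export
plantedModules <- function(truth, condition) {
  stopifnot(is(truth, "GroundTruth"))
  if (!condition %in% names(truth@modules))
    stop("no planted modules recorded for condition '", condition, "'")
  truth@modules[[condition]]
}

#' @describeIn GroundTruth-class planted crosstalk module pairs (data.frame).
#' @export
plantedCrosstalkPairs <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  truth@crosstalkPairs
}

#' @describeIn GroundTruth-class planted pivot regulators (data.frame).
#' @export
plantedPivots <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  truth@pivots
}

#' A set of detected (or planted) network modules of one condition
#'
#' Thin S4 container pairing module gene sets with their condition label and
#' density-times-size scores, as produced by [mcodeModules()].
#'
#' @slot modules named list of gene-id character vectors.
#' @slot condition condition label the modules belong to.
#' @slot scores numeric score per module (graph density x size).
#' @exportClass ModuleSet
setClass("ModuleSet",
  representation(
    modules = "list",
    condition = "character",
    scores = "numeric"
  )
)

setValidity("ModuleSet", function(object) {
  msgs <- character(0)
  if (length(object@condition) != 1L)
    msgs <- c(msgs, "condition must be a single label")
  if (length(object@scores) != length(object@modules))
    msgs <- c(msgs, "one score per module required")
  if (is.null(names(object@modules)) && length(object@modules))
    msgs <- c(msgs, "modules must be named")
  if (anyDuplicated(names(object@modules)))
    msgs <- c(msgs, "module ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ModuleSet
#'
#' @param modules named list of gene-id character vectors.
#' @param condition condition label.
#' @param scores optional numeric scores (default NA per module).
#' @return A [ModuleSet-class] object.
#' @export
moduleSet <- function(modules, condition, scores = NULL) {
  if (is.null(scores)) scores <- rep(NA_real_, length(modules))
  names(scores) <- names(modules)
  obj <- new("ModuleSet", modules = modules, condition = condition,
             scores = as.numeric(scores))
  validObject(obj)
  obj
}

#' @describeIn ModuleSet-class module ids.
#' @param x a ModuleSet.
#' @export
moduleIds <- function(x) {
  stopifnot(is(x, "ModuleSet"))
  names(x@modules)
}

#' @describeIn ModuleSet-class gene sets, as a named list (all modules) or a
#'   character vector (one module).
#' @param id optional single module id.
#' @export
moduleGenes <- function(x, id = NULL) {
  stopifnot(is(x, "ModuleSet"))
  if (is.null(id)) return(x@modules)
  if (!id %in% names(x@modules)) stop("unknown module id '", id, "'")
  x@modules[[id]]
}

#' @describeIn ModuleSet-class condition label.
#' @export
moduleCondition <- function(x) {
  stopifnot(is(x, "ModuleSet"))
  x@condition
}

#' @describeIn ModuleSet-class density-times-size scores.
#' @export
moduleScores <- function(x) {
  stopifnot(is(x, "ModuleSet"))
  stats::setNames(x@scores, names(x@modules))
}

setMethod("length", "ModuleSet", function(x) length(x@modules))

setMethod("show", "ModuleSet", function(object) {
  cat(sprintf("ModuleSet: %d module(s) for condition '%s'\n",
              length(object@modules), object@condition))
  if (length(object@modules)) {
    sizes <- lengths(object@modules)
    df <- data.frame(module = names(object@modules), size = sizes,
                     score = round(object@scores, 3), row.names = NULL)
    print(head(df, 8))
    if (nrow(df) > 8) cat(sprintf("  ... and %d more\n", nrow(df) - 8))
  }
})

#' Coerce a ModuleSet to a data.frame
#'
#' One row per module: module_id, condition, score, comma-joined genes — the
#' on-disk module table dialect.
#'
#' @param x a ModuleSet.
#' @param ... ignored.
#' @return data.frame with columns module_id, condition, size, score, genes.
#' @method as.data.frame ModuleSet
#' @export
as.data.frame.ModuleSet <- function(x, ...) {
  data.frame(
    module_id = names(x@modules),
    condition = rep(x@condition, length(x@modules)),
    size = as.integer(lengths(x@modules)),
    score = as.numeric(x@scores),
    genes = vapply(x@modules, function(g) paste(sort(g), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
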