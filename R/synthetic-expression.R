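#' Generate synthetic expression datasets for one condition
#'
#' Simulates the replicated case/control design of a two-condition study:
#' `nDatasetsPerCondition` independent datasets, each a genes x samples matrix
#' of unit-variance Gaussian noise in which a planted fraction of genes
#' (`degFraction`) carries a mean shift of `effectSize` noise SDs in the
#' disease group — in every dataset of the condition, so that the planted
#' genes survive the cross-dataset intersection the pipeline applies. The
#' planted DEG genes are also partitioned into `nModulesPerCondition` planted
#' module gene sets (sizes drawn from `moduleSizeRange`), which
#' [generateNetwork()] later densifies.
#'
#' All randomness derives deterministically from `rngSeed` and the condition
#' label; per-dataset sub-streams are split deterministically, so identical
#' configurations yield identical output.
#'
#' @param config a [SyntheticConfig-class].
#' @param condition condition label (e.g. `"UC"`).
#' @param truth optional [GroundTruth-class] from a previous call for another
#'   condition; this condition's truth is added to it.
#' @return list with elements `datasets` (list of
#'   [SummarizedExperiment::SummarizedExperiment] objects with assay
#'   `"exprs"`, colData columns `group` in \{disease, normal\} and `dataset`)
#'   and `truth` (the updated [GroundTruth-class]).
#' @examples
#' cfg <- syntheticConfig(nGenes = 100, degFraction = 0.3,
#'                        nModulesPerCondition = 2, moduleSizeRange = c(4, 6),
#'                        rngSeed = 1)
#' ex <- generateExpression(cfg, "UC")
#' length(ex$datasets)
#' length(plantedDegGenes(ex$truth, "UC"))
#' @export
generateExpression <- function(config, condition, truth = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  msg <- validObject(config, test = TRUE)
  if (!isTRUE(msg)) stop("invalid SyntheticConfig: ",
                         paste(msg, collapse = "; "), call. = FALSE)
  if (is.null(truth)) truth <- new("GroundTruth")
  stopifnot(is(truth, "GroundTruth"))

  genes <- geneIds(config@nGenes)
  nDeg <- floor(config@degFraction * config@nGenes)
  nPerGroup <- config@nSamplesPerGroup

  out <- withSeed(deriveSeed(config@rngSeed, paste0("expr:", condition)), {
    degGenes <- sort(sample(genes, nDeg))
    # partition planted DEGs into planted module gene sets
    sizeChoices <- seq(config@moduleSizeRange[1], config@moduleSizeRange[2])
    sizes <- if (config@nModulesPerCondition > 0L)
      sizeChoices[sample.int(length(sizeChoices),
                             config@nModulesPerCondition, replace = TRUE)]
      else integer(0)
    pool <- sample(degGenes)
    modules <- list()
    off <- 0L
    for (i in seq_along(sizes)) {
      modules[[sprintf("P%d", i)]] <- sort(pool[(off + 1L):(off + sizes[i])])
      off <- off + sizes[i]
    }
    datasets <- lapply(seq_len(config@nDatasetsPerCondition), function(d) {
      dsSeed <- deriveSeed(config@rngSeed,
                           sprintf("expr:%s:dataset%d", condition, d))
      withSeed(dsSeed, {
        nSamp <- 2L * nPerGroup
        mat <- matrix(rnorm(config@nGenes * nSamp), nrow = config@nGenes,
                      dimnames = list(genes, sprintf("%s_d%d_s%02d",
                                                     condition, d,
                                                     seq_len(nSamp))))
        groups <- rep(c("disease", "normal"), each = nPerGroup)
        mat[degGenes, groups == "disease"] <-
          mat[degGenes, groups == "disease"] + config@effectSize
        SummarizedExperiment::SummarizedExperiment(
          assays = list(exprs = mat),
          colData = S4Vectors::DataFrame(
            group = groups,
            dataset = rep(sprintf("%s_d%d", condition, d), nSamp),
            row.names = colnames(mat)),
          metadata = list(condition = condition,
                          dataset_id = sprintf("%s_d%d", condition, d))
        )
      })
    })
    list(degGenes = degGenes, modules = modules, datasets = datasets)
  })

  truth@degGenes[[condition]] <- out$degGenes
  truth@modules[[condition]] <- out$modules
  validObject(truth)
  list(datasets = out$datasets, truth = truth)
}

#' Extract the expression matrix and group labels from a dataset
#'
#' Accepts either a `SummarizedExperiment` (assay `"exprs"`, colData `group`)
#' or a plain list with elements `matrix` and `groups`; used by [samTest()].
#'
#' @param dataset a SummarizedExperiment or list.
#' @return list with elements `matrix`, `groups`, `dataset_id`.
#' @keywords internal
.datasetParts <- function(dataset) {
  if (is(dataset, "SummarizedExperiment")) {
    mat <- SummarizedExperiment::assay(dataset, "exprs")
    groups <- as.character(SummarizedExperiment::colData(dataset)$group)
    id <- S4Vectors::metadata(dataset)$dataset_id
    if (is.null(id)) id <- "dataset"
  } else if (is.list(dataset) && !is.null(dataset$matrix)) {
    mat <- dataset$matrix
    groups <- as.character(dataset$groups)
    id <- if (is.null(dataset$dataset_id)) "dataset" else dataset$dataset_id
  } else stop("dataset must be a SummarizedExperiment or a list(matrix, groups)")
  if (is.null(rownames(mat))) stop("expression matrix must have gene ids as rownames")
  if (anyDuplicated(rownames(mat))) stop("gene ids must be unique")
  if (length(groups) != ncol(mat))
    stop("one group label per sample required")
  if (!all(groups %in% c("disease", "normal")))
    stop("sample groups must be 'disease' or 'normal'")
  list(matrix = mat, groups = groups, dataset_id = id)
}
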