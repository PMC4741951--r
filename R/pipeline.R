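#' Assemble a validated pipeline configuration
#'
#' A pipeline run is driven by one configuration holding either a
#' [SyntheticConfig-class] (inputs are generated) or input file paths
#' (expression matrix + annotation per condition, edge-list network,
#' regulation table), plus every stage's tuning parameters. Defaults follow
#' the conventional printed cutoffs: per-dataset FDR 0.05, pair significance
#' 0.05, 1000 network randomizations, pivots with at least 2 targets per
#' module at enrichment 0.05.
#'
#' @param synthetic a [SyntheticConfig-class], or NULL when reading inputs
#'   from files.
#' @param inputs when `synthetic` is NULL: named list with elements
#'   `expression` (named per condition: list(matrix=, annot=)), `network`
#'   (edge-list TSV path) and `regnet` (regulation TSV path). All referenced
#'   files must exist at validation time.
#' @param conditions two condition labels (default `c("UC", "CRC")`).
#' @param fdrCutoff per-dataset BH cutoff for DEG calling (default 0.05).
#' @param nPermutations label permutations for [samTest()] (default 500).
#' @param degMethod `"sam"` or `"welch"`.
#' @param confidenceCutoff edge-confidence pre-filter (default 0.9; only
#'   applied when the network carries scores).
#' @param vwp,haircut,fluff,fluffDensity,minSize MCODE parameters (defaults
#'   0.2, TRUE, FALSE, 0.5, 3).
#' @param R network randomizations (default 1000).
#' @param swapsPerEdge double-edge swaps per edge (default 10).
#' @param alpha pair significance cutoff (default 0.05).
#' @param pivotAlpha,minTargets pivot criteria (defaults 0.05 and 2).
#' @param seed master integer seed for every stage.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(synthetic = NULL, inputs = NULL,
                           conditions = c("UC", "CRC"),
                           fdrCutoff = 0.05, nPermutations = 500L,
                           degMethod = "sam", confidenceCutoff = 0.9,
                           vwp = 0.2, haircut = TRUE, fluff = FALSE,
                           fluffDensity = 0.5, minSize = 3L,
                           R = 1000L, swapsPerEdge = 10L, alpha = 0.05,
                           pivotAlpha = 0.05, minTargets = 2L, seed = 1L) {
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of 'synthetic' or 'inputs' must be given")
  if (!is.null(synthetic)) stopifnot(is(synthetic, "SyntheticConfig"))
  if (!is.null(inputs)) {
    need <- c("expression", "network", "regnet")
    if (!all(need %in% names(inputs)))
      stop("inputs must name ", paste(need, collapse = ", "))
    for (cond in conditions) {
      e <- inputs$expression[[cond]]
      if (is.null(e$matrix) || is.null(e$annot))
        stop("inputs$expression$", cond, " must name matrix and annot paths")
      for (f in c(e$matrix, e$annot))
        if (!file.exists(f)) stop("input file not found: ", f)
    }
    for (f in c(inputs$network, inputs$regnet))
      if (!file.exists(f)) stop("input file not found: ", f)
  }
  stopifnot(length(conditions) == 2L)
  structure(list(synthetic = synthetic, inputs = inputs,
                 conditions = conditions, fdrCutoff = fdrCutoff,
                 nPermutations = as.integer(nPermutations),
                 degMethod = degMethod, confidenceCutoff = confidenceCutoff,
                 vwp = vwp, haircut = haircut, fluff = fluff,
                 fluffDensity = fluffDensity, minSize = as.integer(minSize),
                 R = as.integer(R), swapsPerEdge = as.integer(swapsPerEdge),
                 alpha = alpha, pivotAlpha = pivotAlpha,
                 minTargets = as.integer(minTargets), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors [pipelineConfig()]'s arguments; a `synthetic:` mapping is
#' passed to [syntheticConfig()]. See
#' `system.file("extdata", "demo_config.yaml", package = "modlink")` for the
#' bundled demo.
#'
#' @param path configuration file path (`.yaml`/`.yml` or `.json`).
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$synthetic))
    raw$synthetic <- do.call(syntheticConfig, raw$synthetic)
  if (!is.null(raw$conditions)) raw$conditions <- as.character(raw$conditions)
  do.call(pipelineConfig, raw)
}

.stageLog <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[modlink] ", fmt), ...))
}

#' Run the full module-crosstalk pipeline
#'
#' Executes every stage in order — input generation or loading, per-dataset
#' DEG calling with cross-dataset intersection per condition, DEG-subnetwork
#' module detection, module-pair overlap and crosstalk scoring, pivot
#' identification on the significant pairs, and annotated subnetwork export —
#' writing each stage's table under `outDir` plus a JSON run manifest
#' (package version, seed, parameter echo, per-stage row counts, wall time).
#' Reruns with the same configuration and seed produce byte-identical result
#' tables. For synthetic runs the manifest additionally audits the planted
#' ground truth: how many planted crosstalk pairs map to detected significant
#' pairs, and how many planted pivot regulators were recovered.
#'
#' @param config a `PipelineConfig` (see [pipelineConfig()]).
#' @param outDir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(package = "modlink",
                   version = as.character(packageVersion("modlink")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("synthetic", "inputs"))],
                   stages = list())
  conds <- config$conditions
  condA <- conds[1]; condB <- conds[2]
  truth <- NULL

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed [E_%s]: %s", name, toupper(name),
                   conditionMessage(e)), call. = FALSE))
    .stageLog(quiet, "stage %s done", name)
    res
  }

  # -- inputs ---------------------------------------------------------------
  ins <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      study <- generateSyntheticStudy(config$synthetic, conditions = conds)
      for (cond in conds)
        writeExpressionTsv(study$expression[[cond]],
                           file.path(outDir, sprintf("expression_%s.tsv", cond)),
                           file.path(outDir, sprintf("samples_%s.tsv", cond)))
      writeEdgeListTsv(study$network, file.path(outDir, "network.tsv"))
      writeRegulationsTsv(study$regnet, file.path(outDir, "regulations.tsv"))
      writeGroundTruthJson(study$truth, file.path(outDir, "ground_truth.json"))
      study
    } else {
      list(expression = stats::setNames(lapply(conds, function(cond)
             readExpressionTsv(config$inputs$expression[[cond]]$matrix,
                               config$inputs$expression[[cond]]$annot)), conds),
           network = readEdgeListTsv(config$inputs$network),
           regnet = readRegulationsTsv(config$inputs$regnet))
    }
  })
  if (!is.null(config$synthetic)) truth <- ins$truth
  network <- filterByConfidence(ins$network, config$confidenceCutoff)
  manifest$stages$inputs <- list(
    n_network_nodes = igraph::vcount(network),
    n_network_edges = igraph::ecount(network),
    n_regulations = nrow(ins$regnet))

  # -- DEG calling ----------------------------------------------------------
  degSets <- stage("deg", {
    out <- list()
    for (cond in conds) {
      results <- lapply(seq_along(ins$expression[[cond]]), function(i) {
        ds <- ins$expression[[cond]][[i]]
        r <- samTest(ds, nPermutations = config$nPermutations,
                     fdrCutoff = config$fdrCutoff,
                     seed = deriveSeed(config$seed,
                                       sprintf("deg:%s:%d", cond, i)),
                     method = config$degMethod)
        writeDegTsv(r, file.path(outDir,
                                 sprintf("deg_%s_dataset%d.tsv", cond, i)))
        r
      })
      out[[cond]] <- sort(intersectDegs(results))
      writeLines(out[[cond]], file.path(outDir, sprintf("deg_%s.txt", cond)))
    }
    out
  })
  manifest$stages$deg <- stats::setNames(
    lapply(conds, function(cond) length(degSets[[cond]])),
    paste0("n_deg_", conds))

  # -- module detection -----------------------------------------------------
  mods <- stage("modules", {
    out <- lapply(conds, function(cond)
      mcodeModules(induceSubnetwork(network, degSets[[cond]]),
                   vwp = config$vwp, haircut = config$haircut,
                   fluff = config$fluff, fluffDensity = config$fluffDensity,
                   minSize = config$minSize, condition = cond))
    names(out) <- conds
    writeModulesTsv(out, file.path(outDir, "modules.tsv"))
    out
  })
  manifest$stages$modules <- stats::setNames(
    lapply(conds, function(cond) length(mods[[cond]])),
    paste0("n_modules_", conds))

  # -- module-pair statistics ----------------------------------------------
  pairTab <- stage("pairs", {
    tab <- scoreModulePairs(mods[[condA]], mods[[condB]], network,
                            R = config$R, swapsPerEdge = config$swapsPerEdge,
                            alpha = config$alpha,
                            seed = deriveSeed(config$seed, "pairs"))
    write.table(tab, file.path(outDir, "module_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tab
  })
  sigPairs <- pairTab[pairTab$overlap_significant |
                        pairTab$crosstalk_significant, , drop = FALSE]
  manifest$stages$pairs <- list(
    n_pairs = nrow(pairTab),
    n_overlap_significant = sum(pairTab$overlap_significant),
    n_crosstalk_significant = sum(pairTab$crosstalk_significant),
    n_significant = nrow(sigPairs))

  # -- pivots ---------------------------------------------------------------
  pivotTab <- stage("pivots", {
    tab <- pivotScan(ins$regnet, sigPairs, mods[[condA]], mods[[condB]],
                     universe = igraph::V(network)$name,
                     alpha = config$pivotAlpha,
                     minTargets = config$minTargets)
    write.table(tab, file.path(outDir, "pivots.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tab
  })
  manifest$stages$pivots <- list(
    n_candidates = nrow(pivotTab),
    n_pivots = sum(pivotTab$is_pivot),
    n_pivot_regulators = length(unique(pivotTab$regulator[pivotTab$is_pivot])))

  # -- subnetwork export ----------------------------------------------------
  if (nrow(sigPairs)) {
    sub <- stage("export", {
      s <- buildSubnetwork(sigPairs, mods[[condA]], mods[[condB]], network,
                           pivots = pivotTab, regnet = ins$regnet)
      writeSubnetworkGraphml(s, file.path(outDir, "subnetwork.graphml"))
      writeSubnetworkSif(s, file.path(outDir, "subnetwork.sif"))
      writeSubnetworkTables(s, file.path(outDir, "subnetwork_nodes.tsv"),
                            file.path(outDir, "subnetwork_edges.tsv"))
      s
    })
    manifest$stages$export <- list(n_nodes = igraph::vcount(sub),
                                   n_edges = igraph::ecount(sub))
  } else {
    manifest$stages$export <- list(n_nodes = 0L, n_edges = 0L,
                                   note = "no significant pairs to export")
  }

  # -- planted-truth audit (synthetic runs) ---------------------------------
  if (!is.null(truth)) {
    manifest$truth_audit <- .auditAgainstTruth(truth, degSets, mods, pairTab,
                                               pivotTab, conds)
  }

  manifest$wall_time_sec <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .stageLog(quiet, "pipeline complete (%.1fs): %s",
            manifest$wall_time_sec, outDir)
  invisible(manifest)
}

# Check, for each planted crosstalk pair, whether some detected significant
# pair captures it (module detection may fragment or merge planted modules,
# so the match asks for >= 2 shared genes on each side rather than a
# best-Jaccard bijection), and whether each planted pivot regulator is
# flagged on any scanned pair.
.auditAgainstTruth <- function(truth, degSets, mods, pairTab, pivotTab,
                               conds) {
  degRecall <- stats::setNames(lapply(conds, function(cond) {
    planted <- plantedDegGenes(truth, cond)
    length(intersect(degSets[[cond]], planted)) / max(1L, length(planted))
  }), paste0("deg_recall_", conds))

  ctp <- plantedCrosstalkPairs(truth)
  sig <- pairTab[pairTab$overlap_significant | pairTab$crosstalk_significant, ,
                 drop = FALSE]
  nSigPlanted <- 0L
  mapped <- character(nrow(ctp))
  for (i in seq_len(nrow(ctp))) {
    pA <- plantedModules(truth, ctp$conditionA[i])[[ctp$moduleA[i]]]
    pB <- plantedModules(truth, ctp$conditionB[i])[[ctp$moduleB[i]]]
    hit <- NA_character_
    for (j in seq_len(nrow(sig))) {
      dA <- moduleGenes(mods[[ctp$conditionA[i]]], sig$module_id_A[j])
      dB <- moduleGenes(mods[[ctp$conditionB[i]]], sig$module_id_B[j])
      if (length(intersect(dA, pA)) >= 2L && length(intersect(dB, pB)) >= 2L) {
        hit <- paste(sig$module_id_A[j], sig$module_id_B[j])
        break
      }
    }
    mapped[i] <- hit
    if (!is.na(hit)) nSigPlanted <- nSigPlanted + 1L
  }

  piv <- plantedPivots(truth)
  flagged <- unique(pivotTab$regulator[pivotTab$is_pivot])
  nPivRecovered <- length(intersect(unique(piv$regulator), flagged))

  list(n_planted_crosstalk_pairs = nrow(ctp),
       n_planted_pairs_significant = nSigPlanted,
       planted_pair_mapping = mapped,
       deg_recall = degRecall,
       n_planted_pivots = length(unique(piv$regulator)),
       n_planted_pivots_recovered = nPivRecovered)
}
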