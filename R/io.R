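# On-disk dialects: tab-separated text throughout, JSON for the ground truth.

#' Write expression datasets of one condition as TSV
#'
#' Column-binds all datasets into one genes x samples matrix file (first
#' column `gene`, header row = sample ids) and writes a companion
#' sample-annotation TSV with columns `sample`, `group`, `dataset`.
#'
#' @param datasets list of SummarizedExperiment objects sharing a gene set.
#' @param matrixPath,annotPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionTsv <- function(datasets, matrixPath, annotPath) {
  parts <- lapply(datasets, .datasetParts)
  mat <- do.call(cbind, lapply(parts, `[[`, "matrix"))
  annot <- do.call(rbind, lapply(parts, function(p)
    data.frame(sample = colnames(p$matrix), group = p$groups,
               dataset = p$dataset_id, stringsAsFactors = FALSE)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(annot, annotPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrixPath, annotPath))
}

#' Read expression datasets from the TSV dialect
#'
#' Inverse of [writeExpressionTsv()]: splits the combined matrix by the
#' annotation's `dataset` column.
#'
#' @param matrixPath,annotPath input file paths.
#' @return list of SummarizedExperiment objects (assay `"exprs"`), one per
#'   dataset id, in order of first appearance.
#' @export
readExpressionTsv <- function(matrixPath, annotPath) {
  df <- read.delim(matrixPath, check.names = FALSE, stringsAsFactors = FALSE)
  annot <- read.delim(annotPath, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column of the matrix must be 'gene'")
  if (!all(c("sample", "group", "dataset") %in% names(annot)))
    stop("annotation must have columns sample, group, dataset")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  miss <- setdiff(annot$sample, colnames(mat))
  if (length(miss)) stop("annotation samples missing from matrix: ",
                         paste(head(miss, 3), collapse = ", "))
  lapply(unique(annot$dataset), function(ds) {
    a <- annot[annot$dataset == ds, ]
    SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = mat[, a$sample, drop = FALSE]),
      colData = S4Vectors::DataFrame(group = a$group, dataset = a$dataset,
                                     row.names = a$sample),
      metadata = list(dataset_id = ds))
  })
}

#' Write a network as an edge-list TSV
#'
#' Two columns (`from`, `to`), plus a `confidence` column when the network
#' carries one.
#'
#' @param network an [igraph::igraph] with named vertices.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEdgeListTsv <- function(network, path) {
  stopifnot(igraph::is_igraph(network))
  el <- igraph::as_edgelist(network)
  df <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  if ("confidence" %in% igraph::edge_attr_names(network))
    df$confidence <- igraph::E(network)$confidence
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected network from an edge-list TSV
#'
#' Accepts 2 columns (from, to) or 3 (plus confidence in \[0, 1\]); the graph
#' is simplified (self-loops and duplicate edges removed).
#'
#' @param path input path.
#' @return an [igraph::igraph].
#' @export
readEdgeListTsv <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least 2 columns")
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  if (ncol(df) >= 3L) {
    conf <- as.numeric(df[[3]])
    if (any(is.na(conf) | conf < 0 | conf > 1))
      stop("confidence scores must lie in [0, 1]")
    igraph::E(g)$confidence <- conf
  }
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Write / read a bipartite regulation table
#'
#' TSV with columns regulator, target, class and optionally evidence.
#'
#' @param regnet data.frame (see [findPivots()]).
#' @param path file path.
#' @return `writeRegulationsTsv`: the path, invisibly; `readRegulationsTsv`:
#'   the deduplicated data.frame.
#' @export
writeRegulationsTsv <- function(regnet, path) {
  regnet <- .checkRegnet(regnet)
  write.table(regnet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegulationsTsv
#' @export
readRegulationsTsv <- function(path) {
  if (!file.exists(path)) stop("regulation table not found: ", path)
  .checkRegnet(read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read module tables
#'
#' TSV with columns module_id, condition, size, score, genes (comma-joined).
#' A file may hold modules of several conditions; reading returns one
#' [ModuleSet-class] per condition.
#'
#' @param modules a [ModuleSet-class] or list of them.
#' @param path file path.
#' @return `writeModulesTsv`: the path, invisibly; `readModulesTsv`: named
#'   list of [ModuleSet-class] objects keyed by condition.
#' @export
writeModulesTsv <- function(modules, path) {
  if (is(modules, "ModuleSet")) modules <- list(modules)
  df <- do.call(rbind, lapply(modules, as.data.frame))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeModulesTsv
#' @export
readModulesTsv <- function(path) {
  if (!file.exists(path)) stop("module table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$condition)[unique(df$condition)], function(d)
    moduleSet(stats::setNames(strsplit(d$genes, ",", fixed = TRUE),
                              d$module_id),
              condition = d$condition[1], scores = d$score))
}

#' Write a per-gene differential-expression result
#'
#' Writes the full per-gene table (gene, d, p, q, is_deg) and, optionally, a
#' plain DEG-list text file with one gene id per line.
#'
#' @param result a [samTest()] result.
#' @param path output TSV path.
#' @param listPath optional DEG-list path.
#' @return invisibly, the TSV path.
#' @export
writeDegTsv <- function(result, path, listPath = NULL) {
  stopifnot(inherits(result, "DifferentialResult"))
  write.table(result$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(listPath))
    writeLines(result$degSet, listPath)
  invisible(path)
}

#' Write / read the planted ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path file path.
#' @return `writeGroundTruthJson`: the path, invisibly;
#'   `readGroundTruthJson`: a [GroundTruth-class].
#' @export
writeGroundTruthJson <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  obj <- list(
    deg_genes = truth@degGenes,
    modules = truth@modules,
    crosstalk_pairs = truth@crosstalkPairs,
    pivots = truth@pivots
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeGroundTruthJson
#' @export
readGroundTruthJson <- function(path) {
  if (!file.exists(path)) stop("ground-truth file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asChr <- function(x) lapply(x, function(v) as.character(unlist(v)))
  asDf <- function(x, template) {
    if (is.null(x) || (is.list(x) && length(x) == 0L)) return(template)
    as.data.frame(lapply(x, as.character), stringsAsFactors = FALSE)
  }
  proto <- new("GroundTruth")
  new("GroundTruth",
      degGenes = asChr(obj$deg_genes),
      modules = lapply(obj$modules, asChr),
      crosstalkPairs = asDf(obj$crosstalk_pairs, proto@crosstalkPairs),
      pivots = asDf(obj$pivots, proto@pivots))
}
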