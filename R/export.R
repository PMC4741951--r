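#' Assemble an annotated module-pair subnetwork
#'
#' Builds the figure-style export graph for a set of significant
#' cross-condition module pairs: the union of the paired modules' genes, plus
#' their pivot regulators when a pivot table is supplied. Node roles are
#' exhaustive and mutually exclusive: `conditionA_deg` / `conditionB_deg` for
#' genes of one side only, `overlapping_deg` for genes present in modules of
#' both conditions, `pivot_TF` / `pivot_miRNA` for host pivot regulators, and
#' `virus_protein` / `virus_miRNA` for viral pivots. Edge kinds:
#' `ppi_internal` (interaction within one region of the module union),
#' `ppi_crosstalk` (interaction bridging regions, consistent with
#' [crosstalkCount()]), `regulation` (host pivot to target) and `virus_host`
#' (viral pivot to target). Each node carries its degree *within the exported
#' subnetwork*.
#'
#' @param pairs data.frame with columns `module_id_A`, `module_id_B` (e.g.
#'   significant rows of [scoreModulePairs()] output).
#' @param modulesA,modulesB the [ModuleSet-class] objects the ids refer to.
#' @param network the background interaction network (igraph).
#' @param pivots optional data.frame from [pivotScan()]; rows with
#'   `is_pivot = TRUE` referencing the given pairs are attached. A pivot row
#'   referencing a module pair absent from `pairs` is a consistency error.
#' @param regnet optional regulation table supplying the regulator-target
#'   edges (required when `pivots` is given).
#' @return an undirected [igraph::igraph] with vertex attributes `role` and
#'   `degree` and edge attribute `kind`.
#' @export
buildSubnetwork <- function(pairs, modulesA, modulesB, network,
                            pivots = NULL, regnet = NULL) {
  stopifnot(is(modulesA, "ModuleSet"), is(modulesB, "ModuleSet"),
            igraph::is_igraph(network))
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no module pairs to export")
  pairs <- unique(pairs[, c("module_id_A", "module_id_B")])
  badA <- setdiff(pairs$module_id_A, moduleIds(modulesA))
  badB <- setdiff(pairs$module_id_B, moduleIds(modulesB))
  if (length(badA) || length(badB))
    stop("pairs reference unknown module id(s): ",
         paste(c(badA, badB), collapse = ", "))

  genesA <- unique(unlist(moduleGenes(modulesA)[unique(pairs$module_id_A)]))
  genesB <- unique(unlist(moduleGenes(modulesB)[unique(pairs$module_id_B)]))
  allGenes <- union(genesA, genesB)

  role <- stats::setNames(ifelse(allGenes %in% genesA & allGenes %in% genesB,
                                 "overlapping_deg",
                                 ifelse(allGenes %in% genesA,
                                        "conditionA_deg", "conditionB_deg")),
                          allGenes)

  sub <- induceSubnetwork(network, allGenes)
  el <- igraph::as_edgelist(sub)
  region <- function(v) ifelse(v %in% genesA & v %in% genesB, "shared",
                               ifelse(v %in% genesA, "Aonly", "Bonly"))
  kind <- if (nrow(el)) ifelse(region(el[, 1]) != region(el[, 2]),
                               "ppi_crosstalk", "ppi_internal") else character(0)

  edgeDf <- if (nrow(el))
    data.frame(from = el[, 1], to = el[, 2], kind = kind,
               stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0),
                  kind = character(0), stringsAsFactors = FALSE)

  if (!is.null(pivots) && nrow(pivots)) {
    pv <- pivots[pivots$is_pivot, , drop = FALSE]
    if (nrow(pv)) {
      if (is.null(regnet))
        stop("regnet is required to draw regulation edges for pivots")
      regnet <- .checkRegnet(regnet)
      key <- paste(pv$module_id_A, pv$module_id_B)
      known <- paste(pairs$module_id_A, pairs$module_id_B)
      bad <- setdiff(unique(key), known)
      if (length(bad))
        stop("pivot table references module pair(s) absent from 'pairs': ",
             paste(bad, collapse = "; "))
      pvReg <- unique(pv[, c("regulator", "class")])
      regRole <- c(TF = "pivot_TF", miRNA = "pivot_miRNA",
                   virus_protein = "virus_protein",
                   virus_miRNA = "virus_miRNA")[pvReg$class]
      clash <- intersect(pvReg$regulator, allGenes)
      if (length(clash))
        stop("regulator id(s) collide with gene ids: ",
             paste(head(clash, 3), collapse = ", "))
      role <- c(role, stats::setNames(regRole, pvReg$regulator))
      re <- regnet[regnet$regulator %in% pvReg$regulator &
                     regnet$target %in% allGenes, , drop = FALSE]
      if (nrow(re)) {
        isVirus <- re$class %in% c("virus_protein", "virus_miRNA")
        edgeDf <- rbind(edgeDf, data.frame(
          from = re$regulator, to = re$target,
          kind = ifelse(isVirus, "virus_host", "regulation"),
          stringsAsFactors = FALSE))
      }
    }
  }

  g <- igraph::graph_from_data_frame(edgeDf, directed = FALSE,
                                     vertices = data.frame(
                                       name = names(role), role = unname(role),
                                       stringsAsFactors = FALSE))
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Export an annotated subnetwork
#'
#' `writeSubnetworkGraphml` writes a lossless attributed GraphML file
#' (round-trippable via [readSubnetworkGraphml()]); `writeSubnetworkSif`
#' writes the interoperable SIF dialect (`node<TAB>kind<TAB>node`);
#' `writeSubnetworkTables` writes node- and edge-attribute TSVs.
#'
#' @param subnetwork graph from [buildSubnetwork()].
#' @param path output path (for the tables: node table path).
#' @param edgePath edge-table output path.
#' @return invisibly, the path(s) written.
#' @export
writeSubnetworkGraphml <- function(subnetwork, path) {
  igraph::write_graph(subnetwork, path, format = "graphml")
  invisible(path)
}

#' @rdname writeSubnetworkGraphml
#' @export
readSubnetworkGraphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path)
  igraph::read_graph(path, format = "graphml")
}

#' @rdname writeSubnetworkGraphml
#' @export
writeSubnetworkSif <- function(subnetwork, path) {
  el <- igraph::as_edgelist(subnetwork)
  kind <- igraph::E(subnetwork)$kind
  writeLines(if (nrow(el)) paste(el[, 1], kind, el[, 2], sep = "\t")
             else character(0), path)
  invisible(path)
}

#' @rdname writeSubnetworkGraphml
#' @export
writeSubnetworkTables <- function(subnetwork, path, edgePath) {
  nodes <- data.frame(node = igraph::V(subnetwork)$name,
                      role = igraph::V(subnetwork)$role,
                      degree = igraph::V(subnetwork)$degree,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(subnetwork)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      kind = igraph::E(subnetwork)$kind,
                      stringsAsFactors = FALSE)
  write.table(nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(edges, edgePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, edgePath))
}
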