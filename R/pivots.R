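# Validate and normalize a bipartite regulation table.
.checkRegnet <- function(regnet) {
  if (!is.data.frame(regnet) ||
      !all(c("regulator", "target", "class") %in% names(regnet)))
    stop("regnet must be a data.frame with columns regulator, target, class")
  okClasses <- c("TF", "miRNA", "virus_protein", "virus_miRNA")
  bad <- setdiff(unique(regnet$class), okClasses)
  if (length(bad))
    stop("unknown regulator class(es): ", paste(bad, collapse = ", "))
  regnet[!duplicated(regnet[, c("regulator", "target")]), , drop = FALSE]
}

#' Find pivot regulators of one module pair
#'
#' A regulator (TF, miRNA, viral protein or viral miRNA) pivots a
#' cross-condition module pair when (i) it has at least `minTargets` (default
#' 2) targets inside *each* module of the pair and (ii) its targets are
#' significantly enriched in each module at `alpha` (default 0.05) by the
#' hypergeometric upper-tail test ([hypergeomOverlapP()]) with background
#' `N = |universe|`, drawing the regulator's in-universe target set against
#' each module's in-universe gene set. Both criteria are evaluated per module
#' independently; the same machinery applies to every regulator class. A row
#' is emitted for every regulator with at least one target in either module.
#'
#' @param regnet data.frame with columns `regulator`, `target`, `class`
#'   (optionally `evidence`, carried but unused by the statistic).
#' @param moduleA,moduleB gene-id character vectors: the module pair.
#' @param universe background gene-id set; must contain both modules' genes.
#' @param alpha enrichment cutoff (default 0.05).
#' @param minTargets minimum targets per module (default 2).
#' @return data.frame with one row per candidate regulator: regulator, class,
#'   n_targets (in universe), k_A, k_B, p_A, p_B, is_pivot; sorted by
#'   max(p_A, p_B).
#' @export
findPivots <- function(regnet, moduleA, moduleB, universe, alpha = 0.05,
                       minTargets = 2L) {
  regnet <- .checkRegnet(regnet)
  missing <- setdiff(union(moduleA, moduleB), universe)
  if (length(missing))
    stop("universe is missing module genes: ",
         paste(head(missing, 5), collapse = ", "))
  N <- length(unique(universe))
  mA <- intersect(moduleA, universe)
  mB <- intersect(moduleB, universe)

  split_tg <- split(regnet$target, regnet$regulator)
  classOf <- regnet$class[!duplicated(regnet$regulator)]
  names(classOf) <- regnet$regulator[!duplicated(regnet$regulator)]

  rows <- lapply(names(split_tg), function(reg) {
    tg <- intersect(unique(split_tg[[reg]]), universe)
    kA <- length(intersect(tg, mA))
    kB <- length(intersect(tg, mB))
    if (kA == 0L && kB == 0L) return(NULL)
    pA <- hypergeomOverlapP(N = N, M = length(mA), n = length(tg), m = kA)
    pB <- hypergeomOverlapP(N = N, M = length(mB), n = length(tg), m = kB)
    data.frame(regulator = reg, class = unname(classOf[reg]),
               n_targets = length(tg), k_A = kA, k_B = kB,
               p_A = pA, p_B = pB,
               is_pivot = kA >= minTargets && kB >= minTargets &&
                 pA <= alpha && pB <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(regulator = character(0), class = character(0),
                      n_targets = integer(0), k_A = integer(0),
                      k_B = integer(0), p_A = numeric(0), p_B = numeric(0),
                      is_pivot = logical(0)))
  out <- out[order(pmax(out$p_A, out$p_B), out$regulator), ]
  rownames(out) <- NULL
  out
}

#' Scan all significant module pairs for pivot regulators
#'
#' Applies [findPivots()] to every (deduplicated) significant pair and
#' concatenates the results with pair provenance columns; a regulator may
#' pivot several pairs. A BH-adjusted column over each per-pair scan is
#' emitted for reference, but pivot calling uses the raw per-module p-values.
#'
#' @param regnet regulation table (see [findPivots()]).
#' @param pairs data.frame with columns `module_id_A`, `module_id_B` —
#'   typically the significant rows of [scoreModulePairs()] output.
#' @param modulesA,modulesB the [ModuleSet-class] objects the pair ids refer
#'   to.
#' @param universe background gene-id set.
#' @param alpha,minTargets pivot criteria (defaults 0.05 and 2).
#' @return data.frame: module_id_A, module_id_B, regulator, class, n_targets,
#'   k_A, k_B, p_A, p_B, q_max, is_pivot.
#' @export
pivotScan <- function(regnet, pairs, modulesA, modulesB, universe,
                      alpha = 0.05, minTargets = 2L) {
  stopifnot(is(modulesA, "ModuleSet"), is(modulesB, "ModuleSet"))
  empty <- data.frame(module_id_A = character(0), module_id_B = character(0),
                      regulator = character(0), class = character(0),
                      n_targets = integer(0), k_A = integer(0),
                      k_B = integer(0), p_A = numeric(0), p_B = numeric(0),
                      q_max = numeric(0), is_pivot = logical(0))
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  pairs <- unique(pairs[, c("module_id_A", "module_id_B")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    res <- findPivots(regnet,
                      moduleGenes(modulesA, pairs$module_id_A[i]),
                      moduleGenes(modulesB, pairs$module_id_B[i]),
                      universe, alpha, minTargets)
    if (nrow(res) == 0L) return(NULL)
    cbind(data.frame(module_id_A = pairs$module_id_A[i],
                     module_id_B = pairs$module_id_B[i],
                     stringsAsFactors = FALSE),
          res,
          q_max = p.adjust(pmax(res$p_A, res$p_B), "BH"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
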