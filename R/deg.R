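#' SAM-style permutation test for differential expression
#'
#' Computes, per gene, the moderated statistic
#' \deqn{d(g) = \frac{\bar x_{disease} - \bar x_{normal}}{s(g) + s_0}}
#' where \eqn{s(g)} is the pooled standard error of the group-mean difference
#' and the fudge factor \eqn{s_0} is the median of \eqn{s(g)} over genes —
#' stabilizing the statistic for genes with small variance. Significance comes
#' from a pooled permutation null: sample labels are shuffled
#' `nPermutations` times (full unrestricted shuffles; duplicates allowed), the
#' statistic is recomputed for every gene, and the raw p-value of gene g is
#' the fraction of all permuted |d| values (all genes x all permutations) at
#' or above |d(g)|. Benjamini-Hochberg adjustment across genes gives q-values;
#' the DEG set is \{g : q(g) <= fdrCutoff\}.
#'
#' `method = "welch"` instead computes an ordinary Welch t-test per gene with
#' BH adjustment (no permutations).
#'
#' @param dataset a `SummarizedExperiment` (assay `"exprs"`, colData column
#'   `group` in \{disease, normal\}) or a `list(matrix=, groups=)`.
#' @param nPermutations number of label permutations (>= 100) for
#'   `method = "sam"`.
#' @param fdrCutoff BH q-value cutoff defining the DEG set (default 0.05).
#' @param seed integer seed for the permutations.
#' @param method `"sam"` (default) or `"welch"`.
#' @return list of class `DifferentialResult`: `table` (data.frame with
#'   columns gene, d, p, q, is_deg), `degSet` (character vector),
#'   `fdrCutoff`, `method`, `datasetId`.
#' @examples
#' cfg <- syntheticConfig(nGenes = 100, degFraction = 0.2,
#'                        nModulesPerCondition = 2, moduleSizeRange = c(4, 6),
#'                        nSamplesPerGroup = 5, rngSeed = 2)
#' ds <- generateExpression(cfg, "UC")$datasets[[1]]
#' res <- samTest(ds, nPermutations = 100, seed = 1)
#' head(res$table)
#' @export
samTest <- function(dataset, nPermutations = 500L, fdrCutoff = 0.05,
                    seed = 1L, method = c("sam", "welch")) {
  method <- match.arg(method)
  parts <- .datasetParts(dataset)
  mat <- parts$matrix
  groups <- parts$groups
  n1 <- sum(groups == "disease")
  n2 <- sum(groups == "normal")
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (disease: ", n1,
         ", normal: ", n2, ")")
  if (method == "sam" && nPermutations < 100L)
    stop("nPermutations must be >= 100")

  mat2 <- mat * mat
  # group means/variances for many label assignments at once: `D` is a
  # samples x assignments 0/1 disease-indicator matrix
  groupStats <- function(D) {
    m1 <- (mat %*% D) / n1
    m2 <- (mat %*% (1 - D)) / n2
    v1 <- (mat2 %*% D - n1 * m1 * m1) / (n1 - 1)
    v2 <- (mat2 %*% (1 - D) - n2 * m2 * m2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    list(diff = m1 - m2, s = sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n2)))
  }

  if (method == "sam") {
    obs <- groupStats(matrix(as.numeric(groups == "disease"), ncol = 1))
    s0 <- median(obs$s)
    denom <- obs$s + s0
    d <- as.numeric(ifelse(denom > 0, obs$diff / denom, 0))
    perm <- withSeed(seed, {
      D <- vapply(seq_len(nPermutations),
                  function(b) as.numeric(sample(groups) == "disease"),
                  numeric(length(groups)))
      st <- groupStats(D)
      dn <- st$s + s0
      ifelse(dn > 0, st$diff / dn, 0)
    })
    nullAbs <- sort(abs(as.numeric(perm)))
    # count of permuted |d| >= |d(g)|, via the sorted pooled null
    geq <- length(nullAbs) - findInterval(abs(d) - 1e-12, nullAbs)
    p <- geq / length(nullAbs)
  } else {
    isD <- groups == "disease"
    m1 <- rowMeans(mat[, isD, drop = FALSE])
    m2 <- rowMeans(mat[, !isD, drop = FALSE])
    v1 <- apply(mat[, isD, drop = FALSE], 1L, var)
    v2 <- apply(mat[, !isD, drop = FALSE], 1L, var)
    se2 <- v1 / n1 + v2 / n2
    d <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    p <- ifelse(se2 > 0, 2 * pt(abs(d), df, lower.tail = FALSE), 1)
  }

  q <- p.adjust(p, method = "BH")
  tab <- data.frame(gene = rownames(mat), d = as.numeric(d),
                    p = as.numeric(p), q = as.numeric(q),
                    is_deg = q <= fdrCutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, degSet = tab$gene[tab$is_deg],
                 fdrCutoff = fdrCutoff, method = method,
                 datasetId = parts$dataset_id),
            class = "DifferentialResult")
}

#' @export
print.DifferentialResult <- function(x, ...) {
  cat(sprintf("DifferentialResult (%s, dataset '%s'): %d/%d genes at q <= %g\n",
              x$method, x$datasetId, length(x$degSet), nrow(x$table),
              x$fdrCutoff))
  invisible(x)
}

#' Intersect DEG calls across the datasets of a condition
#'
#' A gene counts as condition-associated only if it is called differentially
#' expressed in every dataset of that condition; FDR control is applied per
#' dataset first, then the calls are intersected.
#'
#' @param results non-empty list of [samTest()] results (or plain character
#'   vectors of gene ids).
#' @return character vector: the intersection of the DEG sets.
#' @examples
#' intersectDegs(list(c("A", "B", "C"), c("B", "C", "D")))
#' @export
intersectDegs <- function(results) {
  if (!is.list(results) || length(results) == 0L)
    stop("results must be a non-empty list")
  sets <- lapply(results, function(r) {
    if (inherits(r, "DifferentialResult")) r$degSet
    else if (is.character(r)) r
    else stop("each element must be a DifferentialResult or character vector")
  })
  Reduce(intersect, sets)
}
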