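#' Read gene-set collections in GMT format
#'
#' Thin wrapper over [fgsea::gmtPathways()]: one set per line, tab-separated
#' as name, description, member genes.
#'
#' @param path path to a `.gmt` file.
#' @return named list of gene-id character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set enrichment
#'
#' Annotates a gene set (e.g. a detected module) against named collections
#' (GO terms, pathways, ...): for each set, the overlap with the query is
#' scored by the hypergeometric upper-tail test ([hypergeomOverlapP()]) on
#' the given universe, with BH adjustment across sets. Collections with no
#' member in the universe are skipped with a warning.
#'
#' @param genes query gene-id character vector.
#' @param collections named list of gene-id vectors (see [readGmt()]).
#' @param universe background gene-id set.
#' @param alpha significance cutoff recorded in the `significant` column
#'   (default 0.05).
#' @return data.frame sorted by p ascending: set, set_size, overlap, p, q,
#'   significant.
#' @export
genesetEnrichment <- function(genes, collections, universe, alpha = 0.05) {
  if (!is.list(collections) || length(collections) == 0L ||
      is.null(names(collections)))
    stop("collections must be a non-empty named list of gene sets")
  universe <- unique(universe)
  q <- intersect(unique(genes), universe)
  N <- length(universe)

  rows <- lapply(names(collections), function(nm) {
    s <- intersect(unique(collections[[nm]]), universe)
    if (length(s) == 0L) {
      warning("gene set '", nm, "' is disjoint from the universe; skipped")
      return(NULL)
    }
    ov <- length(intersect(q, s))
    data.frame(set = nm, set_size = length(s), overlap = ov,
               p = hypergeomOverlapP(N = N, M = length(s), n = length(q),
                                     m = ov),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  out$q <- p.adjust(out$p, "BH")
  out$significant <- out$p <= alpha
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
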