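#' Induce the subnetwork spanned by a gene set
#'
#' Restriction of an interaction network to a gene set: nodes are the
#' intersection of the set with the network's vertices, edges are all network
#' edges with both endpoints retained. Used to map a condition's DEGs onto
#' the interaction network before module detection.
#'
#' @param network an [igraph::igraph] with named vertices.
#' @param genes character vector of gene ids.
#' @return the induced [igraph::igraph] (possibly empty).
#' @export
induceSubnetwork <- function(network, genes) {
  stopifnot(igraph::is_igraph(network))
  keep <- intersect(genes, igraph::V(network)$name)
  igraph::induced_subgraph(network, keep)
}

#' Filter network edges by confidence score
#'
#' Drops edges whose `confidence` attribute falls below a cutoff (default
#' 0.90, the conventional high-confidence threshold for scored interaction
#' databases). Networks without a confidence attribute pass through unchanged.
#'
#' @param network an [igraph::igraph], optionally with an edge attribute
#'   `confidence` in \[0, 1\].
#' @param cutoff minimum confidence retained.
#' @return the filtered [igraph::igraph].
#' @export
filterByConfidence <- function(network, cutoff = 0.9) {
  stopifnot(igraph::is_igraph(network))
  if (!"confidence" %in% igraph::edge_attr_names(network)) return(network)
  conf <- igraph::E(network)$confidence
  igraph::delete_edges(network, igraph::E(network)[conf < cutoff])
}

# Highest k-core of a graph: the induced subgraph on vertices of maximal
# coreness, together with that k. Empty graph -> k = 0.
.highestKCore <- function(g) {
  if (igraph::vcount(g) == 0L) return(list(k = 0L, core = g))
  cores <- igraph::coreness(g)
  k <- max(cores)
  list(k = k, core = igraph::induced_subgraph(g, which(cores == k)))
}

#' MCODE vertex weight
#'
#' The local-density weight that seeds molecular-complex detection: for a
#' vertex v, take the subgraph induced by v and its neighbors (the closed
#' neighborhood), find its highest k-core, and return k times the density
#' (2E / (n (n - 1))) of that core. Vertices in denser, more cliquish
#' neighborhoods weigh more; an isolated vertex weighs 0.
#'
#' @param network an [igraph::igraph] with named vertices.
#' @param v a vertex name present in the network.
#' @return a non-negative numeric weight.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:4]
#' vertexWeight(g, "a") # (4-1) x density 1 = 3
#' @export
vertexWeight <- function(network, v) {
  stopifnot(igraph::is_igraph(network))
  if (!v %in% igraph::V(network)$name)
    stop("vertex '", v, "' is not in the network")
  nb <- igraph::neighbors(network, v)
  if (length(nb) == 0L) return(0)
  gv <- igraph::induced_subgraph(network, union(v, igraph::V(network)$name[nb]))
  hk <- .highestKCore(gv)
  n <- igraph::vcount(hk$core)
  dens <- if (n < 2L) 0 else 2 * igraph::ecount(hk$core) / (n * (n - 1))
  hk$k * dens
}

# Vectorized weights for all vertices.
.vertexWeights <- function(network) {
  nms <- igraph::V(network)$name
  adj <- igraph::as_adj_list(network, mode = "all")
  vapply(seq_along(nms), function(i) {
    nb <- as.integer(adj[[i]])
    if (length(nb) == 0L) return(0)
    gv <- igraph::induced_subgraph(network, c(i, nb))
    hk <- .highestKCore(gv)
    n <- igraph::vcount(hk$core)
    dens <- if (n < 2L) 0 else 2 * igraph::ecount(hk$core) / (n * (n - 1))
    hk$k * dens
  }, numeric(1), USE.NAMES = FALSE) -> w
  stats::setNames(w, nms)
}

#' Detect dense modules with the MCODE algorithm
#'
#' Re-implementation of molecular complex detection. Vertices are weighted by
#' [vertexWeight()]; seeds are processed in decreasing weight order (ties
#' broken by vertex name). From each still-unassigned seed, a breadth-first
#' expansion adds an unassigned neighbor u whenever
#' `weight(u) > (1 - vwp) * weight(seed)`; once assigned to a complex, a
#' vertex neither re-seeds nor joins another complex, so complexes are
#' pairwise disjoint. Post-processing: `haircut` iteratively removes complex
#' members with fewer than 2 neighbors inside the complex (i.e. keeps its
#' 2-core); `fluff` (off by default) adds neighboring vertices whose closed
#' neighborhoods have density above `fluffDensity` (fluffed vertices may be
#' shared between complexes). Complexes smaller than `minSize` are dropped.
#' Modules are scored by density x size and returned sorted by score
#' (descending), ties by size (larger first) then by lexicographically
#' smallest member.
#'
#' @param network an [igraph::igraph] with named vertices (typically the
#'   DEG-induced subnetwork).
#' @param vwp vertex weight percentage, in \[0, 1): expansion tolerance
#'   relative to the seed weight (default 0.2).
#' @param haircut drop weakly attached members (default TRUE).
#' @param fluff add dense-neighborhood vertices (default FALSE).
#' @param fluffDensity closed-neighborhood density threshold for fluff
#'   (default 0.5).
#' @param minSize minimum module size (default 3).
#' @param condition condition label stored on the result (default "NA").
#' @return a [ModuleSet-class]; module ids are `M1, M2, ...` in rank order.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' g <- igraph::add_vertices(g, 1, name = "p")
#' g <- igraph::add_edges(g, c("a", "p"))
#' mcodeModules(g) # the 5-clique; the pendant is trimmed
#' @export
mcodeModules <- function(network, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluffDensity = 0.5, minSize = 3L,
                         condition = "NA") {
  stopifnot(igraph::is_igraph(network))
  if (vwp < 0 || vwp >= 1) stop("vwp must lie in [0, 1)")
  nms <- igraph::V(network)$name
  if (igraph::vcount(network) == 0L)
    return(moduleSet(stats::setNames(list(), character(0)), condition))

  w <- .vertexWeights(network)
  adj <- igraph::as_adj_list(network, mode = "all")
  names(adj) <- nms
  seedOrder <- nms[order(-w, nms)]
  assigned <- stats::setNames(rep(FALSE, length(nms)), nms)

  complexes <- list()
  for (seed in seedOrder) {
    if (assigned[[seed]]) next
    thr <- (1 - vwp) * w[[seed]]
    members <- seed
    assigned[[seed]] <- TRUE
    queue <- seed
    seen <- stats::setNames(rep(FALSE, length(nms)), nms)
    seen[[seed]] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (u in nms[as.integer(adj[[v]])]) {
        if (seen[[u]] || assigned[[u]]) next
        seen[[u]] <- TRUE
        if (w[[u]] > thr) {
          members <- c(members, u)
          assigned[[u]] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    complexes[[length(complexes) + 1L]] <- members
  }

  finalize <- function(members) {
    sub <- igraph::induced_subgraph(network, members)
    if (haircut) {
      # iterate to the 2-core so every member keeps >= 2 in-module neighbors
      repeat {
        deg <- igraph::degree(sub)
        drop <- names(deg)[deg < 2L]
        if (length(drop) == 0L || igraph::vcount(sub) == 0L) break
        sub <- igraph::delete_vertices(sub, drop)
      }
    }
    members <- igraph::V(sub)$name
    if (fluff && length(members)) {
      cand <- setdiff(unique(unlist(lapply(members, function(v)
        nms[as.integer(adj[[v]])]))), members)
      add <- cand[vapply(cand, function(u) {
        gv <- igraph::induced_subgraph(network,
                                       c(u, nms[as.integer(adj[[u]])]))
        n <- igraph::vcount(gv)
        dens <- if (n < 2L) 0 else
          2 * igraph::ecount(gv) / (n * (n - 1))
        dens > fluffDensity
      }, logical(1))]
      members <- c(members, add)
    }
    members
  }

  complexes <- lapply(complexes, finalize)
  complexes <- complexes[lengths(complexes) >= minSize]
  if (length(complexes) == 0L)
    return(moduleSet(stats::setNames(list(), character(0)), condition))

  score <- vapply(complexes, function(m) {
    sub <- igraph::induced_subgraph(network, m)
    n <- igraph::vcount(sub)
    dens <- if (n < 2L) 0 else 2 * igraph::ecount(sub) / (n * (n - 1))
    dens * n
  }, numeric(1))
  smallest <- vapply(complexes, function(m) min(m), "")
  ord <- order(-score, -lengths(complexes), smallest)
  complexes <- lapply(complexes[ord], sort)
  score <- score[ord]
  names(complexes) <- sprintf("M%d", seq_along(complexes))
  moduleSet(complexes, condition, score)
}
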