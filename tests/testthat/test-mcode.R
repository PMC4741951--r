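test_that("subnetwork induction filters nodes and edges correctly", {
  g <- igraph::make_graph(~ a - b, b - c, a - c, c - d)
  tri <- induceSubnetwork(g, c("a", "b", "c"))
  expect_setequal(igraph::V(tri)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(tri), 3L)
  expect_equal(igraph::vcount(induceSubnetwork(g, c("x", "y"))), 0L)
  same <- induceSubnetwork(g, c("a", "b", "c", "d", "e"))
  expect_setequal(igraph::V(same)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(same), igraph::ecount(g))
})

test_that("vertex weights match closed-form neighborhoods", {
  # isolated vertex
  g <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g)$name <- c("a", "b")
  expect_equal(vertexWeight(g, "a"), 0)
  # c-clique vertex: (c-1) x density 1
  for (c in c(3, 5)) {
    k <- namedClique(c, "v")
    expect_equal(vertexWeight(k, "v1"), c - 1)
  }
  # center of a 4-leaf star: 1-core density 2*4/(5*4)
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  expect_equal(vertexWeight(star, "hub"), 0.4)
  expect_error(vertexWeight(star, "nope"), "not in the network")
})

test_that("haircut trims the pendant from a clique-plus-pendant graph", {
  g <- namedClique(5, "c")
  g <- igraph::add_vertices(g, 1, name = "p")
  g <- igraph::add_edges(g, c("c1", "p"))
  ms <- mcodeModules(g, condition = "x")
  expect_equal(length(ms), 1L)
  expect_setequal(moduleGenes(ms, "M1"), paste0("c", 1:5))
})

test_that("graphs below the size floor yield no modules", {
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(length(mcodeModules(empty)), 0L)
  duo <- igraph::make_graph(~ a - b)
  expect_equal(length(mcodeModules(duo)), 0L)
})

test_that("equal-weight cliques joined by a bridge merge into one complex", {
  # Hand-trace: all eight vertices carry weight 3 (their closed neighborhoods'
  # highest k-core is a 4-clique: k = 3, density 1), so at vwp = 0.2 the
  # expansion threshold from any seed is 2.4 and the breadth-first expansion
  # crosses the bridge; the symmetric weights make any other outcome
  # impossible under a seed-relative threshold.
  g <- igraph::disjoint_union(namedClique(4, "a"), namedClique(4, "b"))
  g <- igraph::add_edges(g, c("a4", "b1"))
  w <- sapply(igraph::V(g)$name, vertexWeight, network = g)
  expect_true(all(w == 3))
  ms <- mcodeModules(g, vwp = 0.2, haircut = TRUE, condition = "x")
  expect_equal(length(ms), 1L)
  expect_setequal(moduleGenes(ms, "M1"), igraph::V(g)$name)
})

test_that("modules are disjoint in basic mode and 2-connected after haircut", {
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(60, 0.12)
    igraph::V(g)$name <- sprintf("n%02d", 1:60)
    ms <- mcodeModules(g, condition = "x")
    genes <- unlist(moduleGenes(ms))
    expect_equal(anyDuplicated(genes), 0L)
    for (mod in moduleGenes(ms)) {
      sub <- igraph::induced_subgraph(g, mod)
      expect_gte(min(igraph::degree(sub)), 2L)
    }
  }
})

test_that("module ordering is by score, then size, then smallest member", {
  g <- igraph::disjoint_union(namedClique(5, "a"), namedClique(4, "b"),
                              namedClique(4, "c"))
  ms <- mcodeModules(g, condition = "x")
  df <- as.data.frame(ms)
  expect_equal(df$module_id, c("M1", "M2", "M3"))
  expect_equal(df$size, c(5L, 4L, 4L))
  # the two 4-cliques tie on score and size; lexicographic member break
  expect_equal(moduleGenes(ms, "M2")[1], "b1")
  expect_true(all(diff(moduleScores(ms)) <= 1e-12))
})

test_that("fluff adds dense neighborhood vertices without removing core ones", {
  # pendant p attached to all vertices of a 4-clique has a dense neighborhood
  g <- namedClique(4, "c")
  g <- igraph::add_vertices(g, 1, name = "p")
  g <- igraph::add_edges(g, c("c1", "p", "c2", "p"))
  msOff <- mcodeModules(g, fluff = FALSE, haircut = FALSE, condition = "x")
  msOn <- mcodeModules(g, fluff = TRUE, fluffDensity = 0.5, haircut = FALSE,
                       condition = "x")
  expect_true(all(moduleGenes(msOff, "M1") %in% moduleGenes(msOn, "M1")))
  expect_true("p" %in% moduleGenes(msOn, "M1"))
})

test_that("edge-confidence filtering drops low-confidence edges only", {
  g <- igraph::make_graph(~ a - b, b - c, c - a)
  igraph::E(g)$confidence <- c(0.95, 0.5, 0.91)
  f <- filterByConfidence(g, 0.9)
  expect_equal(igraph::ecount(f), 2L)
  plain <- igraph::make_graph(~ a - b)
  expect_equal(igraph::ecount(filterByConfidence(plain)), 1L)
})
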