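test_that("overlap p-value matches closed forms and rejects bad input", {
  expect_equal(hypergeomOverlapP(N = 100, M = 10, n = 10, m = 0), 1)
  expect_equal(hypergeomOverlapP(N = 5, M = 5, n = 5, m = 5), 1)
  expect_equal(hypergeomOverlapP(N = 4, M = 2, n = 2, m = 2), 1 / 6,
               tolerance = 1e-12)
  expect_error(hypergeomOverlapP(N = 10, M = 11, n = 2, m = 1), "M")
  expect_error(hypergeomOverlapP(N = 10, M = 5, n = 2, m = 3), "min")
  expect_error(hypergeomOverlapP(N = -1, M = 0, n = 0, m = 0), "N")
})

test_that("overlap p-value agrees with phyper across random instances", {
  set.seed(1)
  for (i in 1:50) {
    N <- sample(5:2000, 1)
    M <- sample(0:N, 1)
    n <- sample(0:N, 1)
    m <- sample(0:min(n, M), 1)
    expect_equal(hypergeomOverlapP(N, M, n, m),
                 phyper(m - 1, n, N - n, M, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("crosstalk counting applies the region rules", {
  g <- igraph::make_graph(~ 1 - 3, 2 - 5, 5 - 4, 1 - 2)
  expect_equal(crosstalkCount(g, A = c("1", "2", "5"), B = c("3", "4", "5")),
               3L)
  g2 <- igraph::make_graph(~ a - b, c - d)
  expect_equal(crosstalkCount(g2, A = c("a", "b"), B = c("c", "d")), 0L)
  g3 <- igraph::make_graph(~ 1 - 3)
  expect_equal(crosstalkCount(g3, A = c("1", "2"), B = c("3", "4")), 1L)
  # edges wholly inside the shared set are excluded
  g4 <- igraph::make_graph(~ s - t, s - x)
  expect_equal(crosstalkCount(g4, A = c("s", "t", "x"), B = c("s", "t")), 1L)
})

test_that("randomization preserves the degree sequence and is seeded", {
  set.seed(4)
  g <- igraph::sample_gnp(80, 0.08)
  igraph::V(g)$name <- sprintf("n%02d", 1:80)
  r1 <- randomizeNetwork(g, seed = 9)
  r2 <- randomizeNetwork(g, seed = 9)
  r3 <- randomizeNetwork(g, seed = 10)
  deg <- function(x) igraph::degree(x)[igraph::V(g)$name]
  expect_identical(deg(r1), deg(g))
  expect_identical(igraph::as_edgelist(r1), igraph::as_edgelist(r2))
  expect_false(identical(igraph::as_edgelist(r1), igraph::as_edgelist(r3)))
  expect_true(igraph::is_simple(r1))
})

test_that("rigid graphs pass through randomization unchanged", {
  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  r <- randomizeNetwork(tri, seed = 1)
  expect_setequal(apply(igraph::as_edgelist(r), 1, function(x)
    paste(sort(x), collapse = "-")), c("a-b", "b-c", "a-c"))
  single <- igraph::make_graph(~ a - b)
  expect_equal(igraph::ecount(randomizeNetwork(single, seed = 1)), 1L)
})

test_that("empirical crosstalk p-values hit their boundary cases", {
  # no observed crosstalk -> p = 1 under the add-one estimator
  g <- igraph::make_graph(~ a - b, c - d, e - f)
  res <- crosstalkPvalue(g, A = c("a", "b"), B = c("c", "d"), R = 20,
                         seed = 1)
  expect_equal(res$observed, 0L)
  expect_equal(res$p, 1)
  # complete graph admits no valid swap: every null equals the observed count
  k <- namedClique(6, "v")
  res2 <- crosstalkPvalue(k, A = paste0("v", 1:3), B = paste0("v", 4:6),
                          R = 25, seed = 2)
  expect_true(all(res2$null == res2$observed))
  expect_equal(res2$p, 1)
  expect_error(crosstalkPvalue(g, "a", "b", R = 0), "R")
})

test_that("the add-one estimator is monotone in the observed count", {
  null <- c(0L, 1L, 1L, 3L, 5L)
  p <- vapply(0:6, function(obs) (1 + sum(null >= obs)) / (1 + length(null)),
              numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("strict mode implements the plain exceedance fraction", {
  cfg <- smallConfig(seed = 6L)
  st <- generateSyntheticStudy(cfg)
  ctp <- plantedCrosstalkPairs(st$truth)
  A <- plantedModules(st$truth, ctp$conditionA[1])[[ctp$moduleA[1]]]
  B <- plantedModules(st$truth, ctp$conditionB[1])[[ctp$moduleB[1]]]
  res <- crosstalkPvalue(st$network, A, B, R = 30, seed = 3, strict = TRUE)
  expect_equal(res$p, sum(res$null > res$observed) / 30)
})

test_that("pair scoring is exhaustive, consistent and reuses one null set", {
  st <- generateSyntheticStudy(smallConfig(seed = 8L))
  msA <- moduleSet(plantedModules(st$truth, "UC"), "UC")
  msB <- moduleSet(plantedModules(st$truth, "CRC"), "CRC")
  tab <- scoreModulePairs(msA, msB, st$network, R = 30, seed = 5,
                          keepNull = TRUE)
  expect_equal(nrow(tab), length(msA) * length(msB))
  expect_equal(tab$overlap_significant, tab$p_overlap <= 0.05)
  expect_equal(tab$crosstalk_significant, tab$p_crosstalk <= 0.05)
  null <- attr(tab, "null")
  expect_equal(dim(null), c(nrow(tab), 30L))
  expect_equal(tab$p_crosstalk,
               (1 + rowSums(null >= tab$crosstalk_observed)) / 31)
  # single-module sets give a single pair
  one <- scoreModulePairs(moduleSet(list(P1 = moduleGenes(msA, "P1")), "UC"),
                          moduleSet(list(P1 = moduleGenes(msB, "P1")), "CRC"),
                          st$network, R = 5, seed = 1)
  expect_equal(nrow(one), 1L)
})

test_that("identical module sets give minimal overlap p among equal sizes", {
  set.seed(2)
  g <- igraph::sample_gnp(60, 0.1)
  igraph::V(g)$name <- sprintf("n%02d", 1:60)
  genes <- igraph::V(g)$name
  shared <- genes[1:6]
  msA <- moduleSet(list(M1 = shared, M2 = genes[7:12]), "UC")
  msB <- moduleSet(list(M1 = shared, M2 = genes[13:18]), "CRC")
  tab <- scoreModulePairs(msA, msB, g, R = 5, seed = 1)
  full <- tab$p_overlap[tab$module_id_A == "M1" & tab$module_id_B == "M1"]
  expect_equal(full, min(tab$p_overlap))
  expect_lt(full, 1e-6)
})
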