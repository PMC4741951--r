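test_that("configuration validation names the violated bound", {
  expect_error(syntheticConfig(degFraction = 1.5), "degFraction")
  expect_error(syntheticConfig(moduleSizeRange = c(2L, 5L)), "moduleSizeRange")
  expect_error(syntheticConfig(nGenes = 100, degFraction = 0.05,
                               nModulesPerCondition = 4,
                               moduleSizeRange = c(8L, 15L)),
               "module genes")
  expect_error(syntheticConfig(intraModuleEdgeProb = -0.1),
               "intraModuleEdgeProb")
})

test_that("planted DEG bookkeeping is exact and effects land where planted", {
  cfg <- syntheticConfig(nGenes = 1000L, degFraction = 0.1,
                         nModulesPerCondition = 4L,
                         moduleSizeRange = c(8L, 15L),
                         effectSize = 2, nSamplesPerGroup = 10L, rngSeed = 7L)
  gen <- generateExpression(cfg, "UC")
  planted <- plantedDegGenes(gen$truth, "UC")
  expect_length(planted, 100L)
  expect_length(gen$datasets, 2L)

  # Welch statistic oracle, computed directly on the emitted matrix: planted
  # genes must carry visibly larger statistics than background genes
  mat <- SummarizedExperiment::assay(gen$datasets[[1]], "exprs")
  grp <- SummarizedExperiment::colData(gen$datasets[[1]])$group
  tstat <- apply(mat, 1, function(x)
    t.test(x[grp == "disease"], x[grp == "normal"])$statistic)
  expect_gt(mean(tstat[planted]), mean(tstat[setdiff(rownames(mat), planted)]))
  expect_gt(mean(tstat[planted]), 2)
})

test_that("zero effect size makes planted and background exchangeable", {
  cfg <- smallConfig(effectSize = 0)
  gen <- generateExpression(cfg, "UC")
  mat <- SummarizedExperiment::assay(gen$datasets[[1]], "exprs")
  grp <- SummarizedExperiment::colData(gen$datasets[[1]])$group
  planted <- plantedDegGenes(gen$truth, "UC")
  diff <- rowMeans(mat[, grp == "disease"]) - rowMeans(mat[, grp == "normal"])
  # planted-gene mean shift is statistically indistinguishable from zero
  expect_gt(t.test(diff[planted])$p.value, 0.01)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- smallConfig(seed = 42L)
  a <- generateSyntheticStudy(cfg)
  b <- generateSyntheticStudy(cfg)
  expect_identical(
    SummarizedExperiment::assay(a$expression$UC[[1]]),
    SummarizedExperiment::assay(b$expression$UC[[1]]))
  expect_identical(igraph::as_edgelist(a$network),
                   igraph::as_edgelist(b$network))
  expect_identical(a$regnet, b$regnet)
  expect_identical(plantedPivots(a$truth), plantedPivots(b$truth))
})

test_that("saturated intra-module probability yields planted cliques", {
  cfg <- smallConfig(intraModuleEdgeProb = 1, seed = 3L)
  tr <- generateExpression(cfg, "UC")$truth
  tr <- generateExpression(cfg, "CRC", truth = tr)$truth
  net <- generateNetwork(cfg, tr)$network
  for (mod in plantedModules(tr, "UC")) {
    sub <- igraph::induced_subgraph(net, mod)
    expect_equal(igraph::ecount(sub), choose(length(mod), 2))
  }
})

test_that("zero background and zero crosstalk leave modules as components", {
  cfg <- smallConfig(backgroundEdgeProb = 0, nPlantedCrosstalkPairs = 0L,
                     crosstalkEdgesPerPair = 0L, nPlantedPivots = 0L,
                     intraModuleEdgeProb = 1, seed = 5L)
  tr <- generateExpression(cfg, "UC")$truth
  tr <- generateExpression(cfg, "CRC", truth = tr)$truth
  net <- generateNetwork(cfg, tr)$network
  comp <- igraph::components(net)
  nonTrivial <- which(comp$csize > 1)
  planted <- c(plantedModules(tr, "UC"), plantedModules(tr, "CRC"))
  # every non-trivial component is exactly one planted module (modules of the
  # two conditions can share genes and thereby fuse, so compare as a cover)
  memb <- split(names(comp$membership), comp$membership)
  for (mod in planted) {
    holder <- unique(comp$membership[mod])
    expect_length(holder, 1L)
    expect_true(all(memb[[as.character(holder)]] %in% unlist(planted)))
  }
})

test_that("planted crosstalk edges connect the exclusive gene sets", {
  cfg <- smallConfig(crosstalkEdgesPerPair = 5L, backgroundEdgeProb = 0,
                     seed = 11L)
  tr <- generateExpression(cfg, "UC")$truth
  tr <- generateExpression(cfg, "CRC", truth = tr)$truth
  gn <- generateNetwork(cfg, tr)
  ctp <- plantedCrosstalkPairs(gn$truth)
  expect_equal(nrow(ctp), 1L)
  A <- plantedModules(tr, ctp$conditionA[1])[[ctp$moduleA[1]]]
  B <- plantedModules(tr, ctp$conditionB[1])[[ctp$moduleB[1]]]
  el <- igraph::as_edgelist(gn$network)
  exA <- setdiff(A, B); exB <- setdiff(B, A)
  inter <- sum((el[, 1] %in% exA & el[, 2] %in% exB) |
                 (el[, 1] %in% exB & el[, 2] %in% exA))
  expect_gte(inter, 5L)
})

test_that("impossible crosstalk requests raise a generation error", {
  cfg <- smallConfig(moduleSizeRange = c(3L, 3L), crosstalkEdgesPerPair = 50L,
                     seed = 2L)
  tr <- generateExpression(cfg, "UC")$truth
  tr <- generateExpression(cfg, "CRC", truth = tr)$truth
  expect_error(generateNetwork(cfg, tr), "free pairs")
})

test_that("planted pivots cover at least half of each module of their pair", {
  for (s in 1:3) {
    st <- generateSyntheticStudy(smallConfig(seed = s))
    piv <- plantedPivots(st$truth)
    expect_gte(nrow(piv), 1L)
    for (i in seq_len(nrow(piv))) {
      tg <- st$regnet$target[st$regnet$regulator == piv$regulator[i]]
      A <- plantedModules(st$truth, piv$conditionA[i])[[piv$moduleA[i]]]
      B <- plantedModules(st$truth, piv$conditionB[i])[[piv$moduleB[i]]]
      expect_gte(length(intersect(tg, A)), max(2, ceiling(0.5 * length(A))))
      expect_gte(length(intersect(tg, B)), max(2, ceiling(0.5 * length(B))))
    }
  }
})

test_that("ground-truth invariants hold across random configurations", {
  for (s in 1:5) {
    cfg <- smallConfig(seed = 100L + s,
                       nModulesPerCondition = sample(1:3, 1),
                       degFraction = runif(1, 0.25, 0.4))
    st <- generateSyntheticStudy(cfg)
    tr <- st$truth
    for (cond in c("UC", "CRC")) {
      mods <- plantedModules(tr, cond)
      expect_true(all(unlist(mods) %in% plantedDegGenes(tr, cond)))
      if (length(mods) > 1)
        expect_equal(anyDuplicated(unlist(mods)), 0L)
    }
    # density ordering: planted modules denser than background
    bg <- igraph::edge_density(st$network)
    for (cond in c("UC", "CRC")) for (mod in plantedModules(tr, cond))
      expect_gte(igraph::edge_density(
        igraph::induced_subgraph(st$network, mod)), bg)
    expect_equal(anyDuplicated(st$regnet[, c("regulator", "target")]), 0L)
  }
})

test_that("no planted pivots means no guaranteed enrichment", {
  st <- generateSyntheticStudy(smallConfig(nPlantedPivots = 0L, seed = 9L))
  expect_equal(nrow(plantedPivots(st$truth)), 0L)
  expect_true(all(st$regnet$class %in%
    c("TF", "miRNA", "virus_protein", "virus_miRNA")))
})
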