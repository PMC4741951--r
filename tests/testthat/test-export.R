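makePairFixture <- function(seed = 4L) {
  st <- generateSyntheticStudy(smallConfig(seed = seed))
  tr <- st$truth
  ctp <- plantedCrosstalkPairs(tr)
  msA <- moduleSet(plantedModules(tr, "UC"), "UC")
  msB <- moduleSet(plantedModules(tr, "CRC"), "CRC")
  pairs <- data.frame(module_id_A = ctp$moduleA, module_id_B = ctp$moduleB,
                      stringsAsFactors = FALSE)
  pivots <- pivotScan(st$regnet, pairs, msA, msB,
                      igraph::V(st$network)$name)
  list(study = st, msA = msA, msB = msB, pairs = pairs, pivots = pivots)
}

test_that("node roles are exhaustive, exclusive and match membership", {
  fx <- makePairFixture()
  g <- buildSubnetwork(fx$pairs, fx$msA, fx$msB, fx$study$network,
                       pivots = fx$pivots, regnet = fx$study$regnet)
  roles <- igraph::V(g)$role
  expect_true(all(roles %in% c("conditionA_deg", "conditionB_deg",
                               "overlapping_deg", "pivot_TF", "pivot_miRNA",
                               "virus_protein", "virus_miRNA")))
  gA <- moduleGenes(fx$msA, fx$pairs$module_id_A[1])
  gB <- moduleGenes(fx$msB, fx$pairs$module_id_B[1])
  for (v in intersect(gA, gB))
    expect_equal(igraph::V(g)$role[igraph::V(g)$name == v], "overlapping_deg")
  for (v in setdiff(gA, gB))
    expect_equal(igraph::V(g)$role[igraph::V(g)$name == v], "conditionA_deg")
  # degree attribute is subnetwork-local
  expect_equal(igraph::V(g)$degree, unname(igraph::degree(g)))
})

test_that("module-only export is the induced subgraph with internal edges", {
  fx <- makePairFixture(seed = 7L)
  onePair <- fx$pairs[1, , drop = FALSE]
  g <- buildSubnetwork(onePair, fx$msA, fx$msB, fx$study$network)
  gA <- moduleGenes(fx$msA, onePair$module_id_A)
  gB <- moduleGenes(fx$msB, onePair$module_id_B)
  expect_setequal(igraph::V(g)$name, union(gA, gB))
  ind <- induceSubnetwork(fx$study$network, union(gA, gB))
  expect_equal(igraph::ecount(g), igraph::ecount(ind))
  expect_true(all(igraph::E(g)$kind %in% c("ppi_internal", "ppi_crosstalk")))
  # crosstalk kind agrees with the counting rule
  expect_equal(sum(igraph::E(g)$kind == "ppi_crosstalk"),
               crosstalkCount(fx$study$network, gA, gB))
})

test_that("regulation edges always connect a regulator to a module gene", {
  fx <- makePairFixture()
  g <- buildSubnetwork(fx$pairs, fx$msA, fx$msB, fx$study$network,
                       pivots = fx$pivots, regnet = fx$study$regnet)
  el <- igraph::as_edgelist(g)
  kinds <- igraph::E(g)$kind
  role <- stats::setNames(igraph::V(g)$role, igraph::V(g)$name)
  regRoles <- c("pivot_TF", "pivot_miRNA", "virus_protein", "virus_miRNA")
  degRoles <- c("conditionA_deg", "conditionB_deg", "overlapping_deg")
  for (i in which(kinds %in% c("regulation", "virus_host"))) {
    pairRoles <- role[el[i, ]]
    expect_length(intersect(pairRoles, regRoles), 1L)
    expect_length(intersect(pairRoles, degRoles), 1L)
  }
})

test_that("pivot rows referencing unknown pairs are a consistency error", {
  fx <- makePairFixture()
  bad <- fx$pivots
  if (nrow(bad) == 0L) skip("fixture produced no pivot candidates")
  bad$module_id_A <- "P99"
  bad$is_pivot <- TRUE
  expect_error(buildSubnetwork(fx$pairs, fx$msA, fx$msB, fx$study$network,
                               pivots = bad, regnet = fx$study$regnet),
               "absent from 'pairs'")
  expect_error(buildSubnetwork(data.frame(module_id_A = "nope",
                                          module_id_B = "P1"),
                               fx$msA, fx$msB, fx$study$network),
               "unknown module")
})

test_that("GraphML round-trip preserves the attributed graph", {
  fx <- makePairFixture()
  g <- buildSubnetwork(fx$pairs, fx$msA, fx$msB, fx$study$network,
                       pivots = fx$pivots, regnet = fx$study$regnet)
  tmp <- withr::local_tempfile(fileext = ".graphml")
  writeSubnetworkGraphml(g, tmp)
  h <- readSubnetworkGraphml(tmp)
  ord <- match(igraph::V(g)$name, igraph::V(h)$name)
  expect_false(any(is.na(ord)))
  expect_equal(igraph::V(h)$role[ord], igraph::V(g)$role)
  expect_equal(igraph::V(h)$degree[ord], igraph::V(g)$degree)
  canon <- function(x) sort(apply(cbind(igraph::as_edgelist(x),
                                        igraph::E(x)$kind), 1,
                                  function(r) paste(sort(r[1:2])[1],
                                                    sort(r[1:2])[2], r[3])))
  expect_identical(canon(h), canon(g))
})

test_that("SIF and table exports carry every edge and node", {
  fx <- makePairFixture()
  g <- buildSubnetwork(fx$pairs, fx$msA, fx$msB, fx$study$network)
  sif <- withr::local_tempfile(fileext = ".sif")
  nt <- withr::local_tempfile(fileext = ".tsv")
  et <- withr::local_tempfile(fileext = ".tsv")
  writeSubnetworkSif(g, sif)
  writeSubnetworkTables(g, nt, et)
  expect_length(readLines(sif), igraph::ecount(g))
  nodes <- read.delim(nt)
  edges <- read.delim(et)
  expect_setequal(nodes$node, igraph::V(g)$name)
  expect_equal(nrow(edges), igraph::ecount(g))
})
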