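test_that("modularity matches closed forms and the igraph cross-check", {
  tri <- twoTriangles()
  byComponent <- Partition(setNames(rep(c("x", "y"), each = 3),
                                    graphNodes(tri)))
  expect_equal(graphModularity(tri, byComponent), 0.5, tolerance = 1e-12)
  allOne <- Partition(setNames(rep("m", 6), graphNodes(tri)))
  expect_equal(graphModularity(tri, allOne), 0, tolerance = 1e-12)

  # complete graph K4: single module is the optimum at Q = 0
  k4 <- makeGraph(data.frame(
    a = c("a", "a", "a", "b", "b", "c"),
    b = c("b", "c", "d", "c", "d", "d"), w = 1))
  expect_equal(bruteBestModularity(k4), 0, tolerance = 1e-12)

  # independent route: igraph's weighted modularity on random graphs
  for (seed in 1:5) {
    cg <- randomSparseGraph(7, seed)
    part <- louvainRun(cg, seed)
    g <- asIgraph(cg)
    mem <- as.integer(factor(moduleAssignments(part)[igraph::V(g)$name]))
    expect_equal(graphModularity(cg, part),
                 igraph::modularity(g, mem, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }

  edgeless <- makeGraph(data.frame(a = character(), b = character(),
                                   w = numeric()), nodes = c("a", "b"))
  expect_error(graphModularity(edgeless, Partition(setNames(c("1", "2"),
                                                            c("a", "b")))),
               "zero total")
})

test_that("Louvain recovers disjoint triangles and is seed-deterministic", {
  tri <- twoTriangles()
  p <- louvainRun(tri, 7)
  expect_identical(length(moduleSizes(p)), 2L)
  expect_equal(modularityScore(p), 0.5, tolerance = 1e-12)
  expect_identical(unname(table(moduleAssignments(p)[c("a", "b", "c")])),
                   unname(table(c("x", "x", "x"))))

  p2 <- louvainRun(tri, 7)
  expect_identical(moduleAssignments(p2), moduleAssignments(p))

  single <- makeGraph(data.frame(a = character(), b = character(),
                                 w = numeric()), nodes = "only")
  sp <- louvainRun(single, 1)
  expect_identical(moduleAssignments(sp), c(only = "M1"))
})

test_that("Louvain does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  louvainRun(twoTriangles(), 5)
  expect_identical(.Random.seed, before)
})

test_that("ensemble keeps the best partitions in non-increasing Q order", {
  cg <- randomSparseGraph(20, 3)
  ens <- clusterEnsemble(cg, nRuns = 10, keep = 3, baseSeed = 11)
  qs <- vapply(ensemblePartitions(ens), modularityScore, numeric(1))
  expect_length(qs, 3)
  expect_true(all(diff(qs) <= 1e-12))
  summ <- ensembleSummary(ens)
  expect_identical(summ$seed, 11:20)
  # stored Q equals recomputed modularity
  for (p in ensemblePartitions(ens))
    expect_equal(modularityScore(p), graphModularity(cg, p),
                 tolerance = 1e-12)
  expect_error(clusterEnsemble(cg, nRuns = 5, keep = 6), "keep")
})

test_that("identical base seed reproduces the ensemble byte-for-byte", {
  cg <- randomSparseGraph(25, 8)
  a <- clusterEnsemble(cg, nRuns = 8, keep = 4, baseSeed = 100)
  b <- clusterEnsemble(cg, nRuns = 8, keep = 4, baseSeed = 100)
  expect_identical(lapply(ensemblePartitions(a), moduleAssignments),
                   lapply(ensemblePartitions(b), moduleAssignments))
  expect_identical(ensembleSummary(a), ensembleSummary(b))
})

test_that("best ensemble Q is non-decreasing in the number of runs", {
  cg <- randomSparseGraph(30, 5)
  qOf <- function(n) modularityScore(
    ensemblePartitions(clusterEnsemble(cg, nRuns = n, keep = 1,
                                       baseSeed = 50))[[1]])
  q10 <- qOf(10); q30 <- qOf(30); q60 <- qOf(60)
  expect_gte(q30, q10)
  expect_gte(q60, q30)
})

test_that("ensemble Q reaches the enumeration optimum on small graphs", {
  hits <- 0L
  nGraphs <- 30L
  for (seed in seq_len(nGraphs)) {
    n <- 5L + (seed %% 4L)   # 5..8 nodes
    cg <- randomSparseGraph(n, 1000 + seed)
    best <- modularityScore(
      ensemblePartitions(clusterEnsemble(cg, nRuns = 100, keep = 1,
                                         baseSeed = seed))[[1]])
    if (abs(best - bruteBestModularity(cg)) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / nGraphs, 0.95)
})

test_that("module labels are ordered by non-increasing size", {
  mem <- setNames(c(1, 1, 2, 2, 2, 3), paste0("g", 1:6))
  p <- relabelPartition(mem)
  sz <- moduleSizes(p)
  expect_identical(names(sz), c("M1", "M2", "M3"))
  expect_true(all(diff(sz) <= 0))
  expect_identical(unname(moduleAssignments(p)[c("g3", "g4", "g5")]),
                   rep("M1", 3))
})

test_that("enrichment strategy can prefer a planted split over a coarser merge", {
  # two 4-cliques joined by a single light bridge: max modularity may
  # merge them, but the planted signatures resolve the two cliques
  nodes <- c(paste0("a", 1:4), paste0("b", 1:4))
  cl <- function(v) {
    p <- t(combn(v, 2)); data.frame(a = p[, 1], b = p[, 2], w = 1)
  }
  cg <- makeGraph(rbind(cl(nodes[1:4]), cl(nodes[5:8]),
                        data.frame(a = "a1", b = "b1", w = 0.1)))
  merged <- Partition(setNames(rep("M1", 8), nodes),
                      graphModularity(cg, Partition(setNames(rep("M1", 8),
                                                             nodes))))
  split2 <- relabelPartition(setNames(rep(c(1, 2), each = 4), nodes))
  split2@modularity <- graphModularity(cg, split2)
  ens <- new("EnsembleResult",
             partitions = list(split2, merged)[order(-c(split2@modularity,
                                                        merged@modularity))],
             nRuns = 2L, kept = 2L, baseSeed = 1L,
             summary = data.frame())
  sigs <- SignatureSet(list(cliqueA = nodes[1:4], cliqueB = nodes[5:8]))
  sel <- selectPartition(ens, "enrichment", sigs, nodes)
  expect_identical(length(moduleSizes(sel)), 2L)
  expect_error(selectPartition(ens, "enrichment"), "requires")
  expect_identical(moduleAssignments(selectPartition(ens, "max_modularity")),
                   moduleAssignments(ensemblePartitions(ens)[[1]]))
})
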