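# Welch oracle evaluated from the closed-form Welch/Satterthwaite
# formulas, independent of stats::t.test.
welchOracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

test_that("Welch t-test matches the closed-form oracle and is antisymmetric", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- welchTTest(x, y)
  exp <- welchOracle(x, y)
  expect_equal(got$statistic, exp$t, tolerance = 1e-12)
  expect_equal(got$df, exp$df, tolerance = 1e-12)
  expect_equal(got$p.value, exp$p, tolerance = 1e-12)

  swapped <- welchTTest(y, x)
  expect_equal(swapped$statistic, -got$statistic, tolerance = 1e-12)
  expect_equal(swapped$p.value, got$p.value, tolerance = 1e-12)

  same <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # degenerate zero-variance equal-mean case is not an error
  expect_equal(welchTTest(c(2, 2), c(2, 2))$p.value, 1)
  expect_error(welchTTest(1, c(1, 2)), "at least 2")
})

test_that("differential caller finds planted shifts and respects strict bounds", {
  pe <- makeProbeExperiment(nProbes = 20, donors = 4,
                            timepoints = "t1", seed = 11)
  v <- assay(pe, "exprs")
  a <- resolveGroup(pe, list(condition = "C1"))
  b <- resolveGroup(pe, list(condition = "C2"))
  # flatten baseline noise, then plant effects
  set.seed(42)
  v[] <- rnorm(length(v), 8, 0.1)
  v[1, a] <- v[1, a] + 2.0                      # strong planted shift
  v[2, ] <- 8                                    # identical everywhere
  v[3, a] <- log2(1.2); v[3, b] <- 0             # boundary: exactly log2(1.2)
  pe2 <- ProbeExperiment(v, data.frame(sample_id = colnames(v),
                                       as.data.frame(colData(pe))))
  res <- differentialProbes(pe2, a, b, selectionConfig())
  expect_true("P001" %in% res$up)
  expect_false("P002" %in% c(res$up, res$down))
  expect_false("P003" %in% res$up)   # strict inequality at the FC boundary
  expect_length(intersect(res$up, res$down), 0)

  rev <- differentialProbes(pe2, b, a, selectionConfig())
  expect_identical(sort(rev$up), sort(res$down))
  expect_identical(sort(rev$down), sort(res$up))

  expect_error(differentialProbes(pe2, a, a, selectionConfig()), "disjoint")
  expect_error(differentialProbes(pe2, character(), b, selectionConfig()),
               "empty contrast")
})

test_that("no probes are called when groups are identical", {
  pe <- makeProbeExperiment(nProbes = 10, donors = 3, timepoints = "t1")
  v <- assay(pe, "exprs")
  a <- resolveGroup(pe, list(condition = "C1"))
  b <- resolveGroup(pe, list(condition = "C2"))
  v[, b] <- v[, a]
  pe2 <- ProbeExperiment(v, data.frame(sample_id = colnames(v),
                                       as.data.frame(colData(pe))))
  res <- differentialProbes(pe2, a, b)
  expect_length(res$up, 0)
  expect_length(res$down, 0)
})

test_that("variance filter uses per-group donor medians with strict threshold", {
  pe <- makeProbeExperiment(nProbes = 3, donors = 3,
                            conditions = "C1", timepoints = c("t1", "t2"))
  v <- assay(pe, "exprs")
  v[1, ] <- 5                                   # constant -> excluded
  g1 <- resolveGroup(pe, list(timepoint = "t1"))
  g2 <- resolveGroup(pe, list(timepoint = "t2"))
  v[2, g1] <- 0; v[2, g2] <- 1                  # medians (0,1): var 0.5
  v[3, g1] <- 0; v[3, g2] <- sqrt(2 * 0.05)     # var exactly 0.05
  pe2 <- ProbeExperiment(v, data.frame(sample_id = colnames(v),
                                       as.data.frame(colData(pe))))
  kept <- varianceFilter(pe2, selectionConfig())
  expect_identical(kept, "P002")
  # hand check: var(c(0,1)) = 0.5 with the n-1 denominator
  expect_equal(var(c(0, 1)), 0.5)

  one <- makeProbeExperiment(conditions = "C1", timepoints = "t1")
  expect_error(varianceFilter(one), "at least two")
})

test_that("informative set is the union of DE and variance probes", {
  de <- list(list(up = c("p1"), down = character()),
             list(up = character(), down = c("p2")))
  expect_setequal(selectInformative(de, c("p2", "p3")), c("p1", "p2", "p3"))
  expect_length(selectInformative(list(), character()), 0)
  # monotone: adding a contrast can only grow the set
  more <- c(de, list(list(up = "p9", down = character())))
  expect_true(all(selectInformative(de, "p3") %in%
                  selectInformative(more, "p3")))
})

test_that("probe merging keeps the most variable probe per gene with lexical ties", {
  pe <- makeProbeExperiment(nProbes = 5, seed = 2)
  v <- assay(pe, "exprs")
  v[1, ] <- seq_len(ncol(v)) * 0.1     # gene G: lower variance
  v[2, ] <- seq_len(ncol(v)) * 0.5     # gene G: higher variance -> chosen
  v[3, ] <- v[4, ]                     # gene H: equal variance, P003 < P004
  pe2 <- ProbeExperiment(v, data.frame(sample_id = colnames(v),
                                       as.data.frame(colData(pe))))
  ann <- data.frame(probe_id = sprintf("P%03d", 1:5),
                    gene = c("G", "G", "H", "H", ""))
  ge <- mergeProbesToGenes(pe2, rownames(v), ann)
  expect_setequal(rownames(ge), c("G", "H"))
  rd <- rowData(ge)
  expect_identical(rd["G", "probe_id"], "P002")
  expect_identical(rd["H", "probe_id"], "P003")
  # unannotated probe dropped; gene count <= probe count
  expect_lte(nrow(ge), 5)
  expect_error(mergeProbesToGenes(pe2, character(), ann), "empty")
})
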