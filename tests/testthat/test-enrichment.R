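test_that("hypergeometric tail matches closed forms and direct summation", {
  expect_equal(hypergeomUpperTail(5, 5, 5, 20), 1 / 15504,
               tolerance = 1e-12)
  expect_equal(hypergeomUpperTail(0, 3, 4, 10), 1)
  expect_equal(hypergeomUpperTail(1, 1, 10, 10), 1)
  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(20:200, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomUpperTail(k, n, K, N), sumHyperTail(k, n, K, N),
                 tolerance = 1e-10,
                 label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
  }
  expect_error(hypergeomUpperTail(6, 5, 5, 20), "invalid")
})

test_that("hypergeometric tail agrees with Monte-Carlo draws within 3 SE", {
  set.seed(2024)
  B <- 1e5
  for (i in 1:8) {
    N <- sample(30:100, 1); K <- sample(5:(N - 5), 1)
    n <- sample(5:(N - 5), 1); k <- sample(0:min(n, K), 1)
    draws <- rhyper(B, K, N - K, n)
    phat <- mean(draws >= k)
    p <- hypergeomUpperTail(k, n, K, N)
    se <- sqrt(max(p * (1 - p), 1 / B) / B)
    expect_lte(abs(phat - p), 3 * se + 1e-12,
               label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
  }
})

test_that("BH step-up matches the hand-computed example and dominates input", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(1), 1)
  set.seed(1)
  p <- runif(50)
  q <- bhFdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  # manual step-up on a shuffled vector, preserving input order
  ord <- order(p)
  manual <- numeric(50)
  manual[ord] <- rev(cummin(rev(p[ord] * 50 / seq_len(50))))
  expect_equal(q, pmin(manual, 1))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("module identical to a signature ranks first at the closed-form p", {
  pop <- sprintf("G%03d", 1:100)
  mem <- setNames(rep("M1", 10), pop[1:10])
  sigs <- SignatureSet(list(match = pop[1:10],
                            other = pop[11:40],
                            offPop = paste0("X", 1:10)))
  tab <- enrichModules(Partition(mem), sigs, pop, minSize = 5,
                       maxSize = 1500, fdrThreshold = 1, top = Inf)
  expect_identical(tab$signature[1], "match")
  expect_equal(tab$p[1], 1 / choose(100, 10), tolerance = 1e-12)
  # signature fully outside the population is excluded before testing
  expect_false("offPop" %in% tab$signature)
})

test_that("size filters, FDR threshold and top-N are applied as specified", {
  pop <- sprintf("G%03d", 1:60)
  mem <- setNames(rep(c("M1", "M2"), each = 10), pop[1:20])
  sigs <- SignatureSet(list(tiny = pop[1:4],          # size 4 < 5: excluded
                            hit = pop[1:10],
                            hit2 = pop[c(1:8, 21, 22)],
                            rand = pop[30:50]))
  tab <- enrichModules(Partition(mem), sigs, pop)
  expect_false("tiny" %in% tab$signature)
  expect_true(all(tab$fdr < 0.1))
  top1 <- enrichModules(Partition(mem), sigs, pop, fdrThreshold = 1, top = 1)
  expect_true(all(table(top1$module) <= 1))
  # FDR >= p within the corrected family
  full <- enrichModules(Partition(mem), sigs, pop, fdrThreshold = 1,
                        top = Inf)
  expect_true(all(full$fdr >= full$p - 1e-15))
})

test_that("raw p is invariant to renaming and to irrelevant signatures", {
  pop <- sprintf("G%03d", 1:50)
  mem <- setNames(rep("M1", 8), pop[1:8])
  sigs <- SignatureSet(list(s1 = pop[c(1:5, 20:24)]))
  t1 <- enrichModules(Partition(mem), sigs, pop, minSize = 1,
                      fdrThreshold = 1, top = Inf)
  # permute names consistently
  set.seed(9)
  perm <- setNames(sample(pop), pop)
  t2 <- enrichModules(Partition(setNames(rep("M1", 8), perm[pop[1:8]])),
                      SignatureSet(list(s1 = perm[pop[c(1:5, 20:24)]])),
                      perm[pop], minSize = 1, fdrThreshold = 1, top = Inf)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)

  sigs2 <- SignatureSet(list(s1 = pop[c(1:5, 20:24)], junk = pop[40:49]))
  t3 <- enrichModules(Partition(mem), sigs2, pop, minSize = 1,
                      fdrThreshold = 1, top = Inf)
  expect_equal(t3$p[t3$signature == "s1"], t1$p[t1$signature == "s1"],
               tolerance = 1e-15)
})

test_that("depletion uses the lower tail with the same filters", {
  pop <- sprintf("G%03d", 1:40)
  mem <- setNames(rep("M1", 10), pop[1:10])
  sigs <- SignatureSet(list(absent = pop[31:40]))
  tab <- enrichModules(Partition(mem), sigs, pop, direction = "depleted",
                       fdrThreshold = 1, top = Inf)
  expect_identical(tab$direction, "depleted")
  expect_equal(tab$p, hypergeomLowerTail(0, 10, 10, 40), tolerance = 1e-12)
  expect_error(enrichModules(Partition(mem), sigs, pop[1:5]),
               "outside the population")
})
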