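test_that("CDI reduces to the gene-specific fit for K = 1 and is label-symmetric", {
  set.seed(21)
  fx <- nbClusterMatrix(20, c(120, 80), mu = cbind(runif(20, 0.3, 2),
                                                   runif(20, 0.3, 2)),
                        phi = 0.5, seed = 21)
  sf <- computeSizeFactors(fx$counts)
  one <- LabelSet(rep(1L, 200), name = "one")
  s1 <- computeCDI(fx$counts, one, sf)
  gs <- fitFamily(fx$counts, "gene-specific-nb", sizeFactors = sf)
  expect_equal(cdiAIC(s1), -2 * logLik(gs) + 2 * (2 * 20))
  # relabeling 1 <-> 2 leaves loglik, df and both scores unchanged
  s <- computeCDI(fx$counts, fx$labels, sf)
  flip <- LabelSet(3L - labels(fx$labels), name = "flipped")
  sFlip <- computeCDI(fx$counts, flip, sf)
  expect_equal(logLik(sFlip), logLik(s))
  expect_identical(sFlip@df, s@df)
  expect_equal(cdiBIC(sFlip), cdiBIC(s))
  # single-batch df bookkeeping and the BIC - AIC identity
  expect_identical(s@df, 2 * 20 * 2)
  expect_equal(cdiBIC(s) - cdiAIC(s), (log(200) - 2) * s@df)
})

test_that("log-likelihood is monotone under refinement; CDI is gene-additive", {
  set.seed(22)
  fx <- nbClusterMatrix(30, c(100, 100, 100),
                        mu = matrix(runif(90, 0.3, 2), 30, 3), phi = 0.4,
                        seed = 22)
  sf <- computeSizeFactors(fx$counts)
  lab <- labels(fx$labels)
  coarse <- computeCDI(fx$counts, fx$labels, sf)
  refined <- lab; refined[lab == 2][1:40] <- 4L
  fine <- computeCDI(fx$counts, LabelSet(refined), sf)
  expect_gte(logLik(fine), logLik(coarse) - 1e-4)
  # -2 loglik and df are additive over disjoint gene subsets
  sA <- computeCDI(fx$counts[1:12, ], fx$labels, sf)
  sB <- computeCDI(fx$counts[13:30, ], fx$labels, sf)
  expect_equal(logLik(sA) + logLik(sB), logLik(coarse), tolerance = 1e-8)
  expect_identical(sA@df + sB@df, coarse@df)
})

test_that("CDI prefers the true labels to random labels on separated data", {
  wins <- vapply(1:10, function(seed) {
    set.seed(seed)
    mu <- matrix(CDIndex:::rtruncnorm0(60, 0.3, 0.15), 20, 3)
    mu[1:5, 2] <- mu[1:5, 2] * 6; mu[6:10, 3] <- mu[6:10, 3] * 6
    fx <- nbClusterMatrix(20, c(100, 100, 100), mu = mu, phi = 0.5,
                          seed = seed)
    sf <- rep(1, 300)   # tiny gene panels leave some cells all-zero
    sTrue <- computeCDI(fx$counts, fx$labels, sf)
    rnd <- LabelSet(sample(1:3, 300, replace = TRUE), name = "random")
    sRnd <- computeCDI(fx$counts, rnd, sf)
    (cdiAIC(sTrue) < cdiAIC(sRnd)) && (cdiBIC(sTrue) < cdiBIC(sRnd))
  }, TRUE)
  expect_true(all(wins))
})

test_that("batch-effect LRT: nesting, identical batches, and null calibration", {
  set.seed(23)
  x <- rnbinom(400, size = 2, mu = 2)
  same <- batchEffectLRT(c(x, x), rep(c("a", "b"), each = 400))
  expect_lt(same$statistic, 1e-4)
  expect_false(same$rejected)
  expect_identical(same$df, 2)
  # statistic is non-negative on arbitrary inputs
  stats <- vapply(1:20, function(i) {
    set.seed(i)
    batchEffectLRT(rnbinom(120, size = 1, mu = runif(1, 0.2, 4)),
                   sample(c("a", "b"), 120, TRUE))$statistic
  }, 0)
  expect_true(all(stats >= 0))
  # empty batch level dropped with a warning, df adjusts to represented count
  expect_warning(
    r3 <- batchEffectLRT(c(x, x), factor(rep(c("a", "b"), each = 400),
                                         levels = c("a", "b", "c"))),
    "dropped")
  expect_identical(r3$df, 2)
  expect_identical(r3$nBatches, 2L)
  # under H0 the rejection rate is near the nominal 5%
  set.seed(24)
  rej <- vapply(1:150, function(i) {
    xx <- rnbinom(600, size = 1 / 0.5, mu = 2)
    batchEffectLRT(xx, rep(c("a", "b"), each = 300))$rejected
  }, TRUE)
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
})

test_that("multi-batch CDI keeps batch parameters only where the LRT rejects", {
  set.seed(25)
  G <- 25L; N <- 600
  batch <- rep(c("b1", "b2"), each = N / 2)
  lab <- rep(1:2, N / 2)
  mu <- matrix(CDIndex:::rtruncnorm0(G * 2, 1, 0.4), G, 2)
  X <- matrix(0, G, N)
  for (k in 1:2) {
    cells <- which(lab == k)
    X[, cells] <- rnbinom(G * length(cells), size = 2, mu = rep(mu[, k], length(cells)))
  }
  # inject a real batch effect in the first 5 genes of cluster 1
  shifted <- which(lab == 1 & batch == "b2")
  X[1:5, shifted] <- rnbinom(5 * length(shifted), size = 2,
                             mu = rep(mu[1:5, 1] * 6, length(shifted)))
  cd <- CountData(X, batch = batch)
  s <- computeCDI(cd, LabelSet(lab), rep(1, N))
  bt <- s@batchTests
  expect_identical(nrow(bt), G * 2L)
  # df accounting matches the per-(g,k) decisions exactly
  expect_identical(s@df, sum(ifelse(bt$rejected, 4, 2)))
  hot <- bt$gene %in% sprintf("gene%d", 1:5) & bt$cluster == 1
  expect_true(all(bt$rejected[hot]))
  expect_lt(mean(bt$rejected[!hot]), 0.25)
  expect_equal(cdiBIC(s) - cdiAIC(s), (log(N) - 2) * s@df)
})

test_that("rankLabelSets flags optima deterministically and handles edge cases", {
  set.seed(26)
  fx <- nbClusterMatrix(15, c(80, 80), mu = cbind(rep(0.3, 15), rep(1.5, 15)),
                        phi = 0.5, seed = 26)
  sf <- rep(1, 160)
  lone <- suppressWarnings(rankLabelSets(fx$counts, list(fx$labels), sf))
  expect_identical(lone$aicOptimum, "truth")
  expect_identical(lone$bicOptimum, "truth")
  cands <- list(fx$labels, LabelSet(labels(fx$labels), name = "truth"),
                LabelSet(sample(1:2, 160, TRUE), name = "rnd"))
  expect_warning(expect_warning(r <- rankLabelSets(fx$counts, cands, sf),
                                "duplicate"), "fewer than 10")
  expect_identical(sort(r$report$label_set[1:2]), c("truth", "truth#1"))
  expect_equal(r$report$CDI_BIC[1], r$report$CDI_BIC[2])
  expect_identical(names(r$report)[1:6],
                   c("label_set", "K", "neg2loglik", "df", "CDI_AIC", "CDI_BIC"))
})
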