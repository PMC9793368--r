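test_that("size factors follow the library-size-over-median definition", {
  cd <- CountData(matrix(rep(c(50L, 100L, 200L), each = 2), 2, 3))
  expect_equal(unname(computeSizeFactors(cd)), c(0.5, 1, 2))
  # even N: midpoint-of-middle-two median convention
  cd2 <- CountData(matrix(rep(c(50L, 100L, 150L, 200L), each = 2), 2, 4))
  expect_equal(unname(computeSizeFactors(cd2)), c(0.4, 0.8, 1.2, 1.6))
  cd3 <- CountData(matrix(5L, 2, 3))
  expect_equal(unname(computeSizeFactors(cd3)), rep(1, 3))
  expect_equal(unname(computeSizeFactors(cd2, center = "mean")),
               c(50, 100, 150, 200) / 125)
  cdBad <- CountData(cbind(c(1L, 2L), c(0L, 0L)), cellIds = c("ok", "empty"))
  expect_error(computeSizeFactors(cdBad), "'empty'")
})

test_that("NB log pmf: closed forms, Poisson limit, and tail normalization", {
  m <- 2.3; phi <- 0.7
  expect_equal(nbLogPmf(0, m, phi), -(1 / phi) * log(1 + phi * m))
  expect_equal(nbLogPmf(3, 2, 1e-10), dpois(3, 2, log = TRUE), tolerance = 1e-6)
  expect_equal(nbLogPmf(4, 2, 0), dpois(4, 2, log = TRUE))
  expect_identical(nbLogPmf(0, 0, 0.5), 0)
  expect_identical(nbLogPmf(2, 0, 0.5), -Inf)
  expect_error(nbLogPmf(-1, 2, 0.5), "non-negative")
  expect_error(nbLogPmf(1, -2, 0.5), "mean")
  # agreement with the standard library parametrization (size = 1/phi)
  expect_equal(nbLogPmf(0:20, 1.7, 0.8),
               dnbinom(0:20, size = 1 / 0.8, mu = 1.7, log = TRUE))
  # brute-force normalization oracle over a parameter grid
  set.seed(9)
  for (i in 1:20) {
    m <- runif(1, 0.05, 20); phi <- runif(1, 0, 3)
    expect_lt(abs(sum(exp(nbLogPmf(0:10000, m, phi))) - 1), 1e-10)
  }
})

test_that("ZINB log pmf is the stable log-space mixture", {
  x <- 0:50
  expect_equal(zinbLogPmf(x, 1.7, 0.8, 0), nbLogPmf(x, 1.7, 0.8))
  expect_equal(zinbLogPmf(3, 1.7, 0.8, 0.3),
               log(1 - 0.3) + nbLogPmf(3, 1.7, 0.8))
  expect_lt(abs(sum(exp(zinbLogPmf(0:10000, 1.7, 0.8, 0.25))) - 1), 1e-10)
  expect_error(zinbLogPmf(0, 1, 0.5, 1), "pi0")
})

test_that("single-cell NB MLE hits boundaries and beats a grid-search oracle", {
  expect_equal(fitNBCell(rep(0L, 10)),
               list(mu = 0, phi = 0, loglik = 0, converged = TRUE))
  # equal size factors: mean score equation gives mu = xbar / s
  set.seed(10)
  x <- rnbinom(500, size = 2, mu = 3)
  f0 <- fitNBCell(x, rep(2, 500))
  expect_equal(f0$mu, mean(x) / 2, tolerance = 1e-6)
  # parameter recovery with heterogeneous size factors + grid dominance
  s <- rep(c(0.5, 1, 2), length.out = 2000)
  x2 <- rnbinom(2000, size = 1 / 0.6, mu = 3 * s)
  f <- fitNBCell(x2, s)
  expect_lt(abs(f$mu - 3), 0.1)
  expect_lt(abs(f$phi - 0.6), 0.1)
  grid <- expand.grid(mu = seq(1, 5, length.out = 50),
                      phi = seq(0.1, 1.5, length.out = 50))
  gridLL <- mapply(function(m, p) sum(nbLogPmf(x2, s * m, p)),
                   grid$mu, grid$phi)
  expect_gte(f$loglik, max(gridLL))
})

test_that("NB MLE bias shrinks as n grows", {
  err <- vapply(c(200, 2000, 20000), function(n) {
    set.seed(n)
    x <- rnbinom(n, size = 1 / 0.5, mu = 2)
    f <- fitNBCell(x)
    abs(f$mu - 2) + abs(f$phi - 0.5)
  }, 0)
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.05)
})

test_that("family fits are monotone under nesting and exact for degenerate K", {
  set.seed(11)
  fx <- nbClusterMatrix(40, c(150, 150), mu = cbind(runif(40, 0.5, 3),
                                                    runif(40, 0.5, 3)),
                        phi = 0.5, seed = 11)
  sf <- computeSizeFactors(fx$counts)
  fits <- lapply(c("gene-common-nb", "gene-common-zinb", "gene-specific-nb",
                   "gene-specific-zinb"), fitFamily, counts = fx$counts,
                 sizeFactors = sf)
  names(fits) <- c("gcNB", "gcZINB", "gsNB", "gsZINB")
  tol <- 1e-4
  expect_lte(logLik(fits$gcNB), logLik(fits$gsNB) + tol)
  expect_lte(logLik(fits$gcNB), logLik(fits$gcZINB) + tol)
  expect_lte(logLik(fits$gsNB), logLik(fits$gsZINB) + tol)
  ctc <- fitFamily(fx$counts, "cell-type-common-nb", fx$labels, sf)
  cts <- fitFamily(fx$counts, "cell-type-specific-nb", fx$labels, sf)
  expect_lte(logLik(ctc), logLik(cts) + tol)
  # K = 1: cell-type-specific equals the gene-specific fit exactly
  one <- LabelSet(rep(1L, ncol(fx$counts)))
  expect_equal(logLik(fitFamily(fx$counts, "cell-type-specific-nb", one, sf)),
               logLik(fitFamily(fx$counts, "gene-specific-nb",
                                sizeFactors = sf)))
  # stored loglik is recomputable from stored parameters
  p <- fitParams(cts)
  row <- p[which(p$mu > 0)[1], ]
  cells <- which(labels(fx$labels) == row$cluster)
  x <- umiCounts(fx$counts)[row$gene, cells]
  expect_equal(row$loglik, sum(nbLogPmf(x, sf[cells] * row$mu, row$phi)),
               tolerance = 1e-8)
})

test_that("gene-common dispersion is recovered from shared-dispersion data", {
  G <- 200; n <- 2000
  set.seed(12)
  mu <- runif(G, 0.5, 4)
  X <- matrix(rnbinom(G * n, size = 1 / 0.4, mu = rep(mu, n)), G, n)
  fit <- fitFamily(CountData(X), "gene-common-nb",
                   sizeFactors = rep(1, n))
  expect_equal(fitParams(fit)$phi[1], 0.4, tolerance = 0.04)
})

test_that("held-out zero proportions are calibrated for the generating family", {
  set.seed(13)
  G <- 60
  mu <- matrix(CDIndex:::rtruncnorm0(G * 2, 0.8, 0.3), G, 2)
  fx <- nbClusterMatrix(G, c(400, 400), mu = mu,
                        phi = matrix(rep(c(0.2, 1.5), each = G), G, 2),
                        seed = 13)
  N <- ncol(fx$counts)
  tr <- sample(N, N / 2); te <- setdiff(seq_len(N), tr)
  sTr <- rep(1, N / 2); sTe <- rep(1, N / 2)
  labTr <- LabelSet(labels(fx$labels)[tr]); labTe <- LabelSet(labels(fx$labels)[te])
  spec <- fitFamily(fx$counts[, tr], "cell-type-specific-nb", labTr, sTr)
  comm <- fitFamily(fx$counts[, tr], "cell-type-common-nb", labTr, sTr)
  ds <- predictZeroProportions(spec, fx$counts[, te], labTe, sTe)
  dc <- predictZeroProportions(comm, fx$counts[, te], labTe, sTe)
  expect_lt(abs(mean(ds$diff)), 0.02)
  # the pooled fit misstates zeros with opposite signs in the two clusters
  expect_lt(mean(dc$diff[dc$cluster == 1]), -0.01)
  expect_gt(mean(dc$diff[dc$cluster == 2]), 0.01)
  # Poisson-like closed form
  fitP <- fitFamily(CountData(matrix(rpois(2000, 2), 1, 2000)),
                    "gene-specific-nb", sizeFactors = rep(1, 2000))
  pz <- predictZeroProportions(fitP,
                               CountData(matrix(rpois(1000, 2), 1, 1000)),
                               sizeFactors = rep(1, 1000))
  expect_equal(pz$expected, exp(-fitParams(fitP)$mu[1]), tolerance = 1e-6)
})
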