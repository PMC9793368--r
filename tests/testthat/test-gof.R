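test_that("df bookkeeping follows 5*K0 - p - 1 for both families", {
  set.seed(31)
  fx <- nbClusterMatrix(1, rep(120, 5), mu = matrix(runif(5, 0.5, 2), 1, 5),
                        phi = 0.5, seed = 31)
  x <- as.numeric(umiCounts(fx$counts)[1, ])
  rs <- gofTestGene(x, fx$labels, family = "cell-type-specific")
  expect_identical(rs$df, 5 * 5 - 2 * 5 - 1)   # p = 2 K0 -> 14
  rc <- gofTestGene(x, fx$labels, family = "cell-type-common")
  expect_identical(rc$df, 5 * 5 - 2 - 1)       # p = 2 -> 22
  # K0 = 1: both reduce to the monoclonal test with df 2
  one <- LabelSet(rep(1L, length(x)))
  expect_identical(gofTestGene(x, one, family = "cell-type-specific")$df, 2)
  expect_identical(gofTestGene(x, one, family = "cell-type-common")$df, 2)
})

test_that("statistic is non-negative, permutation-invariant, and sane", {
  set.seed(32)
  fx <- nbClusterMatrix(1, c(300, 300), mu = matrix(c(0.8, 2), 1, 2),
                        phi = 0.6, seed = 32)
  x <- as.numeric(umiCounts(fx$counts)[1, ])
  r <- gofTestGene(x, fx$labels, family = "cell-type-specific")
  expect_gte(r$statistic, 0)
  expect_equal(sum(r$observed), length(x))
  expect_lt(abs(sum(r$expected) - 1), 1e-6)
  flip <- LabelSet(3L - labels(fx$labels))
  rf <- gofTestGene(x, flip, family = "cell-type-specific")
  expect_equal(rf$statistic, r$statistic, tolerance = 1e-6)
  # all-zero gene is untestable, not a spurious rejection
  rz <- gofTestGene(rep(0L, 600), fx$labels)
  expect_true(rz$untestable)
})

test_that("rejection rate is conservative with plug-in proportions and near
           nominal with known proportions under multinomial labels", {
  G <- 300; N <- 1200; K <- 3
  pars <- sd1BaselineParams(G, K, seed = 33)
  # fixed equal cluster sizes, plug-in proportions (the default reading)
  fxFixed <- nbClusterMatrix(G, rep(N / K, K), pars$mu, pars$phi, seed = 34)
  rFixed <- gofRejectionRate(fxFixed$counts, fxFixed$labels,
                             family = "cell-type-specific", sizeFactors = NULL)
  expect_lt(rFixed$rate, 0.06)
  # multinomial labels + known proportions: the printed df becomes exact by
  # restoring the cluster-size deviation term that plug-in proportions
  # constrain to zero. That term is shared by every gene of one dataset, so
  # the check pools label redraws and uses the paired statistic gap (its
  # unconditional mean is the 2-df difference between the two readings).
  set.seed(35)
  gaps <- c(); rejKnown <- c(); rejPlug <- c()
  for (rep in 1:30) {
    g <- 30
    mu <- matrix(CDIndex:::rtruncnorm0(g * K, 0.2, 0.1), g, K)
    phi <- matrix(CDIndex:::rtruncnorm0(g * K, 0.5, 0.1), g, K)
    labv <- sample.int(K, 900, replace = TRUE)
    X <- matrix(0, g, 900)
    for (k in seq_len(K)) {
      cells <- which(labv == k)
      X[, cells] <- rnbinom(g * length(cells),
                            size = rep(1 / phi[, k], length(cells)),
                            mu = rep(mu[, k], length(cells)))
    }
    cd <- CountData(X); lab <- LabelSet(labv)
    rk <- gofRejectionRate(cd, lab, family = "cell-type-specific",
                           sizeFactors = NULL, clusterProbs = rep(1 / K, K))
    rp <- gofRejectionRate(cd, lab, family = "cell-type-specific",
                           sizeFactors = NULL)
    ok <- !rk$table$untestable & !rp$table$untestable
    expect_true(all(rk$table$statistic[ok] >= 0))
    gaps <- c(gaps, rk$table$statistic[ok] - rp$table$statistic[ok])
    rejKnown <- c(rejKnown, rk$table$rejected[ok])
    rejPlug <- c(rejPlug, rp$table$rejected[ok])
  }
  expect_gt(mean(gaps), 0.8)       # restored marginal term, ~2 in theory
  expect_lt(mean(gaps), 3.5)
  expect_gte(mean(rejKnown), mean(rejPlug))
  expect_gt(mean(rejKnown), 0.01)
  expect_lt(mean(rejKnown), 0.10)
})

test_that("misfit detection: pooled family rejected when dispersions vary", {
  G <- 150
  set.seed(36)
  mu <- matrix(CDIndex:::rtruncnorm0(G * 2, 1, 0.3), G, 2)
  fx <- nbClusterMatrix(G, c(400, 400), mu = mu,
                        phi = matrix(rep(c(0.15, 1.5), each = G), G, 2),
                        seed = 36)
  rSpec <- gofRejectionRate(fx$counts, fx$labels,
                            family = "cell-type-specific", sizeFactors = NULL)
  rComm <- gofRejectionRate(fx$counts, fx$labels,
                            family = "cell-type-common", sizeFactors = NULL)
  expect_gt(rComm$rate, rSpec$rate)      # power ordering
  expect_gt(rComm$rate, 0.25)
  expect_lt(rSpec$rate, 0.1)
  # power grows with N for the misspecified family
  fxSmall <- nbClusterMatrix(G, c(100, 100), mu = mu,
                             phi = matrix(rep(c(0.15, 1.5), each = G), G, 2),
                             seed = 37)
  rCommSmall <- gofRejectionRate(fxSmall$counts, fxSmall$labels,
                                 family = "cell-type-common",
                                 sizeFactors = NULL)
  expect_gte(rComm$rate, rCommSmall$rate)
  # rates are proportions
  for (r in list(rSpec, rComm)) {
    expect_gte(r$rate, 0); expect_lte(r$rate, 1)
  }
})

test_that("all-untestable input errors rather than reporting a rate", {
  cd <- CountData(matrix(0L, 3, 100))
  lab <- LabelSet(rep(1:2, 50))
  expect_error(gofRejectionRate(cd, lab, sizeFactors = NULL), "no testable")
})
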