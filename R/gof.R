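# UMI count categories for the binned goodness-of-fit test:
# {0}, {1}, {2}, {3}, [4, Inf).
.nBins <- 5L

# NB probabilities of the five count categories, averaged over cells' size
# factors. sU are the unique size factors, wU their weights (cell counts).
.binProbs <- function(mu, phi, sU, wU) {
  m <- sU * mu
  p <- vapply(0:3, function(j)
    sum(wU * exp(nbLogPmf(j, m, phi))) / sum(wU), 0)
  c(p, max(0, 1 - sum(p)))
}

# Multinomial MLE of (mu, phi) for one cluster's binned counts.
.binnedMLE <- function(nvec, sU, wU, muInit, phiInit) {
  obj <- function(par) {
    p <- .binProbs(exp(par[1]), exp(par[2]), sU, wU)
    pos <- nvec > 0
    if (any(p[pos] <= 0)) return(1e12)
    -sum(nvec[pos] * log(p[pos]))
  }
  init <- c(log(max(muInit, 1e-4)), log(max(phiInit, 1e-4)))
  opt <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(-20, log(1e-8)), upper = c(15, log(1e6)),
                      control = list(maxit = 500, factr = 1e5))
  list(mu = exp(opt$par[1]), phi = exp(opt$par[2]), value = -opt$value)
}

#' Binned chi-squared goodness-of-fit test for one gene
#'
#' Cells are cross-classified into the 5 x K0 bins of count category
#' ({0}, {1}, {2}, {3}, [4, Inf)) by cluster. Expected bin probabilities are
#' pi_{U,k} = (N_k / N) * p_{U,k}(mu, phi), with p the NB bin probability
#' averaged over the cluster's cells' size factors; (mu, phi) — one pair per
#' cluster for the cell-type-specific family, one shared pair for the
#' cell-type-common family — maximize the multinomial likelihood of the bin
#' counts. The statistic T = sum (n_{U,k} - N pi_{U,k})^2 / (N pi_{U,k}) is
#' referred to the 95\% chi-squared quantile with 5 K0 - p - 1 degrees of
#' freedom, p = 2 K0 (specific) or 2 (common). Genes with an expected bin
#' count below \code{floor * N} are flagged untestable instead of producing an
#' inflated statistic.
#'
#' @param x one gene's counts over all cells.
#' @param labelSet benchmark \linkS4class{LabelSet} (K0 clusters).
#' @param sizeFactors per-cell size factors; pass \code{rep(1, N)} for the
#'   plain iid reading of the statistic.
#' @param family \code{"cell-type-specific"} or \code{"cell-type-common"}.
#' @param alpha test level (default 0.05, i.e. the 95\% quantile threshold).
#' @param floor untestability floor on expected bin proportions.
#' @param clusterProbs optional vector of known cluster proportions. The
#'   default (NULL) plugs in the observed N_k / N; the printed df is then
#'   conservative because the cluster bin totals are constrained. Supplying
#'   known proportions makes the printed df exact when cells fall into
#'   clusters multinomially.
#' @return List: statistic, df, threshold, pvalue, rejected, untestable,
#'   observed (5 x K0 counts), expected (5 x K0 probabilities), mu, phi.
#' @export
gofTestGene <- function(x, labelSet, sizeFactors = rep(1, length(x)),
                        family = c("cell-type-specific", "cell-type-common"),
                        alpha = 0.05, floor = 1e-8, clusterProbs = NULL) {
  family <- match.arg(family)
  K <- nClusters(labelSet)
  lab <- labels(labelSet)
  N <- length(x)
  stopifnot(length(lab) == N, length(sizeFactors) == N)
  cat5 <- pmin(x, 4L) + 1L
  obs <- matrix(0, .nBins, K)
  for (k in seq_len(K))
    obs[, k] <- tabulate(cat5[lab == k], .nBins)
  Nk <- colSums(obs)
  sByK <- lapply(seq_len(K), function(k) {
    tt <- table(sizeFactors[lab == k])
    list(sU = as.numeric(names(tt)), wU = as.numeric(tt))
  })
  momInit <- function(cells) {
    m <- mean(x[cells]) / mean(sizeFactors[cells])
    v <- stats::var(x[cells])
    list(mu = m, phi = if (m > 0) max((v - m) / m^2, 1e-4) else 1e-4)
  }
  if (family == "cell-type-specific") {
    fits <- lapply(seq_len(K), function(k) {
      if (sum(obs[-1, k]) == 0) return(list(mu = 0, phi = 0))
      ini <- momInit(which(lab == k))
      .binnedMLE(obs[, k], sByK[[k]]$sU, sByK[[k]]$wU, ini$mu, ini$phi)
    })
    mu <- vapply(fits, `[[`, 0, "mu"); phi <- vapply(fits, `[[`, 0, "phi")
    p <- vapply(seq_len(K), function(k)
      .binProbs(mu[k], phi[k], sByK[[k]]$sU, sByK[[k]]$wU), numeric(.nBins))
    pFree <- 2 * K
  } else {
    ini <- momInit(seq_len(N))
    obj <- function(par) {
      ll <- 0
      for (k in seq_len(K)) {
        p <- .binProbs(exp(par[1]), exp(par[2]), sByK[[k]]$sU, sByK[[k]]$wU)
        pos <- obs[, k] > 0
        if (any(p[pos] <= 0)) return(1e12)
        ll <- ll + sum(obs[pos, k] * log(p[pos]))
      }
      -ll
    }
    opt <- stats::optim(c(log(max(ini$mu, 1e-4)), log(max(ini$phi, 1e-4))),
                        obj, method = "L-BFGS-B",
                        lower = c(-20, log(1e-8)), upper = c(15, log(1e6)),
                        control = list(maxit = 500, factr = 1e5))
    mu <- rep(exp(opt$par[1]), K); phi <- rep(exp(opt$par[2]), K)
    p <- vapply(seq_len(K), function(k)
      .binProbs(mu[k], phi[k], sByK[[k]]$sU, sByK[[k]]$wU), numeric(.nBins))
    pFree <- 2
  }
  props <- if (is.null(clusterProbs)) Nk / N else {
    stopifnot(length(clusterProbs) == K, all(clusterProbs > 0))
    clusterProbs / sum(clusterProbs)
  }
  expectedPi <- sweep(p, 2, props, `*`)
  df <- .nBins * K - pFree - 1
  untestable <- any(expectedPi < floor) || df < 1
  if (untestable)
    return(list(statistic = NA_real_, df = df,
                threshold = NA_real_, pvalue = NA_real_, rejected = NA,
                untestable = TRUE, observed = obs, expected = expectedPi,
                mu = mu, phi = phi))
  stat <- sum((obs - N * expectedPi)^2 / (N * expectedPi))
  thr <- stats::qchisq(1 - alpha, df)
  list(statistic = stat, df = df, threshold = thr,
       pvalue = stats::pchisq(stat, df, lower.tail = FALSE),
       rejected = stat > thr, untestable = FALSE, observed = obs,
       expected = expectedPi, mu = mu, phi = phi)
}

#' Goodness-of-fit rejection rate over all genes
#'
#' Runs \code{gofTestGene} on every gene and reports the proportion of
#' testable genes whose fit is rejected — the overall adequacy criterion for a
#' distribution family. Untestable genes are reported separately and excluded
#' from the denominator.
#'
#' @param counts a (pre-filtered) \linkS4class{CountData}.
#' @param labelSet benchmark labels.
#' @param family,alpha,floor,clusterProbs passed to \code{gofTestGene}.
#' @param sizeFactors per-cell size factors (default computed from
#'   \code{counts}); pass \code{NULL} for the iid reading (all 1).
#' @return List: \code{rate} (rejected / testable), \code{nTestable},
#'   \code{nUntestable}, and \code{table} (per-gene data.frame).
#' @export
gofRejectionRate <- function(counts, labelSet,
                             family = c("cell-type-specific", "cell-type-common"),
                             alpha = 0.05, sizeFactors = computeSizeFactors(counts),
                             floor = 1e-8, clusterProbs = NULL) {
  family <- match.arg(family)
  if (is.null(sizeFactors)) sizeFactors <- rep(1, ncol(counts))
  X <- denseCounts(counts)
  res <- lapply(seq_len(nrow(X)), function(g) {
    r <- gofTestGene(X[g, ], labelSet, sizeFactors, family, alpha, floor,
                     clusterProbs)
    data.frame(gene = rownames(X)[g], statistic = r$statistic, df = r$df,
               pvalue = r$pvalue, rejected = r$rejected,
               untestable = r$untestable)
  })
  tab <- do.call(rbind, res)
  testable <- !tab$untestable
  if (!any(testable)) stop("no testable genes")
  list(rate = mean(tab$rejected[testable]), nTestable = sum(testable),
       nUntestable = sum(!testable), table = tab)
}
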