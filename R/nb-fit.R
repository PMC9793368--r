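#' Maximum-likelihood NB fit for one vector of counts
#'
#' Maximizes \eqn{\sum_c \log NB(x_c \mid s_c \mu, \phi)} over \eqn{\mu \ge 0}
#' and \eqn{\phi \in [0, 10^6]} by profile likelihood: the mean score equation
#' is solved exactly by Newton at each candidate dispersion, and the profile is
#' maximized over log(phi) (golden section after a coarse grid), with the
#' Poisson boundary phi = 0 always considered. All-zero input returns
#' (0, 0, loglik 0) exactly.
#'
#' @param x non-negative integer counts.
#' @param s positive size factors, one per observation (default all 1).
#' @return List with \code{mu}, \code{phi}, \code{loglik}, \code{converged}.
#' @export
fitNBCell <- function(x, s = rep(1, length(x))) {
  if (length(x) < 1L) stop("need at least one observation")
  if (any(x < 0) || any(x != floor(x))) stop("counts must be non-negative integers")
  if (length(s) != length(x) || any(s <= 0)) stop("invalid size factors")
  r <- cpp_fit_nb(as.numeric(x), as.numeric(s))
  out <- list(mu = r[1], phi = r[2], loglik = r[3], converged = r[4] == 1)
  if (!out$converged)
    warning("NB fit did not meet the convergence tolerance; best iterate returned")
  out
}

.nbFamilies <- c("gene-common-nb", "gene-common-zinb", "gene-specific-nb",
                 "gene-specific-zinb", "cell-type-common-nb",
                 "cell-type-specific-nb")

# ZINB fit for one gene: direct 3-parameter optimization started from the NB
# solution; the NB boundary (pi0 -> 0) is kept as a candidate so the maximized
# likelihood never drops below the nested NB fit.
fitZINBCell <- function(x, s = rep(1, length(x))) {
  if (sum(x) == 0)
    return(list(mu = 0, phi = 0, pi0 = 0, loglik = 0, converged = TRUE))
  nb <- fitNBCell(x, s)
  p0obs <- mean(x == 0)
  p0nb <- mean(exp(nbLogPmf(0, s * nb$mu, nb$phi)))
  pi0init <- min(max((p0obs - p0nb) / max(1 - p0nb, 1e-8), 1e-4), 0.9)
  obj <- function(par) {
    mu <- exp(par[1]); phi <- exp(par[2]); pi0 <- stats::plogis(par[3])
    -sum(zinbLogPmf(x, s * mu, phi, pi0))
  }
  init <- c(log(max(nb$mu, 1e-8)), log(max(nb$phi, 1e-6)), stats::qlogis(pi0init))
  opt <- try(stats::optim(init, obj, method = "L-BFGS-B",
                          lower = c(-30, log(1e-8), -30), upper = c(30, log(1e6), 10),
                          control = list(maxit = 500, factr = 1e4)), silent = TRUE)
  if (inherits(opt, "try-error") || -opt$value < nb$loglik)
    return(list(mu = nb$mu, phi = nb$phi, pi0 = 0, loglik = nb$loglik,
                converged = nb$converged))
  pi0 <- stats::plogis(opt$par[3])
  list(mu = exp(opt$par[1]), phi = exp(opt$par[2]),
       pi0 = if (pi0 < 1e-8) 0 else pi0, loglik = -opt$value,
       converged = opt$convergence == 0)
}

# Profile fit of a dispersion (and, for ZINB, zero-inflation) shared across
# genes with gene-specific means.
fitGeneCommon <- function(X, s, zinb = FALSE) {
  G <- nrow(X)
  if (!zinb) {
    prof <- function(lphi) sum(cpp_nb_mu_given_phi(X, s, 10^lphi)$loglik)
    llPois <- sum(cpp_nb_mu_given_phi(X, s, 0)$loglik)
    opt <- stats::optimize(prof, c(-6, 6), maximum = TRUE, tol = 1e-6)
    if (llPois >= opt$objective) {
      phi <- 0; fit <- cpp_nb_mu_given_phi(X, s, 0)
    } else {
      phi <- 10^opt$maximum; fit <- cpp_nb_mu_given_phi(X, s, phi)
    }
    return(list(mu = fit$mu, phi = phi, pi0 = NULL, loglik = fit$loglik))
  }
  # shared (phi, pi0); per-gene mean by 1-D search on each gene
  geneLL <- function(g, phi, pi0) {
    x <- X[g, ]
    if (sum(x) == 0) return(c(0, 0))
    f <- function(lmu) sum(zinbLogPmf(x, s * exp(lmu), phi, pi0))
    o <- stats::optimize(f, c(-20, 15), maximum = TRUE, tol = 1e-6)
    c(exp(o$maximum), o$objective)
  }
  obj <- function(par) {
    phi <- exp(par[1]); pi0 <- stats::plogis(par[2])
    -sum(vapply(seq_len(G), function(g) geneLL(g, phi, pi0)[2], 0))
  }
  opt <- stats::optim(c(log(0.5), stats::qlogis(0.05)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  phi <- exp(opt$par[1]); pi0 <- stats::plogis(opt$par[2])
  per <- vapply(seq_len(G), function(g) geneLL(g, phi, pi0), c(0, 0))
  list(mu = per[1, ], phi = phi, pi0 = pi0, loglik = per[2, ])
}

#' Fit an NB/ZINB distribution family to a count matrix
#'
#' Six families are supported. The monoclonal families treat all cells as one
#' population: \code{gene-specific-nb}/\code{gene-specific-zinb} fit every gene
#' independently, while the \code{gene-common} variants share one dispersion
#' (and, for ZINB, one zero-inflation probability) across genes via profile
#' likelihood. The polyclonal families require labels:
#' \code{cell-type-specific-nb} fits each (gene, cluster) cell independently;
#' \code{cell-type-common-nb} pools cells across clusters per gene.
#'
#' @param counts a \linkS4class{CountData}.
#' @param family one of the six family names (see Details).
#' @param labelSet a \linkS4class{LabelSet}; required for the two cell-type
#'   families.
#' @param sizeFactors per-cell size factors (default
#'   \code{computeSizeFactors(counts)}).
#' @return An \linkS4class{NBFit}.
#' @export
fitFamily <- function(counts, family = .nbFamilies, labelSet = NULL,
                      sizeFactors = computeSizeFactors(counts)) {
  family <- match.arg(family)
  X <- denseCounts(counts)
  s <- as.numeric(sizeFactors)
  G <- nrow(X)
  genes <- rownames(X)
  cellType <- startsWith(family, "cell-type")
  if (cellType && is.null(labelSet))
    stop("family '", family, "' requires a label set")
  if (family == "cell-type-specific-nb") {
    checkLabelsMatch(counts, labelSet)
    K <- nClusters(labelSet)
    if (any(tabulate(labels(labelSet), K) == 1L))
      warning("cluster with a single cell; boundary fit allowed")
    f <- cpp_fit_nb_by_cluster(X, s, labels(labelSet), K)
    params <- S4Vectors::DataFrame(
      gene = rep(genes, times = K), cluster = rep(seq_len(K), each = G),
      mu = as.vector(f$mu), phi = as.vector(f$phi),
      loglik = as.vector(f$loglik), converged = as.vector(f$converged) == 1)
  } else if (family %in% c("gene-specific-nb", "cell-type-common-nb")) {
    if (cellType) checkLabelsMatch(counts, labelSet)
    f <- cpp_fit_nb_by_cluster(X, s, rep(1L, ncol(X)), 1L)
    params <- S4Vectors::DataFrame(
      gene = genes, cluster = NA_integer_, mu = as.vector(f$mu),
      phi = as.vector(f$phi), loglik = as.vector(f$loglik),
      converged = as.vector(f$converged) == 1)
  } else if (family == "gene-specific-zinb") {
    fits <- lapply(seq_len(G), function(g) fitZINBCell(X[g, ], s))
    params <- S4Vectors::DataFrame(
      gene = genes, cluster = NA_integer_,
      mu = vapply(fits, `[[`, 0, "mu"), phi = vapply(fits, `[[`, 0, "phi"),
      pi0 = vapply(fits, `[[`, 0, "pi0"),
      loglik = vapply(fits, `[[`, 0, "loglik"),
      converged = vapply(fits, `[[`, TRUE, "converged"))
  } else { # gene-common-nb / gene-common-zinb
    fit <- fitGeneCommon(X, s, zinb = endsWith(family, "zinb"))
    params <- S4Vectors::DataFrame(
      gene = genes, cluster = NA_integer_, mu = fit$mu,
      phi = rep(fit$phi, G), loglik = fit$loglik,
      converged = TRUE)
    if (!is.null(fit$pi0)) params$pi0 <- rep(fit$pi0, G)
  }
  methods::new("NBFit", family = family, params = params,
               loglik = sum(params$loglik))
}

#' Train/test zero-proportion calibration
#'
#' For each gene (and, for the cell-type families, each cluster) compares the
#' zero proportion predicted by a fitted family with the empirical zero
#' fraction on held-out cells: expected = mean over test cells of
#' P(X = 0 | s_c mu, phi[, pi0]); observed = empirical zero fraction. A
#' well-specified family fitted on a disjoint training half gives differences
#' centred at zero.
#'
#' @param fit an \linkS4class{NBFit} trained on a disjoint cell set.
#' @param test a \linkS4class{CountData} of held-out cells.
#' @param testLabels \linkS4class{LabelSet} for the test cells (cell-type
#'   families only).
#' @param sizeFactors size factors of the test cells.
#' @return data.frame(gene, cluster, expected, observed, diff).
#' @export
predictZeroProportions <- function(fit, test, testLabels = NULL,
                                   sizeFactors = computeSizeFactors(test)) {
  p <- fitParams(fit)
  X <- denseCounts(test)
  s <- as.numeric(sizeFactors)
  perCluster <- fit@family == "cell-type-specific-nb" ||
    (fit@family == "cell-type-common-nb" && !is.null(testLabels))
  if (perCluster && is.null(testLabels))
    stop("testLabels required for per-cluster calibration")
  missing <- setdiff(rownames(X), unique(p$gene))
  if (length(missing)) {
    warning(length(missing), " gene(s) in test absent from fit; skipped")
    X <- X[setdiff(rownames(X), missing), , drop = FALSE]
  }
  zeroProb <- function(mu, phi, pi0, sc) {
    pz <- exp(nbLogPmf(0L, sc * mu, phi))
    if (!is.null(pi0) && !is.na(pi0)) pi0 + (1 - pi0) * pz else pz
  }
  rows <- list()
  groups <- if (perCluster) seq_len(nClusters(testLabels)) else NA_integer_
  for (k in groups) {
    cells <- if (is.na(k)) seq_len(ncol(X)) else which(labels(testLabels) == k)
    for (g in rownames(X)) {
      prow <- if (fit@family == "cell-type-specific-nb")
        p[p$gene == g & p$cluster == k, ] else p[p$gene == g, ]
      if (nrow(prow) == 0L) next
      pi0 <- if ("pi0" %in% colnames(prow)) prow$pi0[1] else NULL
      expz <- mean(zeroProb(prow$mu[1], prow$phi[1], pi0, s[cells]))
      obsz <- mean(X[g, cells] == 0)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cluster = k, expected = expz, observed = obsz,
        diff = obsz - expz)
    }
  }
  do.call(rbind, rows)
}
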