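#' Likelihood-ratio test for a batch effect in one (gene, cluster) cell
#'
#' Tests H0: the NB mean and dispersion of this gene in this cluster are equal
#' across batches, against batch-specific parameters, by comparing the pooled
#' fit with the sum of per-batch fits. The statistic
#' 2 (sum of per-batch logliks - pooled loglik) is referred to chi-squared with
#' 2 (B - 1) degrees of freedom, B being the number of batches actually
#' represented among the supplied cells (unrepresented batches are dropped
#' with a warning).
#'
#' @param x counts of one gene over the cluster's cells.
#' @param batches batch assignment of those cells.
#' @param s size factors of those cells.
#' @param alpha test level (default 0.05).
#' @return One-row data.frame: statistic, df, pvalue, rejected, nBatches.
#' @export
batchEffectLRT <- function(x, batches, s = rep(1, length(x)), alpha = 0.05) {
  batches <- as.factor(batches)   # keeps declared-but-empty levels
  present <- levels(batches)[tabulate(batches, nlevels(batches)) > 0]
  if (length(present) < nlevels(batches)) {
    warning("batch level(s) with no cells in this cluster dropped from the test")
    batches <- factor(batches, levels = present)
  }
  B <- nlevels(batches)
  if (B < 2L) stop("need at least two represented batches")
  pooled <- cpp_fit_nb(as.numeric(x), as.numeric(s))[3]
  perBatch <- sum(vapply(levels(batches), function(b) {
    i <- which(batches == b)
    cpp_fit_nb(as.numeric(x[i]), as.numeric(s[i]))[3]
  }, 0))
  stat <- max(0, 2 * (perBatch - pooled))
  df <- 2 * (B - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(statistic = stat, df = df, pvalue = p, rejected = p < alpha,
             nBatches = B)
}

#' Clustering Deviation Index of one candidate label set
#'
#' Scores a label set by the penalized negative maximized log-likelihood of
#' the gene-specific, cell-type-specific NB model: each (gene, cluster) cell
#' gets its own NB mean and dispersion (cell means scaled by per-cell size
#' factors), the maximized log-likelihoods are summed, and
#' CDI = -2 loglik + c_pen * d with c_pen = 2 (AIC) or log N (BIC). For
#' single-batch data d_gk = 2, so d = 2 G K. For multi-batch data each (g, k)
#' is first tested for a batch effect (\code{batchEffectLRT} at
#' \code{batchAlpha}); when rejected, batch-specific parameters are kept and
#' d_gk = 2 B (B = represented batches), otherwise the pooled fit is used and
#' d_gk = 2.
#'
#' The matrix should be restricted to feature genes first
#' (\code{selectFeatureGenes}); the score records a hash of the gene list so
#' scores are only compared within one gene set.
#'
#' @param counts a \linkS4class{CountData}, already restricted to feature
#'   genes.
#' @param labelSet a \linkS4class{LabelSet} for the same cells.
#' @param sizeFactors per-cell size factors.
#' @param batchAlpha level of the per-(g, k) batch-effect LRT.
#' @return A \linkS4class{CDIScore}.
#' @export
computeCDI <- function(counts, labelSet, sizeFactors = computeSizeFactors(counts),
                       batchAlpha = 0.05) {
  checkLabelsMatch(counts, labelSet)
  X <- denseCounts(counts)
  s <- as.numeric(sizeFactors)
  lab <- labels(labelSet)
  K <- nClusters(labelSet)
  G <- nrow(X)
  N <- ncol(X)
  batch <- batchOf(counts)
  emptyTests <- S4Vectors::DataFrame(gene = character(), cluster = integer(),
    statistic = numeric(), df = numeric(), pvalue = numeric(),
    rejected = logical())
  if (is.null(batch) || nlevels(batch) < 2L) {
    fit <- cpp_fit_nb_by_cluster(X, s, lab, K)
    ll <- sum(fit$loglik)
    d <- 2 * G * K
    tests <- emptyTests
  } else {
    pooled <- cpp_fit_nb_by_cluster(X, s, lab, K)
    B <- nlevels(batch)
    perBatch <- lapply(levels(batch), function(b) {
      i <- which(batch == b)
      cpp_fit_nb_by_cluster(X[, i, drop = FALSE], s[i], lab[i], K)
    })
    # batches represented in each cluster (gene-independent)
    repB <- vapply(seq_len(K), function(k)
      sum(vapply(levels(batch), function(b)
        any(batch == b & lab == k), TRUE)), 0L)
    llBatchSum <- Reduce(`+`, lapply(perBatch, `[[`, "loglik"))
    stat <- pmax(0, 2 * (llBatchSum - pooled$loglik))
    df <- matrix(rep(2 * (repB - 1), each = G), G, K)
    pv <- matrix(stats::pchisq(stat, df, lower.tail = FALSE), G, K)
    testable <- df > 0
    rej <- testable & pv < batchAlpha
    ll <- sum(ifelse(rej, llBatchSum, pooled$loglik))
    dgk <- ifelse(rej, 2 * matrix(rep(repB, each = G), G, K), 2)
    d <- sum(dgk)
    tests <- S4Vectors::DataFrame(
      gene = rep(rownames(X), times = K), cluster = rep(seq_len(K), each = G),
      statistic = as.vector(stat), df = as.vector(df),
      pvalue = as.vector(pv), rejected = as.vector(rej))
    tests <- tests[as.vector(testable), ]
  }
  methods::new("CDIScore", name = labelSet@name, K = K, loglik = ll, df = d,
               nCells = as.integer(N), AIC = -2 * ll + 2 * d,
               BIC = -2 * ll + log(N) * d, batchTests = tests,
               geneHash = geneListHash(rownames(X)))
}

#' Score and rank candidate label sets
#'
#' Computes \code{computeCDI} for every candidate and returns a report sorted
#' by CDI-BIC, flagging the CDI-AIC and CDI-BIC optima. The candidate with the
#' lowest score is optimal; BIC (heavier penalty) targets main-type
#' resolution, AIC subtype resolution.
#'
#' @param counts feature-gene \linkS4class{CountData}.
#' @param candidates list of \linkS4class{LabelSet} objects.
#' @param sizeFactors per-cell size factors.
#' @param batchAlpha level of the batch-effect LRT (multi-batch data).
#' @return List with \code{report} (data.frame: label_set, K, neg2loglik, df,
#'   CDI_AIC, CDI_BIC, AIC_optimal, BIC_optimal), \code{scores} (the
#'   \linkS4class{CDIScore} objects), and \code{aicOptimum}/\code{bicOptimum}
#'   (names).
#' @export
rankLabelSets <- function(counts, candidates,
                          sizeFactors = computeSizeFactors(counts),
                          batchAlpha = 0.05) {
  if (length(candidates) < 1L) stop("need at least one candidate label set")
  if (length(candidates) < 10L)
    warning("fewer than 10 candidate label sets; the index is designed to ",
            "compare a pool of at least ten candidates")
  nms <- vapply(candidates, function(l) l@name, "")
  if (anyDuplicated(nms)) {
    warning("duplicate candidate names disambiguated with suffixes")
    nms <- make.unique(nms, sep = "#")
    candidates <- Map(function(l, nm) { l@name <- nm; l }, candidates, nms)
  }
  scores <- lapply(candidates, computeCDI, counts = counts,
                   sizeFactors = sizeFactors, batchAlpha = batchAlpha)
  names(scores) <- nms
  report <- data.frame(
    label_set = nms,
    K = vapply(scores, nClusters, 0L),
    neg2loglik = vapply(scores, function(x) -2 * logLik(x), 0),
    df = vapply(scores, function(x) x@df, 0),
    CDI_AIC = vapply(scores, cdiAIC, 0),
    CDI_BIC = vapply(scores, cdiBIC, 0))
  aicOpt <- nms[which.min(report$CDI_AIC)]
  bicOpt <- nms[which.min(report$CDI_BIC)]
  report$AIC_optimal <- report$label_set == aicOpt
  report$BIC_optimal <- report$label_set == bicOpt
  report <- report[order(report$CDI_BIC), ]
  rownames(report) <- NULL
  list(report = report, scores = scores, aicOptimum = aicOpt,
       bicOptimum = bicOpt)
}
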