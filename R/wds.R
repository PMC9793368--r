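#' Filter genes by zero-count proportion
#'
#' Removes genes whose proportion of zero counts exceeds \code{maxZeroProp}
#' (strictly more than; the default drops genes with more than 95\% zeros).
#' The cell set and the order of surviving genes are unchanged.
#'
#' @param counts a \linkS4class{CountData}.
#' @param maxZeroProp maximum tolerated zero proportion, in (0, 1].
#' @return The filtered \linkS4class{CountData}.
#' @export
filterGenesByZeroProp <- function(counts, maxZeroProp = 0.95) {
  stopifnot(maxZeroProp > 0, maxZeroProp <= 1)
  m <- umiCounts(counts)
  zp <- Matrix::rowSums(m == 0) / ncol(m)
  keep <- zp <= maxZeroProp
  if (!any(keep)) stop("no genes survive the zero-proportion filter")
  counts[keep, ]
}

#' Working dispersion score (WDS)
#'
#' The moment-based dispersion of each gene as if all cells shared one NB
#' distribution: xi_g = (sigma_g^2 - mu_g) / mu_g^2, with the sample mean and
#' the unbiased (n - 1) sample variance pooled over all cells. Under
#' NB(mu, phi) with Var = mu + phi mu^2 this estimates phi; for Poisson data
#' it is near 0; genes whose mean differs across cell types have inflated
#' pooled variance and hence a high score.
#'
#' @param counts a \linkS4class{CountData}; every gene must have positive mean
#'   (run \code{filterGenesByZeroProp} first).
#' @param cells optional cell index subset (used for per-batch scoring).
#' @return Named numeric vector of per-gene scores.
#' @export
computeWDS <- function(counts, cells = NULL) {
  m <- umiCounts(counts)
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  n <- ncol(m)
  if (n < 2L) stop("need at least two cells to compute a sample variance")
  mu <- Matrix::rowMeans(m)
  if (any(mu == 0)) {
    bad <- rownames(m)[which(mu == 0)[1]]
    stop(sprintf("WDS undefined for gene '%s' (all counts zero); filter first",
                 bad))
  }
  v <- (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
  xi <- (v - mu) / mu^2
  names(xi) <- rownames(m)
  xi
}

#' Select feature genes by WDS
#'
#' Single-batch data: the \code{nFeatures} genes with the highest WDS.
#' Multi-batch data: genes are ranked by WDS within each batch (rank 1 =
#' highest); each gene's overall rank is its minimum rank across batches, and
#' the genes with the smallest overall rank are selected. Ties are broken by
#' input gene order.
#'
#' @param counts a filtered \linkS4class{CountData}; its \code{batch} column
#'   (if any) drives the multi-batch ranking.
#' @param nFeatures number of feature genes (default 500).
#' @param manual optional character vector of gene ids that bypasses WDS
#'   entirely.
#' @return Character vector of selected gene ids in rank order.
#' @export
selectFeatureGenes <- function(counts, nFeatures = 500, manual = NULL) {
  if (!is.null(manual)) {
    missing <- setdiff(manual, rownames(counts))
    if (length(missing))
      stop("manual feature genes absent from the matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    return(manual)
  }
  stopifnot(nFeatures >= 1)
  G <- nrow(counts)
  if (nFeatures > G) {
    warning(sprintf("requested %d features but only %d genes; returning all",
                    nFeatures, G))
    nFeatures <- G
  }
  batch <- batchOf(counts)
  if (is.null(batch) || nlevels(batch) < 2L) {
    xi <- computeWDS(counts)
    ord <- order(-xi, seq_along(xi))          # ties: input order
    return(names(xi)[ord][seq_len(nFeatures)])
  }
  ranks <- vapply(levels(batch), function(b) {
    xi <- computeWDS(counts, cells = which(batch == b))
    r <- integer(length(xi))
    r[order(-xi, seq_along(xi))] <- seq_along(xi)
    r
  }, integer(G))
  overall <- apply(ranks, 1, min)
  ord <- order(overall, seq_len(G))
  rownames(counts)[ord][seq_len(nFeatures)]
}
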