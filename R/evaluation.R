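#' External partition-agreement indices
#'
#' Adjusted Rand Index, Fowlkes-Mallows index, and normalized mutual
#' information (arithmetic-mean normalization) between two label sets, from
#' their contingency table. All three equal 1 for identical partitions up to
#' relabeling; ARI is 0 in expectation under chance.
#'
#' @param a,b \linkS4class{LabelSet} objects (or plain label vectors) of equal
#'   length.
#' @return Named numeric vector c(ARI, FM, NMI).
#' @export
externalIndices <- function(a, b) {
  la <- if (methods::is(a, "LabelSet")) labels(a) else LabelSet(a)@labels
  lb <- if (methods::is(b, "LabelSet")) labels(b) else LabelSet(b)@labels
  if (length(la) != length(lb)) stop("label sets have different lengths")
  n <- length(la)
  tab <- table(la, lb)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- ai * bj / tot
  denom <- (ai + bj) / 2 - expected
  ari <- if (denom == 0) {
    if (nij == expected) 1 else 0          # both partitions trivial
  } else (nij - expected) / denom
  fm <- if (ai == 0 || bj == 0) {
    if (identical(unname(ai), unname(bj))) 1 else 0  # K = n degenerate case
  } else nij / sqrt(ai * bj)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  mi <- sum(pij[pij > 0] * log(pij[pij > 0] /
                                 outer(pa, pb)[as.matrix(pij) > 0]))
  nmi <- if (ha + hb == 0) 1 else 2 * mi / (ha + hb)
  c(ARI = ari, FM = fm, NMI = nmi)
}

#' Spearman rank agreement between internal and external index scores
#'
#' The protocol for judging an internal clustering index against an external
#' one over a pool of L candidate label sets: internal scores are negated when
#' smaller means better (so both vectors point the same way), both vectors are
#' ranked with average ties, and the Pearson correlation of the rank vectors
#' is returned.
#'
#' @param internal internal index scores, one per candidate.
#' @param external external index scores, same length.
#' @param lowerIsBetter negate the internal scores first (TRUE for CDI-like
#'   indices).
#' @return Spearman correlation in [-1, 1].
#' @export
spearmanAgreement <- function(internal, external, lowerIsBetter = TRUE) {
  if (length(internal) != length(external) || length(internal) < 2L)
    stop("score vectors must have equal length >= 2")
  if (anyNA(internal) || anyNA(external)) stop("missing scores")
  if (lowerIsBetter) internal <- -internal
  if (stats::sd(internal) == 0 || stats::sd(external) == 0)
    stop("constant score vector: rank correlation undefined")
  stats::cor(rank(internal), rank(external), method = "pearson")
}
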