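#' Negative binomial log pmf (mean/dispersion parametrization)
#'
#' Log probability mass of NB with mean \code{m} and dispersion \code{phi}
#' under the parametrization Var = m + phi m^2:
#' \deqn{\log f(x) = \ln\Gamma(x + 1/\phi) - \ln\Gamma(1/\phi) - \ln\Gamma(x+1)
#'   + (1/\phi)\ln\frac{1}{1+\phi m} + x \ln\frac{\phi m}{1 + \phi m}.}
#' \code{phi = 0} returns the Poisson log pmf (continuous limit); \code{m = 0}
#' returns 0 at x = 0 and -Inf otherwise. Arguments recycle.
#'
#' @param x non-negative integer counts.
#' @param m mean, >= 0.
#' @param phi dispersion, >= 0.
#' @return Numeric vector of log probabilities.
#' @examples
#' nbLogPmf(0, 2, 0.5)            # -(1/0.5) * log(1 + 0.5*2)
#' nbLogPmf(3, 2, 1e-10)          # ~ dpois(3, 2, log = TRUE)
#' @export
nbLogPmf <- function(x, m, phi) {
  if (any(x < 0) || any(x != floor(x))) stop("x must be non-negative integers")
  if (any(m < 0)) stop("mean must be >= 0")
  if (any(phi < 0)) stop("dispersion must be >= 0")
  n <- max(length(x), length(m), length(phi))
  cpp_nb_lpmf(rep_len(as.numeric(x), n), rep_len(as.numeric(m), n),
              rep_len(as.numeric(phi), n))
}

#' Zero-inflated negative binomial log pmf
#'
#' Log pmf of the mixture pi0 * I(x = 0) + (1 - pi0) * NB(m, phi), computed in
#' log space.
#'
#' @inheritParams nbLogPmf
#' @param pi0 zero-inflation probability in [0, 1).
#' @return Numeric vector of log probabilities.
#' @export
zinbLogPmf <- function(x, m, phi, pi0) {
  if (any(pi0 < 0) || any(pi0 >= 1)) stop("pi0 must lie in [0, 1)")
  n <- max(length(x), length(m), length(phi), length(pi0))
  x <- rep_len(as.numeric(x), n); pi0 <- rep_len(pi0, n)
  nb <- nbLogPmf(x, rep_len(m, n), rep_len(phi, n))
  out <- log1p(-pi0) + nb
  z <- which(x == 0 & pi0 > 0)
  if (length(z)) {
    # log(pi0 + (1-pi0) exp(nb0)) stably via log-sum-exp
    a <- log(pi0[z]); b <- log1p(-pi0[z]) + nb[z]
    mx <- pmax(a, b)
    out[z] <- mx + log(exp(a - mx) + exp(b - mx))
  }
  out
}

#' Per-cell size factors
#'
#' Default definition: s_c = (library size of cell c) / (median library size),
#' over the genes present in the supplied matrix, so the median size factor is
#' 1. \code{center = "mean"} divides by the mean library size instead.
#'
#' @param counts a \linkS4class{CountData}.
#' @param center \code{"median"} (default) or \code{"mean"}.
#' @return Named numeric vector of positive per-cell size factors.
#' @export
computeSizeFactors <- function(counts, center = c("median", "mean")) {
  center <- match.arg(center)
  lib <- Matrix::colSums(umiCounts(counts))
  if (any(lib == 0))
    stop(sprintf("cell '%s' has zero total count",
                 colnames(counts)[which(lib == 0)[1]]))
  s <- lib / if (center == "median") stats::median(lib) else mean(lib)
  names(s) <- colnames(counts)
  s
}
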