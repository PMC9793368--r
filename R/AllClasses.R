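#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom Rcpp sourceCpp
#' @useDynLib CDIndex, .registration = TRUE
NULL

#' CountData: a genes-by-cells UMI count matrix
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding one assay
#' named \code{"counts"} with non-negative integer UMI counts, unique gene and
#' cell identifiers as dimnames, and an optional per-cell batch factor in
#' \code{colData(x)$batch}.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @export
setClass("CountData", contains = "SummarizedExperiment")

.validCountData <- function(object) {
  msg <- character()
  if (!("counts" %in% names(SummarizedExperiment::assays(object))))
    return("assay 'counts' is missing")
  x <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene and cell identifiers (dimnames) are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated gene identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated cell identifiers")
  v <- if (methods::is(x, "Matrix")) x@x else x
  if (length(v) && (anyNA(v) || any(v < 0)))
    msg <- c(msg, "counts must be non-negative")
  if (length(v) && any(v != floor(v)))
    msg <- c(msg, "counts must be integers (UMI counts)")
  b <- SummarizedExperiment::colData(object)$batch
  if (!is.null(b)) {
    if (length(b) != ncol(object))
      msg <- c(msg, "batch length must equal the cell count")
    if (is.factor(b) && any(tabulate(b, nbins = nlevels(b)) == 0L))
      msg <- c(msg, "every batch level must contain at least one cell")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CountData", .validCountData)

#' Construct a CountData object
#'
#' @param counts genes x cells matrix (base or \pkg{Matrix} sparse) of
#'   non-negative integer UMI counts.
#' @param geneIds,cellIds character vectors of unique identifiers; defaults are
#'   taken from \code{dimnames(counts)} or generated.
#' @param batch optional per-cell batch assignment (coerced to factor).
#' @return A \linkS4class{CountData} object.
#' @examples
#' cd <- CountData(matrix(rpois(20, 2), 4, 5))
#' dim(cd)
#' @export
CountData <- function(counts, geneIds = NULL, cellIds = NULL, batch = NULL) {
  if (is.null(geneIds))
    geneIds <- if (!is.null(rownames(counts))) rownames(counts) else
      sprintf("gene%d", seq_len(nrow(counts)))
  if (is.null(cellIds))
    cellIds <- if (!is.null(colnames(counts))) colnames(counts) else
      sprintf("cell%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(geneIds, cellIds)
  cdat <- S4Vectors::DataFrame(row.names = cellIds)
  if (!is.null(batch)) cdat$batch <- factor(batch)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cdat)
  methods::new("CountData", se)
}

#' LabelSet: one cluster id per cell
#'
#' Cluster assignments are stored re-coded to contiguous integers 1..K in
#' first-occurrence order, so downstream code may assume \code{1:K}.
#'
#' @slot labels integer vector, one entry per cell, values in 1..K.
#' @slot name character scalar identifying the candidate (method + parameters).
#' @slot K number of distinct clusters.
#' @export
setClass("LabelSet", representation(labels = "integer", name = "character",
                                    K = "integer"))

setValidity("LabelSet", function(object) {
  msg <- character()
  K <- object@K
  if (length(K) != 1L || is.na(K) || K < 1L) msg <- c(msg, "K must be >= 1")
  l <- object@labels
  if (anyNA(l)) msg <- c(msg, "labels contain NA")
  else {
    if (length(l) && (min(l) < 1L || max(l) > K))
      msg <- c(msg, "labels must lie in 1..K")
    if (length(l) && !all(seq_len(K) %in% l))
      msg <- c(msg, "every cluster id in 1..K must occur at least once")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabelSet, re-coding arbitrary cluster names to 1..K
#'
#' @param labels vector of per-cell cluster assignments (any atomic type).
#' @param name identifier for the candidate label set.
#' @return A \linkS4class{LabelSet}.
#' @examples
#' ls1 <- LabelSet(c("a", "a", "b", "b"))
#' labels(ls1)   # 1 1 2 2
#' @export
LabelSet <- function(labels, name = "labels") {
  if (length(labels) == 0L) stop("empty label vector")
  if (anyNA(labels)) stop("labels contain missing values")
  lev <- unique(as.character(labels))        # first-occurrence order
  code <- match(as.character(labels), lev)
  methods::new("LabelSet", labels = as.integer(code), name = as.character(name),
               K = length(lev))
}

#' NBFit: fitted negative binomial family
#'
#' @slot family one of the six supported distribution families.
#' @slot params \code{DataFrame} with one row per fitted (gene, cluster
#'   [, batch]) cell: mean \code{mu}, dispersion \code{phi}, optional
#'   zero-inflation \code{pi0}, maximized \code{loglik} and a convergence flag.
#' @slot loglik total maximized log-likelihood.
#' @export
setClass("NBFit", representation(family = "character", params = "DataFrame",
                                 loglik = "numeric"))

setValidity("NBFit", function(object) {
  p <- object@params
  msg <- character()
  if (nrow(p)) {
    if (any(p$mu < 0) || any(p$phi < 0)) msg <- c(msg, "mu and phi must be >= 0")
    if (!is.null(p$pi0) && (any(p$pi0 < 0) || any(p$pi0 >= 1)))
      msg <- c(msg, "pi0 must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' CDIScore: penalized-likelihood score of one label set
#'
#' @slot name candidate label set name.
#' @slot K number of clusters.
#' @slot loglik maximized log-likelihood.
#' @slot df total degrees of freedom d = sum over (g, k) of d_gk.
#' @slot nCells number of cells N (penalty scale for BIC is log N).
#' @slot AIC,BIC the two CDI flavours: -2 loglik + c_pen * df with c_pen = 2
#'   and log(N).
#' @slot batchTests per-(gene, cluster) batch-effect LRT decisions
#'   (\code{DataFrame}; zero rows for single-batch data).
#' @slot geneHash hash of the feature-gene list; scores are comparable only
#'   within a gene set.
#' @export
setClass("CDIScore", representation(name = "character", K = "integer",
  loglik = "numeric", df = "numeric", nCells = "integer", AIC = "numeric",
  BIC = "numeric", batchTests = "DataFrame", geneHash = "character"))

setValidity("CDIScore", function(object) {
  d <- object@BIC - object@AIC
  want <- (log(object@nCells) - 2) * object@df
  if (abs(d - want) > 1e-6 * max(1, abs(want)))
    "BIC - AIC must equal (log N - 2) * df" else TRUE
})

#' SimSpec: parameterization of an NB population simulation
#'
#' Describes a multi-group negative binomial cell population: group sizes,
#' truncated-normal baseline mean/dispersion distributions, and per-group
#' feature-gene blocks carrying log2 fold changes on the mean and Gaussian
#' shifts on the dispersion.
#'
#' @slot nGenes number of genes.
#' @slot groupNames,groupSizes group labels and cell counts.
#' @slot mainType optional parent main-type label per group (hierarchical
#'   designs); empty when flat.
#' @slot muMean,muSd,phiMean,phiSd baseline truncated-normal parameters
#'   (truncated below at 0).
#' @slot features data.frame(gene, group, log2fc, dispSd): feature-gene blocks.
#' @slot batches optional number of batches to split cells into (no
#'   batch-specific biology; used for multi-batch plumbing tests).
#' @slot librarySizeSd sdlog of optional lognormal library-size variation
#'   (0 = all size factors 1, the default design).
#' @slot outlierFrac fraction of cells replaced by mean-inflated outliers
#'   (robustness option; 0 by default).
#' @slot seed RNG seed; simulation is bit-reproducible given the spec.
#' @export
setClass("SimSpec", representation(nGenes = "integer", groupNames = "character",
  groupSizes = "integer", mainType = "character", muMean = "numeric",
  muSd = "numeric", phiMean = "numeric", phiSd = "numeric",
  features = "data.frame", batches = "integer", librarySizeSd = "numeric",
  outlierFrac = "numeric", seed = "integer"))

setValidity("SimSpec", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (length(object@groupSizes) != length(object@groupNames))
    msg <- c(msg, "groupSizes and groupNames lengths differ")
  if (any(object@groupSizes < 1L)) msg <- c(msg, "group sizes must be >= 1")
  f <- object@features
  if (nrow(f)) {
    if (any(f$gene < 1L | f$gene > object@nGenes))
      msg <- c(msg, "feature gene indices out of range")
    if (!all(f$group %in% object@groupNames))
      msg <- c(msg, "feature group not among groupNames")
  }
  if (object@outlierFrac < 0 || object@outlierFrac >= 1)
    msg <- c(msg, "outlierFrac must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a SimSpec
#'
#' @param nGenes,groupNames,groupSizes,features,seed see \linkS4class{SimSpec}.
#' @param mainType optional parent main-type per group.
#' @param muMean,muSd baseline mean distribution: normal truncated below at 0.
#' @param phiMean,phiSd baseline dispersion distribution, same truncation.
#' @param batches,librarySizeSd,outlierFrac optional structure; see class doc.
#' @return A validated \linkS4class{SimSpec}.
#' @export
SimSpec <- function(nGenes, groupNames, groupSizes, muMean = 0.2, muSd = 0.1,
                    phiMean = 0.5, phiSd = 0.1,
                    features = data.frame(gene = integer(), group = character(),
                                          log2fc = numeric(), dispSd = numeric()),
                    mainType = character(), batches = 1L, librarySizeSd = 0,
                    outlierFrac = 0, seed = 1L) {
  methods::new("SimSpec", nGenes = as.integer(nGenes),
    groupNames = as.character(groupNames), groupSizes = as.integer(groupSizes),
    mainType = as.character(mainType), muMean = muMean, muSd = muSd,
    phiMean = phiMean, phiSd = phiSd, features = features,
    batches = as.integer(batches), librarySizeSd = librarySizeSd,
    outlierFrac = outlierFrac, seed = as.integer(seed))
}
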