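#' @importFrom stats logLik
NULL

#' Accessors for CDIndex classes
#'
#' \code{umiCounts} returns the counts assay; \code{batchOf} the per-cell batch
#' factor (or NULL); \code{labels} the integer 1..K assignment of a
#' \linkS4class{LabelSet}; \code{nClusters} its K; \code{cdiAIC}/\code{cdiBIC}
#' the two penalized scores of a \linkS4class{CDIScore}; \code{fitParams} the
#' per-(gene, cluster) parameter table of an \linkS4class{NBFit}.
#'
#' @param x,object an object of the documented class.
#' @param ... ignored.
#' @return See the individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("umiCounts", function(x) standardGeneric("umiCounts"))
#' @rdname accessors
#' @export
setMethod("umiCounts", "CountData", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("batchOf", function(x) standardGeneric("batchOf"))
#' @rdname accessors
#' @export
setMethod("batchOf", "CountData", function(x)
  SummarizedExperiment::colData(x)$batch)

#' @rdname accessors
#' @export
setMethod("labels", "LabelSet", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setMethod("nClusters", "LabelSet", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("nClusters", "CDIScore", function(x) x@K)

#' @rdname accessors
#' @export
setGeneric("cdiAIC", function(x) standardGeneric("cdiAIC"))
#' @rdname accessors
#' @export
setMethod("cdiAIC", "CDIScore", function(x) x@AIC)

#' @rdname accessors
#' @export
setGeneric("cdiBIC", function(x) standardGeneric("cdiBIC"))
#' @rdname accessors
#' @export
setMethod("cdiBIC", "CDIScore", function(x) x@BIC)

#' @rdname accessors
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setMethod("fitParams", "NBFit", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("logLik", "NBFit", function(object, ...) object@loglik)
#' @rdname accessors
#' @export
setMethod("logLik", "CDIScore", function(object, ...) object@loglik)

setMethod("show", "CountData", function(object) {
  cat(sprintf("CountData: %d genes x %d cells\n", nrow(object), ncol(object)))
  b <- batchOf(object)
  if (!is.null(b))
    cat(sprintf("  batches: %s\n", paste(levels(b), collapse = ", ")))
  methods::callNextMethod()
})

setMethod("show", "LabelSet", function(object) {
  cat(sprintf("LabelSet '%s': %d cells, K = %d\n", object@name,
              length(object@labels), object@K))
  tab <- tabulate(object@labels, object@K)
  cat("  cluster sizes:", paste(tab, collapse = " "), "\n")
})

setMethod("show", "NBFit", function(object) {
  cat(sprintf("NBFit (%s): %d fitted parameter cells, loglik = %.4f\n",
              object@family, nrow(object@params), object@loglik))
})

setMethod("show", "CDIScore", function(object) {
  cat(sprintf("CDIScore '%s' (K = %d, N = %d)\n", object@name, object@K,
              object@nCells))
  cat(sprintf("  loglik = %.4f, df = %g\n", object@loglik, object@df))
  cat(sprintf("  CDI-AIC = %.4f, CDI-BIC = %.4f\n", object@AIC, object@BIC))
  if (nrow(object@batchTests))
    cat(sprintf("  batch-effect LRTs: %d of %d (g,k) cells rejected\n",
                sum(object@batchTests$rejected), nrow(object@batchTests)))
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf("SimSpec: %d genes, %d groups (%s cells), seed %d\n",
              object@nGenes, length(object@groupSizes),
              sum(object@groupSizes), object@seed))
  cat(sprintf("  baseline mu ~ TN(%g, %g), phi ~ TN(%g, %g); %d feature-gene rows\n",
              object@muMean, object@muSd, object@phiMean, object@phiSd,
              nrow(object@features)))
})
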