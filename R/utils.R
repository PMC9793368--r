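# Internal helpers shared across modules.

# Normal draws truncated below at 0 by inverse-cdf sampling (exact, no
# rejection loop so the RNG stream length is deterministic).
rtruncnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + (1 - lo) * stats::runif(n), mean, sd)
}

# Polynomial rolling hash (mod 2^31 - 1, double arithmetic stays exact) over
# the concatenated gene ids; provenance stamp so CDI values are only compared
# within one feature-gene set.
geneListHash <- function(ids) {
  h <- 0
  for (b in utf8ToInt(paste(ids, collapse = "\n")))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Ensure a genes x cells object is a dense base matrix for the C++ fitters.
denseCounts <- function(x) {
  m <- umiCounts(x)
  if (methods::is(m, "Matrix")) m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}

checkLabelsMatch <- function(counts, labelSet) {
  if (length(labels(labelSet)) != ncol(counts))
    stop(sprintf("label set '%s' has %d entries but the matrix has %d cells",
                 labelSet@name, length(labels(labelSet)), ncol(counts)))
  invisible(TRUE)
}
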