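# Shared fixture builders: small NB cell populations with known parameters.

# genes x cells matrix with per-cluster NB parameters.
# mu, phi: G x K matrices (or vectors recycled per cluster).
nbClusterMatrix <- function(G, clusterSizes, mu, phi, seed = 1) {
  set.seed(seed)
  K <- length(clusterSizes)
  mu <- matrix(mu, G, K)
  phi <- matrix(phi, G, K)
  N <- sum(clusterSizes)
  lab <- rep(seq_len(K), clusterSizes)
  X <- matrix(0, G, N)
  for (k in seq_len(K)) {
    cells <- which(lab == k)
    X[, cells] <- stats::rnbinom(G * length(cells),
                                 size = 1 / pmax(phi[, k], 1e-12),
                                 mu = rep(mu[, k], length(cells)))
  }
  list(counts = CountData(X), labels = LabelSet(lab, name = "truth"),
       mu = mu, phi = phi)
}

# SD1-baseline-style parameter draws (means ~ TN(0.2, 0.1), phi ~ TN(0.5, 0.1))
sd1BaselineParams <- function(G, K, seed = 1) {
  set.seed(seed)
  list(mu = matrix(CDIndex:::rtruncnorm0(G * K, 0.2, 0.1), G, K),
       phi = matrix(CDIndex:::rtruncnorm0(G * K, 0.5, 0.1), G, K))
}

# Independent contingency-table oracle for the external indices (kept separate
# from the package implementation on purpose).
oracleIndices <- function(a, b) {
  tab <- table(a, b); n <- length(a)
  nij <- sum(choose(tab, 2)); ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2)); tot <- choose(n, 2)
  exp <- ai * bj / tot
  c(ARI = (nij - exp) / ((ai + bj) / 2 - exp), FM = nij / sqrt(ai * bj))
}
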