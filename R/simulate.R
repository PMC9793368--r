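#' Simulate an NB cell population from a SimSpec
#'
#' Counts for gene g in group k are drawn from NB(mu_gk, phi_gk). Baseline
#' means and dispersions are drawn per gene from normals truncated below at 0;
#' each group's feature genes get their mean multiplied by 2^log2fc and their
#' dispersion shifted by a Gaussian factor (sd \code{dispSd}, clamped at
#' 1e-6). Optional lognormal library-size variation multiplies per-cell means;
#' optional outlier cells have all means inflated fivefold. Bit-reproducible
#' given the spec (including its seed).
#'
#' @param spec a \linkS4class{SimSpec}.
#' @return List: \code{counts} (\linkS4class{CountData}; batch attached when
#'   \code{spec@batches > 1}), \code{labels} (true group \linkS4class{LabelSet}),
#'   \code{mainLabels} (main-type \linkS4class{LabelSet} or NULL),
#'   \code{features} (truth table: gene, group, log2fc), \code{mu}, \code{phi}
#'   (genes x groups true parameter matrices), \code{sizeFactors} (true
#'   per-cell scale, all 1 unless \code{librarySizeSd > 0}).
#' @export
simulatePopulation <- function(spec) {
  methods::validObject(spec)
  set.seed(spec@seed)
  G <- spec@nGenes
  K <- length(spec@groupNames)
  muBase <- rtruncnorm0(G, spec@muMean, spec@muSd)
  phiBase <- rtruncnorm0(G, spec@phiMean, spec@phiSd)
  mu <- matrix(muBase, G, K, dimnames = list(NULL, spec@groupNames))
  phi <- matrix(phiBase, G, K, dimnames = list(NULL, spec@groupNames))
  f <- spec@features
  if (nrow(f)) {
    kIdx <- match(f$group, spec@groupNames)
    mu[cbind(f$gene, kIdx)] <- mu[cbind(f$gene, kIdx)] * 2^f$log2fc
    shift <- stats::rnorm(nrow(f), 0, f$dispSd)
    phi[cbind(f$gene, kIdx)] <- pmax(phi[cbind(f$gene, kIdx)] + shift, 1e-6)
  }
  N <- sum(spec@groupSizes)
  sc <- if (spec@librarySizeSd > 0)
    stats::rlnorm(N, 0, spec@librarySizeSd) else rep(1, N)
  lab <- rep(seq_len(K), spec@groupSizes)
  X <- matrix(0, G, N)
  cell0 <- 0L
  for (k in seq_len(K)) {
    nk <- spec@groupSizes[k]
    cells <- cell0 + seq_len(nk)
    m <- outer(mu[, k], sc[cells])        # G x nk per-cell means
    size <- 1 / pmax(phi[, k], 1e-12)
    X[, cells] <- stats::rnbinom(G * nk, size = rep(size, nk), mu = as.vector(m))
    cell0 <- cell0 + nk
  }
  if (spec@outlierFrac > 0) {
    nOut <- floor(spec@outlierFrac * N)
    if (nOut > 0) {
      out <- sample.int(N, nOut)
      for (c in out) {
        k <- lab[c]
        size <- 1 / pmax(phi[, k], 1e-12)
        X[, c] <- stats::rnbinom(G, size = size, mu = 5 * mu[, k] * sc[c])
      }
    }
  }
  batch <- if (spec@batches > 1L)
    sprintf("batch%d", ((seq_len(N) - 1L) %% spec@batches) + 1L) else NULL
  cd <- CountData(X, geneIds = sprintf("gene%d", seq_len(G)),
                  cellIds = sprintf("cell%d", seq_len(N)), batch = batch)
  groupLabels <- LabelSet(spec@groupNames[lab], name = "truth")
  mainLabels <- NULL
  if (length(spec@mainType))
    mainLabels <- LabelSet(spec@mainType[lab], name = "truth-main")
  feat <- spec@features
  if (nrow(feat)) feat$gene_id <- sprintf("gene%d", feat$gene)
  list(counts = cd, labels = groupLabels, mainLabels = mainLabels,
       features = feat, mu = mu, phi = phi, sizeFactors = sc)
}

# Pick disjoint feature-gene blocks uniformly at random from the gene pool.
.featureBlocks <- function(nGenes, sizes, groups, fcs, dispSd = 0.05) {
  idx <- sample.int(nGenes, sum(sizes))
  split <- rep(seq_along(sizes), sizes)
  do.call(rbind, lapply(seq_along(sizes), function(i)
    data.frame(gene = idx[split == i], group = groups[i], log2fc = fcs[i],
               dispSd = dispSd)))
}

#' SD1: ten equal, well-separated cell groups
#'
#' 10,000 genes, ten groups of 400 cells (4,000 cells). Baseline means ~
#' TN(0.2, 0.1), dispersions ~ TN(0.5, 0.1); each of the nine non-baseline
#' groups carries 25 disjoint feature genes with log2 mean fold change 2.4 and
#' dispersion shifts ~ N(0, 0.05).
#'
#' @param seed RNG seed (drives both the feature-gene draw and the counts).
#' @param nGenes,cellsPerGroup scale-down knobs for quick tests; defaults are
#'   the stated design.
#' @return A \linkS4class{SimSpec}.
#' @export
makeSD1Spec <- function(seed = 1L, nGenes = 10000L, cellsPerGroup = 400L) {
  set.seed(seed)
  groups <- sprintf("G%d", 1:10)
  features <- .featureBlocks(nGenes, rep(25L, 9), groups[2:10], rep(2.4, 9))
  SimSpec(nGenes = nGenes, groupNames = groups,
          groupSizes = rep(cellsPerGroup, 10), muMean = 0.2, muSd = 0.1,
          phiMean = 0.5, phiSd = 0.1, features = features, seed = seed)
}

#' SD2: two abundant and two rare cell types
#'
#' Two abundant types of 2,000 cells each and two rare types; the baseline
#' abundant type has no feature genes, the other abundant type 40 feature
#' genes at log2 fold change 1.5, rare type RC1 50 at 2.8, rare type RC2 50 at
#' 3.2. \code{rc1Cells} reproduces the rare-type reduction experiments
#' (100 -> 85 -> 20 cells).
#'
#' @param rc1Cells number of RC1 cells (default 100).
#' @param seed RNG seed.
#' @param nGenes number of genes (default 10,000).
#' @return A \linkS4class{SimSpec}.
#' @export
makeSD2Spec <- function(rc1Cells = 100L, seed = 1L, nGenes = 10000L) {
  set.seed(seed)
  features <- .featureBlocks(nGenes, c(40L, 50L, 50L), c("A2", "RC1", "RC2"),
                             c(1.5, 2.8, 3.2))
  SimSpec(nGenes = nGenes, groupNames = c("A1", "A2", "RC1", "RC2"),
          groupSizes = c(2000L, 2000L, as.integer(rc1Cells), 100L),
          muMean = 0.2, muSd = 0.1, phiMean = 0.5, phiSd = 0.1,
          features = features, seed = seed)
}

#' SD3: hierarchical main types and subtypes
#'
#' Main type C1: 1,000 homogeneous cells (baseline mu ~ TN(0.4, 0.1), phi ~
#' TN(1, 0.1)). Main type C2: three subtypes of 600 cells each, each with 40
#' feature genes — 30 shared by all subtypes at log2 fold change 4 (the
#' main-type signal) and 10 exclusive per subtype at 1.8 (the subtype signal).
#' Both the 4-level subtype truth and the 2-level main-type truth are emitted
#' by \code{simulatePopulation}.
#'
#' @param seed RNG seed.
#' @param nGenes number of genes (default 10,000).
#' @return A \linkS4class{SimSpec}.
#' @export
makeSD3Spec <- function(seed = 1L, nGenes = 10000L) {
  set.seed(seed)
  subs <- c("S1", "S2", "S3")
  idx <- sample.int(nGenes, 30 + 3 * 10)
  shared <- idx[1:30]
  excl <- split(idx[31:60], rep(subs, each = 10))
  features <- rbind(
    do.call(rbind, lapply(subs, function(s)
      data.frame(gene = shared, group = s, log2fc = 4, dispSd = 0.05))),
    do.call(rbind, lapply(subs, function(s)
      data.frame(gene = excl[[s]], group = s, log2fc = 1.8, dispSd = 0.05))))
  SimSpec(nGenes = nGenes, groupNames = c("C1", subs),
          groupSizes = c(1000L, 600L, 600L, 600L), muMean = 0.4, muSd = 0.1,
          phiMean = 1, phiSd = 0.1, features = features,
          mainType = c("C1", "C2", "C2", "C2"), seed = seed)
}

#' Serialize / load a SimSpec as JSON
#'
#' Round-trips every slot, so simulation inputs can be version-controlled and
#' passed to the command-line tool. Requires \pkg{jsonlite}.
#'
#' @param spec a \linkS4class{SimSpec}.
#' @param path JSON file path.
#' @return \code{writeSimSpec} invisibly returns \code{path};
#'   \code{readSimSpec} returns the reconstructed \linkS4class{SimSpec}.
#' @export
writeSimSpec <- function(spec, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for SimSpec JSON I/O")
  sl <- lapply(methods::slotNames("SimSpec"), methods::slot, object = spec)
  names(sl) <- methods::slotNames("SimSpec")
  jsonlite::write_json(sl, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname writeSimSpec
#' @export
readSimSpec <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for SimSpec JSON I/O")
  sl <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- as.data.frame(sl$features)
  if (nrow(feats) == 0L)
    feats <- data.frame(gene = integer(), group = character(),
                        log2fc = numeric(), dispSd = numeric())
  SimSpec(nGenes = sl$nGenes, groupNames = sl$groupNames,
          groupSizes = sl$groupSizes, muMean = sl$muMean, muSd = sl$muSd,
          phiMean = sl$phiMean, phiSd = sl$phiSd, features = feats,
          mainType = unlist(sl$mainType) %||% character(),
          batches = sl$batches, librarySizeSd = sl$librarySizeSd,
          outlierFrac = sl$outlierFrac, seed = sl$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
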