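---
title: "Scoring scRNA-seq clusterings with a penalized NB likelihood"
author: "CDIndex maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring scRNA-seq clusterings with a penalized NB likelihood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CDIndex)
```

## The problem

Single-cell RNA-seq analyses routinely produce many candidate clusterings of
the same cells — different methods, resolutions, and numbers of clusters K —
and the analyst must pick one without access to ground truth. External indices
(ARI, Fowlkes–Mallows, NMI) need a benchmark label set, which real data rarely
has. CDIndex implements an *internal* index for UMI count matrices: the
clustering deviation index (CDI), the penalized negative maximized
log-likelihood of the counts under a negative binomial model in which every
(gene, cluster) pair has its own mean and dispersion. Lower is better; the
candidate with the lowest score over a pool of at least ten candidates is the
recommended choice.

## The model

UMI counts (not read counts — PCR duplicates are collapsed, so counts reflect
molecules) for gene $g$ in cell $c$ assigned to cluster $k$ are modeled as

$$X_{gc} \sim \mathrm{NB}(s_c\,\mu_{gk},\ \phi_{gk}), \qquad
\mathrm{Var} = m + \phi m^2,$$

where $s_c$ is a per-cell size factor absorbing library-size differences.
$\phi = 0$ is the Poisson boundary and is always considered by the fitter.
This parametrization is the one under which the working dispersion score
(below) is a moment estimator of $\phi$, which pins down the pmf convention
used throughout.

Given a candidate label set $L$ with $K$ clusters over $N$ cells and $G$
feature genes, the score of $L$ is

$$\tilde\ell = -2\,\hat\ell + c_{\mathrm{pen}}\, d, \qquad
\hat\ell = \max_{\mu,\phi} \sum_{g}\sum_{c}
\log \mathrm{NB}\!\left(X_{gc}\mid s_c\mu_{gL_c}, \phi_{gL_c}\right),$$

with $c_{\mathrm{pen}} = 2$ (CDI-AIC) or $\log N$ (CDI-BIC) and
$d = \sum_{g,k} d_{gk}$ the free-parameter count: $d_{gk} = 2$ for
single-batch data, so $d = 2GK$. BIC penalizes extra clusters harder and is
meant for main-type resolution; AIC for subtype resolution. The identity
$\mathrm{BIC} - \mathrm{AIC} = (\log N - 2)\,d$ holds exactly and is asserted
by the class validity method.

For multi-batch data, each (gene, cluster) is first tested for a batch effect
with a likelihood-ratio test of pooled vs per-batch parameters
(`batchEffectLRT`, $\chi^2$ with $2(B-1)$ df at level 0.05 per pair, no
multiplicity correction — each decision is local model selection, and the
decision is recorded per pair in the score object). A rejected pair keeps
batch-specific parameters and contributes $d_{gk} = 2B$; an accepted pair is
pooled and contributes 2. Clusters absent from some batch are tested over the
represented batches only, and $d_{gk}$ uses the represented count, so $d$
always equals the number of actually-free parameters.

## Feature selection (WDS)

CDI is computed on feature genes. The working dispersion score of gene $g$ is

$$\hat\xi_g = \frac{\hat\sigma_g^2 - \hat\mu_g}{\hat\mu_g^2},$$

the pooled moment estimate of NB dispersion. For a homogeneous gene it
estimates $\phi_g$; a gene whose mean differs across cell types has inflated
pooled variance and a high score, so ranking by $\hat\xi$ surfaces
discriminative genes without needing labels. Genes with more than 95% zeros
are removed first (strictly more than), the sample variance uses the $n-1$
denominator, and ties are broken by input order. The default keeps the top
500 genes. Multi-batch data are ranked within each batch and each gene's
overall rank is its *minimum* rank across batches, which protects genes that
are strongly variable in only some batches. A manual gene list bypasses
scoring entirely.

A caveat inherited from the score's construction: when counts show a strong
mean–dispersion trend (common in bulk data and in Splatter simulations, not
in the UMI datasets this model targets), WDS favours dimly expressed genes
and should not be used; inspect a mean–dispersion plot before trusting it.

## Fitting

Each (gene, cluster) NB maximum-likelihood fit uses profile likelihood: at a
candidate dispersion the mean score equation
$\sum_c x_c/\mu = \sum_c s_c(1+\phi x_c)/(1+\phi s_c \mu)$ is solved exactly
by safeguarded Newton (it has a unique root), and the profile is maximized
over $\log\phi$ by golden section after a coarse grid, with $\phi = 0$
always evaluated and $\phi$ capped at $10^6$. This replaces a generic 2-D
quasi-Newton because the $\phi \to 0$ boundary is common in real fits and the
profile is 1-D and well behaved there; it is also what makes scoring a
10-cluster, 500-gene, 4,000-cell candidate take about a second (the inner
loops are C++). All-zero (gene, cluster) cells return
$(\hat\mu, \hat\phi, \hat\ell) = (0, 0, 0)$ exactly and still count their
$d_{gk}$, avoiding $-\infty$ at the boundary. Non-convergence is flagged,
never silent.

Six distribution families are available through `fitFamily` for model
criticism: gene-specific or gene-common dispersion, NB or zero-inflated NB
(monoclonal families), and cell-type-common vs cell-type-specific NB
(polyclonal). "Gene-common" shares one dispersion across genes via an outer
1-D profile; gene-common ZINB also shares its zero-inflation probability,
while gene-specific ZINB estimates one per gene. ZINB fits start from the NB
solution and keep it as a candidate, so maximized likelihoods respect model
nesting numerically — the property tests assert the full nesting lattice.

Size factors default to (library size) / (median library size) over the
supplied genes; `center = "mean"` is available, and for feature-gene scoring
we recommend computing size factors on the full matrix *before* gene
filtering so that feature-gene fold changes do not leak into the library
size. The reports record the definition used.

## Goodness of fit

`gofTestGene` bins each gene's counts into the categories
$\{0\},\{1\},\{2\},\{3\},[4,\infty)$ crossed with the $K_0$ benchmark
clusters, estimates $(\mu, \phi)$ (per cluster, or shared for the
cell-type-common family) by maximizing the multinomial likelihood of the bin
counts, and compares the Pearson statistic to the 95% quantile of
$\chi^2(5K_0 - p - 1)$ with $p = 2K_0$ (cell-type-specific) or $p = 2$
(cell-type-common). Size factors enter through per-cell bin probabilities
averaged within cluster; passing `sizeFactors = NULL` reproduces the plain
iid reading. Genes with an expected bin count below $10^{-8}N$ are flagged
untestable rather than inflating the statistic, and the rejection *rate*
over testable genes is the family-adequacy summary.

A calibration subtlety, documented rather than hidden: with cluster
proportions plugged in as $N_k/N$, each cluster's five bin counts sum to
$N_k$ exactly, so the statistic is asymptotically $\chi^2(2K_0)$, and the
printed $5K_0 - p - 1$ threshold makes the test conservative (empirically
1.5–2% rejection at nominal 5% for $K_0 = 3$). The printed df is
exact when cells fall into clusters multinomially and the proportions are
known — supply `clusterProbs` for that regime. Either way the test ranks
families correctly: misspecified (pooled-dispersion) families are rejected at
far above the nominal rate while the generating family is not, which is the
comparison the rejection rate is used for.

## Simulators

`makeSD1Spec`, `makeSD2Spec`, `makeSD3Spec` reproduce three stated designs —
ten equal well-separated groups; two abundant plus two rare types (with the
rare-type reduction knob `rc1Cells`); and a hierarchical main-type/subtype
design — and `SimSpec` describes arbitrary NB populations. Baseline means and
dispersions are drawn from normals truncated below at zero (truncation is
one-sided because the stated designs say only "truncated normal"); feature
genes multiply the baseline mean by $2^{\mathrm{log2fc}}$ (a constant fold
change, the plainer reading of "log2 fold change of mean x") and shift the
dispersion by a $N(0, 0.05)$ factor clamped at $10^{-6}$. Feature blocks of
different groups are disjoint and drawn uniformly from the gene pool, except
the hierarchical design's explicit 30-shared/10-exclusive structure: shared
genes carry the main-type fold change (4) in every subtype, exclusive genes
the subtype fold change (1.8) in theirs only. Counts are drawn without
library-size variation (all $s_c = 1$) as stated; `librarySizeSd` adds
lognormal variation for size-factor testing, and `outlierFrac` injects
mean-inflated cells as a robustness stand-in for simulator misspecification.
Everything is bit-reproducible from the spec's seed.

What a green test on these simulations does **not** establish: behaviour
under mean–dispersion trends, ambient RNA, doublets, or batch-specific
biology beyond mean/dispersion shifts — none of which the generator emulates.

## Known limitations

* The index compares label sets only within one feature-gene set (the score
  records a gene-list hash for that reason), and its absolute value is not
  interpretable.
* The BIC penalty $2G\log N$ per extra cluster means a cluster is kept only
  if its feature genes carry at least that much log-likelihood; with the
  default $G_1 = 500$ genes, a ten-group design whose weakest group is
  separated by 25 modest-fold-change genes sits below this threshold, and
  CDI-BIC merges it. The index is doing exactly what its penalty says; the
  practical mitigations are a tighter feature list (with the true features
  only, the same data yield the correct K) or CDI-AIC for finer resolution.
* Applies to UMI counts only; raw read counts with PCR duplicates and
  normalized (FPKM/TPM) values violate the count model.
* The per-(g,k) batch test at fixed level 0.05 makes no multiplicity
  correction; with thousands of (g,k) pairs, ~5% of null pairs keep
  batch-specific parameters, slightly inflating $d$ symmetrically across
  candidates.
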