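---
title: "Region-centric DMR and VMR detection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-centric DMR and VMR detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionscan)
library(GenomicRanges)
library(S4Vectors)
library(SummarizedExperiment)
```

## The problem

Single-probe epigenome-wide association testing on Infinium 450K-style
arrays pays a heavy multiple-testing price (~450,000 tests) and ignores
that methylation at neighbouring CpGs is correlated: within 1 kb the
Pearson correlation of methylation values between probe pairs is
substantial (~0.45) and decays with distance. `regionscan` works at the
level of *regions* — runs of nearby probes — which both reduces the test
count by an order of magnitude and aggregates consistent signal across
neighbours.

Two region classes are covered:

* **DMRs** (differentially methylated regions): runs of probes whose
  methylation all associates with a continuous phenotype (age, here)
  beyond a percentile threshold, scored by an area statistic and tested by
  phenotype permutation.
* **VMRs** (variably methylated regions): runs of probes whose
  inter-individual variability (median absolute deviation, MAD) within one
  group all exceeds a percentile threshold, tested by an AR(1) parametric
  bootstrap of the MAD landscape.

## Probe clustering

Probes are grouped into maximal runs in which every adjacent same-
chromosome pair lies within `L` bp (anchor-to-anchor; a gap of exactly
`L` joins, reading "within" inclusively). Runs of one probe are dropped:
a region needs at least two probes. The default `L = 1000` balances
within-region correlation against probe coverage; `sweepL()` tabulates
the trade-off (more clustered probes but eventually fewer, larger regions
as `L` grows). Regions whose fraction of cross-hybridizing probes exceeds
20% (strictly) are removed.

```{r cluster-demo}
scn <- simScenario(n_probes = 1000, seed = 1)
man <- generateManifest(scn)
cl <- clusterProbes(man, L = 1000)
length(cl)
metadata(cl)$fraction_clustered
```

## DMR model

Per probe $j$, methylation is regressed on age by ordinary least squares,

$$ Y_{ij} = \gamma_j + \beta_j X_i + \varepsilon_{ij}, $$

optionally with covariates (fitting is delegated to `limma::lmFit`; the
returned statistic is either $\beta_j$ or its ordinary, unmoderated
t-statistic). Let $q_1$ be the 95th percentile of the strictly positive
statistics and $q_2$ the 5th percentile of the strictly negative ones
(linear interpolation between order statistics; comparison at the cut is
strict, so a probe exactly at $q_1$ fails). A candidate DMR is a maximal
run of two or more probes inside one distance cluster, all with
$\beta_j > q_1$ (hypermethylated with age) or all with $\beta_j < q_2$
(hypomethylated). For multi-data-set analyses the least extreme cut on
each side can be applied everywhere (`harmonizeThresholds()`).

Each candidate $r$ is scored by the trapezoidal area of $|\beta|$ over
genomic position,

$$ A_r = \sum_i \frac{(p_{i+1} - p_i)\,(|s_i| + |s_{i+1}|)}{2}, $$

which rewards both strong and spatially extended signal. Significance
comes from permutation: ages are shuffled across samples $K$ times
(default 100), the statistics refitted, the percentile thresholds
*recomputed from the permuted statistics* (the observed cuts can be
frozen via `frozen_thresholds`), candidates redetected, and all null
areas pooled. The empirical p-value is the fraction of pooled null areas
at least as large as $A_r$ (ties count; $p$ may be 0 — a `laplace`
option adds one-smoothing for users who need strictly positive p).
Benjamini–Hochberg q-values are computed over the candidates, and
regions with $q < 0.05$ are reported. BH is used rather than a
permutation-based $\pi_0$ estimator because with $K = 100$ the latter is
under-determined; BH is deterministic and conservative here.

Permutations address the null of *no phenotype association* while
preserving the full spatial covariance of the probes, which is why the
same cluster geometry is rescanned in every permutation. Age assignments
are permuted over samples in canonical (sorted-id) order, so results are
invariant to the column order of the input matrix.

## VMR model

Within one group of at least three samples, each probe gets the unscaled
MAD, $\mathrm{median}(|x - \mathrm{median}(x)|)$ (no 1.4826 factor). The
cut is the 95th percentile of all defined MADs — or, with several
groups, the lowest of the groups' 95th percentiles, mirroring the
multi-data-set harmonization. Candidates are runs of $\ge 2$ probes in a
cluster, all strictly above the cut, scored by the same area statistic
on the MAD profile.

The null model assumes the log-MAD profile along probes follows a
stationary first-order autoregression
$k_i = \rho\, k_{i-1} + e_i$, $e_i \sim N(0, \Sigma)$. The order-1 Burg
(lattice) estimator is fitted to every cluster with at least 50 probes —
its reflection-coefficient form guarantees $|\rho| < 1$ — and the
estimates are averaged arithmetically (coefficients and innovation
standard deviations separately). MADs of exactly zero (invariant probes)
are floored at $10^{-6}$ before the log.

Bootstrap landscapes are then generated over the *real* probe layout:
one independent stationary AR(1) series per cluster, independent
marginal draws for unclustered probes, exponentiated around the observed
mean log-MAD. Centring at the observed level is essential: the fitted
AR(1) describes fluctuations only, and null areas must live on the
observed MAD scale to be comparable with the observed areas. Each
simulated landscape takes its own 95th-percentile cut (mirroring "rerun
the identification procedure"; the observed cut can be reused via
`frozen_cut`), candidates are detected, and $x$ of them — $x$ being the
observed candidate count — are sampled per simulation, so the null
reflects the clustering geometry, the spatial autocorrelation, and the
selection step. Empirical p and BH q follow as for DMRs.

## Enrichment, SNP filtering, power

* `hypergeomP(k, n, K, N)` is the exact one-tailed upper tail
  $P(X \ge k)$, summed from point masses. Gene-set enrichment counts
  *probes*, not genes (`probeWeightedGeneEnrichment`), weighting each
  gene by its probe representation, with the distance-cluster list as
  the background universe. CpG-island-category and DNase-hot-spot
  enrichments are hypergeometric on probe and region counts
  respectively; overlaps of three or more region lists are tested by
  drawing size-matched null lists from the background ($10^5$
  repetitions by default).
* A probe is SNP-free when no SNP with MAF strictly above 5% lies in the
  250-bp window `[anchor - 100, anchor + 149]` (50-bp probe body
  downstream of the anchor, strand ignored, plus 100-bp flanks); a
  region is SNP-free iff all member probes are.
* `powerComparison()` contrasts the Bonferroni-corrected power of a
  Wilcoxon–Mann–Whitney two-group test under ~450,000 single-probe tests
  versus 55,003 region tests, using the large-sample normal approximation
  with ARE-deflated sample sizes (3/π normal parent; 0.864 worst case).

## The synthetic-data generator

The generators exist so the whole pipeline can be exercised against
known truth without external downloads. They emulate the features the
method relies on:

* **Long-tailed spacing.** Inter-probe gaps are a mixture of a short
  exponential component (default 75% of gaps, mean 300 bp, so ~72% of
  gaps fall within 1 kb) and a Pareto tail (exponent 1.2, scale ~1 kb,
  capped at $2 \times 10^7$ bp), reproducing dense islands separated by
  long deserts.
* **Cis-correlation.** Baselines are drawn around a shared cluster level
  and noise has a shared within-cluster component (share 0.45, matching
  the observed within-1-kb correlation scale), so neighbouring probes
  correlate and distant ones do not — compound symmetry within clusters
  rather than an explicit distance kernel, which is sufficient to
  exercise clustering and the permutation null.
* **Planted DMRs** add `slope` per year to every probe of chosen
  clusters; planted baselines are placed away from the [0,1] boundaries
  so the drift is not clipped elsewhere values are clipped to [0,1].
* **Planted VMRs**: each group's per-probe SD field is
  $\exp(\mu + s_i)$ with $s_i$ a stationary AR(1) along probes within
  clusters ($\rho = 0.5$, marginal SD 0.5, $\mu = \log 0.04$ — a typical
  beta-value SD); planted clusters get their log-SD raised by the stated
  shift in natural-log units in the designated group (a shift of 1.5
  inflates the SD ~4.5-fold, which reproduces the ~1.5–2× ratio of
  95th-percentile MADs between inflated and control groups).

What the generators do *not* emulate: array chemistry (type I/II probes,
dye bias), cell-composition heterogeneity, batch structure, and the
bounded-support distortion of beta values near 0/1 beyond simple
clipping. Passing the recovery tests therefore demonstrates the
statistical machinery, not robustness to those artefacts.

## Problem sizes and numerical choices

The test-bed scenarios use 5,000 probes: 20 planted DMR clusters (≥ 5
probes each, slopes ±0.002/yr, 40 samples aged 1–80, noise SD 0.03,
K = 100 permutations) and 15 planted VMR clusters (≥ 12 probes, shift
1.5, two groups of 40, K = 100 bootstrap simulations). The VMR layout is
densified (97% short gaps, mean 250 bp) so that clusters with ≥ 50
probes — required by the AR(1) pooling rule — exist at the 5,000-probe
scale; on a full 485k-probe array they occur naturally. Planted DMR
clusters need a handful of probes because the area statistic rewards
spatial extent: a two-probe island DMR has a small area however strong
its slope, which is a property of the method, not of the
implementation. The VMR recovery harness applies the harmonized
lowest-95th-percentile cut across the two groups, the procedure used
whenever several data sets are analysed together; it also keeps the
observed cut consistent with the bootstrap landscapes' own cuts.

Other numerical choices: percentiles use R quantile type 7 (linear
interpolation between order statistics); Burg's $\rho$ is clamped
infinitesimally inside $(-1, 1)$ so degenerate inputs (e.g. a perfectly
alternating series) still define a stationary process; probes with more
than 20% missing samples are excluded from statistics and percentiles
(remaining statistics use the available samples); duplicate probe
positions are an error for the area statistic; empty positive or
negative statistic subsets make the corresponding threshold an error
rather than a silent NA.

## Known limitations

* Empirical p-values are granular at $1/|\text{null}|$; with small $K$
  and few candidates, q-values are coarse.
* The AR(1) log-MAD model is a convenience null; real MAD landscapes
  have heavier tails and nonstationarity, so bootstrap p-values should
  be read as calibrated against the fitted process, not against
  biological truth.
* The area statistic confounds effect size and spatial extent by
  design; narrow but strong regions rank below wide moderate ones.
* No cell-composition deconvolution, normalization, or probe-type
  correction is attempted: the package expects preprocessed beta values.
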