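#' Per-probe association statistics
#'
#' Fits, for every probe, an ordinary least-squares regression of
#' fractional methylation on age (plus optional covariates) and returns
#' either the age coefficient (`"beta"`) or its ordinary t-statistic
#' (`"t"`). Fitting is delegated to [limma::lmFit()], which handles missing
#' values probe-wise. Probes with more than `max_missing` missing samples,
#' or with an undefined statistic, are returned as `NA` and excluded from
#' all downstream percentile computations.
#'
#' @param mset a [MethylationSet] whose `colData` has a numeric `age`.
#' @param stat_type `"beta"` (age slope) or `"t"` (slope / SE).
#' @param covariates optional character vector of `colData` column names to
#'   adjust for.
#' @param max_missing maximum tolerated fraction of missing samples per
#'   probe, default 0.2.
#' @return named numeric vector aligned to the manifest, with
#'   `attr(, "stat_type")` set.
#' @export
fitProbeStatistics <- function(mset, stat_type = c("beta", "t"),
                               covariates = NULL, max_missing = 0.2) {
  stat_type <- match.arg(stat_type)
  b <- assay(mset, "beta")
  if (ncol(b) < 3L) stop("at least 3 samples required", call. = FALSE)
  cd <- as.data.frame(colData(mset))
  if (!"age" %in% colnames(cd)) stop("colData lacks 'age'", call. = FALSE)
  if (stats::var(cd$age) == 0)
    stop("age has zero variance", call. = FALSE)
  design <- stats::model.matrix(
    stats::reformulate(c("age", covariates)), data = cd)
  .fitStats(b, design, stat_type, max_missing)
}

.fitStats <- function(b, design, stat_type, max_missing = 0.2) {
  fit <- limma::lmFit(b, design)
  beta <- fit$coefficients[, "age"]
  out <- if (stat_type == "beta") beta
  else beta / (fit$stdev.unscaled[, "age"] * fit$sigma)
  out[!is.finite(out)] <- NA_real_
  missfrac <- rowMeans(is.na(b))
  out[missfrac > max_missing] <- NA_real_
  names(out) <- rownames(b)
  attr(out, "stat_type") <- stat_type
  out
}

#' Percentile thresholds for candidate calling
#'
#' In signed mode (`beta`/`t` statistics), `q1` is the `upper` percentile of
#' the strictly positive statistics only and `q2` the `lower` percentile of
#' the strictly negative ones; both subsets must be non-empty. In MAD mode
#' only `q1` is computed, over all defined values. Percentiles use linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param stats per-probe statistic vector (`NA` = undefined, excluded).
#' @param upper,lower percentiles in (0, 100), defaults 95 and 5.
#' @param mode `"signed"` for beta/t statistics, `"mad"` for MAD scores.
#' @return a [StatThresholds].
#' @export
percentileThresholds <- function(stats, upper = 95, lower = 5,
                                 mode = c("signed", "mad")) {
  mode <- match.arg(mode)
  s <- stats[!is.na(stats)]
  if (mode == "mad")
    return(StatThresholds(q1 = quantile(s, upper / 100, names = FALSE,
                                        type = 7)))
  pos <- s[s > 0]
  neg <- s[s < 0]
  if (!length(pos))
    stop("no positive statistics: upper threshold undefined", call. = FALSE)
  if (!length(neg))
    stop("no negative statistics: lower threshold undefined", call. = FALSE)
  StatThresholds(
    q1 = quantile(pos, upper / 100, names = FALSE, type = 7),
    q2 = quantile(neg, lower / 100, names = FALSE, type = 7))
}

#' Harmonize thresholds across data sets
#'
#' For multi-data-set analyses the least extreme cut on each side is
#' applied everywhere: the smallest `q1` and the largest `q2`.
#'
#' @param per_dataset list of [StatThresholds].
#' @return a single [StatThresholds].
#' @export
harmonizeThresholds <- function(per_dataset) {
  stopifnot(length(per_dataset) >= 1L)
  q1 <- min(vapply(per_dataset, function(t) t@q1, 0))
  q2s <- vapply(per_dataset, function(t) t@q2, 0)
  StatThresholds(q1 = q1,
                 q2 = if (all(is.na(q2s))) NA_real_ else max(q2s, na.rm = TRUE))
}

#' Call candidate regions from a probe statistic
#'
#' Within each distance-defined cluster, finds maximal runs of consecutive
#' probes whose statistic all exceeds `q1` (direction `hyper`) or all falls
#' below `q2` (`hypo`); in VMR mode, all MAD values above `q1` (direction
#' `variable`). Comparison is strict (a probe exactly at the cut fails). A
#' probe failing the cut, with an undefined statistic, or of the opposite
#' sign breaks the run. Runs of at least two probes become candidates.
#'
#' @param regions cluster `GRanges` from [clusterProbes()].
#' @param stats per-probe statistic aligned to the manifest.
#' @param th a [StatThresholds].
#' @param mode `"dmr"` (two-sided, signed) or `"vmr"` (upper tail only).
#' @param manifest the manifest `GRanges` the clusters index into.
#' @return a `GRanges` of unscored candidates with metadata `n_probes`,
#'   `probe_idx`, `probe_ids`, `direction`, `member_stats`, `member_pos`,
#'   and `cluster` (name of the parent distance cluster).
#' @export
detectCandidates <- function(regions, stats, th,
                             mode = c("dmr", "vmr"), manifest) {
  mode <- match.arg(mode)
  if (!length(regions)) return(.emptyCandidates())
  idx <- unlist(regions$probe_idx, use.names = FALSE)
  clu <- rep(seq_along(regions), lengths(regions$probe_idx))
  s <- stats[idx]
  cls <- if (mode == "vmr") ifelse(!is.na(s) & s > th@q1, 1L, 0L)
  else ifelse(is.na(s), 0L,
              ifelse(s > th@q1, 1L, ifelse(s < th@q2, -1L, 0L)))
  n <- length(idx)
  newrun <- c(TRUE, clu[-1L] != clu[-n] | cls[-1L] != cls[-n])
  rid <- cumsum(newrun)
  len <- tabulate(rid)
  keep <- which(cls != 0L & len[rid] >= 2L)
  if (!length(keep)) return(.emptyCandidates())
  r <- rid[keep]
  first <- keep[!duplicated(r)]
  ch <- as.character(seqnames(manifest))[idx]
  pos <- start(manifest)[idx]
  last <- keep[!duplicated(r, fromLast = TRUE)]
  out <- GRanges(ch[first], IRanges(start = pos[first], end = pos[last]))
  grp <- unname(split(keep, r))
  mcols(out)$n_probes <- unname(lengths(grp))
  mcols(out)$probe_idx <- IntegerList(lapply(grp, function(k) idx[k]))
  mcols(out)$probe_ids <- CharacterList(lapply(grp, function(k)
    names(manifest)[idx[k]]))
  mcols(out)$direction <- unname(ifelse(
    cls[first] == 1L, if (mode == "vmr") "variable" else "hyper", "hypo"))
  mcols(out)$member_stats <- NumericList(lapply(grp, function(k)
    unname(s[k])))
  mcols(out)$member_pos <- NumericList(lapply(grp, function(k) pos[k]))
  cluNames <- if (is.null(names(regions)))
    as.character(seq_along(regions)) else names(regions)
  mcols(out)$cluster <- cluNames[clu[first]]
  names(out) <- sprintf("cand_%05d", seq_along(out))
  out
}

# Lean run-and-area scan used inside permutation / bootstrap loops: same
# candidate definition as detectCandidates + regionArea, but returns the
# areas only, with no S4 object construction.
# layout = list(idx, clu, pos) precomputed once from the cluster GRanges.
.scanLayout <- function(regions) {
  idx <- unlist(regions$probe_idx, use.names = FALSE)
  list(idx = idx,
       clu = rep(seq_along(regions), lengths(regions$probe_idx)))
}

.runAreas <- function(s_all, layout, pos_all, q1, q2 = NA_real_,
                      vmr = FALSE) {
  idx <- layout$idx
  clu <- layout$clu
  n <- length(idx)
  if (!n) return(numeric())
  s <- s_all[idx]
  pos <- pos_all[idx]
  cls <- integer(n)
  ok <- !is.na(s)
  cls[ok & s > q1] <- 1L
  if (!vmr) cls[ok & s < q2] <- -1L
  newrun <- c(TRUE, clu[-1L] != clu[-n] | cls[-1L] != cls[-n])
  rid <- cumsum(newrun)
  len <- tabulate(rid)
  kept <- cls != 0L & len[rid] >= 2L
  if (!any(kept)) return(numeric())
  within <- rid[-1L] == rid[-n] & kept[-1L]
  a <- abs(s)
  contrib <- diff(pos) * (a[-n] + a[-1L]) / 2
  as.numeric(rowsum(contrib[within], rid[-1L][within]))
}

.emptyCandidates <- function() {
  out <- GRanges()
  mcols(out)$n_probes <- integer()
  mcols(out)$probe_idx <- IntegerList()
  mcols(out)$probe_ids <- CharacterList()
  mcols(out)$direction <- character()
  mcols(out)$member_stats <- NumericList()
  mcols(out)$member_pos <- NumericList()
  mcols(out)$cluster <- character()
  out
}

#' Trapezoidal region area statistic
#'
#' The area under the absolute per-probe statistic against genomic
#' position, approximated by trapezoidal numerical integration:
#' `sum over adjacent pairs of (pos[i+1]-pos[i]) * (|s[i]|+|s[i+1]|) / 2`.
#'
#' @param candidates candidate `GRanges` from [detectCandidates()], or a
#'   numeric vector of strictly increasing positions (then `stats` must be
#'   given and a single area is returned).
#' @param stats per-probe statistic values when `candidates` is a position
#'   vector.
#' @return numeric vector of areas (one per candidate), or a single area.
#' @export
regionArea <- function(candidates, stats = NULL) {
  if (is.numeric(candidates)) {
    stopifnot(!is.null(stats), length(stats) == length(candidates))
    return(.trapArea(candidates, stats))
  }
  if (!length(candidates)) return(numeric())
  unname(mapply(.trapArea, as.list(candidates$member_pos),
                as.list(candidates$member_stats)))
}

.trapArea <- function(pos, s) {
  if (anyDuplicated(pos)) stop("duplicate probe positions", call. = FALSE)
  if (is.unsorted(pos)) {
    o <- order(pos); pos <- pos[o]; s <- s[o]
  }
  n <- length(pos)
  if (n < 2L) stop("need at least 2 probes for an area", call. = FALSE)
  a <- abs(s)
  sum(diff(pos) * (a[-n] + a[-1L]) / 2)
}

#' Permutation null distribution of DMR areas
#'
#' Repeatedly permutes the ages across samples, refits the per-probe
#' statistics, recomputes the percentile thresholds (unless frozen), reruns
#' candidate detection over the same distance clusters and records every
#' null region area. Areas are pooled over all `K` permutations together
#' with the per-permutation counts.
#'
#' @param mset a [MethylationSet] with `age` in its `colData`.
#' @param regions cluster `GRanges` (after any cross-hybridizing filter).
#' @param stat_type `"beta"` or `"t"`.
#' @param upper,lower percentiles for the cuts.
#' @param K number of permutations, default 100.
#' @param seed integer seed; the whole null is reproducible from it.
#' @param frozen optional [StatThresholds] to reuse in every permutation
#'   instead of recomputing from the permuted statistics.
#' @param covariates covariate column names passed to the fit (kept with
#'   their samples; only the ages are permuted).
#' @param max_missing per-probe missing tolerance, as in
#'   [fitProbeStatistics()].
#' @param permuteFun permutation generator, `function(n)` returning an
#'   ordering of `1:n`; the default is [sample()]. Supplying
#'   `seq_len` forces identity permutations (useful for checking).
#' @return a [NullAreaDistribution].
#' @export
permutationNull <- function(mset, regions, stat_type = c("beta", "t"),
                            upper = 95, lower = 5, K = 100, seed = 1,
                            frozen = NULL, covariates = NULL,
                            max_missing = 0.2, permuteFun = sample) {
  stat_type <- match.arg(stat_type)
  stopifnot(K >= 1L)
  b <- assay(mset, "beta")
  cd <- as.data.frame(colData(mset))
  manifest <- rowRanges(mset)
  pos_all <- start(manifest)
  layout <- .scanLayout(regions)
  n <- ncol(b)
  # permute ages over samples in canonical (sorted-id) order so the null is
  # invariant to the column order of the input matrix
  ord <- order(colnames(b))
  areas <- vector("list", K)
  set.seed(seed)
  for (k in seq_len(K)) {
    cdk <- cd
    cdk$age[ord] <- cd$age[ord][permuteFun(n)]
    design <- stats::model.matrix(
      stats::reformulate(c("age", covariates)), data = cdk)
    s <- .fitStats(b, design, stat_type, max_missing)
    th <- if (is.null(frozen))
      percentileThresholds(s, upper, lower, mode = "signed") else frozen
    areas[[k]] <- .runAreas(s, layout, pos_all, th@q1, th@q2)
  }
  NullAreaDistribution(unlist(areas), vapply(areas, length, 0L))
}

#' Empirical p-values against a pooled null area distribution
#'
#' For each observed region area `A_r`, `p_r` is the fraction of pooled
#' null areas at least as large (ties count). With the default (literal)
#' estimator `p` can be zero; `laplace = TRUE` uses
#' `(1 + count) / (1 + total)` instead.
#'
#' @param candidates candidate `GRanges`; their areas are computed with
#'   [regionArea()] if not already present in `mcols()$area`.
#' @param null a [NullAreaDistribution]; must be non-empty.
#' @param laplace add-one smoothing, default off.
#' @return the candidates with `area` and `p` metadata columns filled.
#' @export
empiricalPvalues <- function(candidates, null, laplace = FALSE) {
  if (!length(nullAreas(null)))
    stop("null area distribution is empty", call. = FALSE)
  if (!length(candidates)) {
    mcols(candidates)$area <- numeric()
    mcols(candidates)$p <- numeric()
    return(candidates)
  }
  if (is.null(mcols(candidates)$area))
    mcols(candidates)$area <- regionArea(candidates)
  a0 <- nullAreas(null)
  cnt <- vapply(candidates$area, function(a) sum(a0 >= a), 0)
  mcols(candidates)$p <- if (laplace) (1 + cnt) / (1 + length(a0))
  else cnt / length(a0)
  candidates
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR q-values (the minimum FDR at which each test would be called
#' significant), input order preserved, capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0,1\].
#' @return numeric vector of q-values, same order.
#' @export
estimateQvalues <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Run the full DMR scan
#'
#' Distance clustering, cross-hybridizing region filter, per-probe
#' regression statistics, percentile thresholds, candidate calling,
#' trapezoidal areas, phenotype-permutation null, empirical p-values and
#' BH q-values, keeping regions with `q < fdr_cut`.
#'
#' @inheritParams permutationNull
#' @param L distance threshold in bp.
#' @param fdr_cut FDR cut-off, default 0.05.
#' @param max_cross_fraction cross-hybridizing filter threshold.
#' @param laplace smoothing for the empirical p (see [empiricalPvalues()]).
#' @param frozen_thresholds if `TRUE`, permutations reuse the observed
#'   thresholds instead of recomputing their own.
#' @param thresholds optional [StatThresholds] to use instead of the data's
#'   own percentiles (e.g. harmonized across data sets).
#' @return a [RegionScanResult]; `scanParams()` additionally reports
#'   `n_hyper`, `n_hypo` and `fraction_hypo` over the significant regions.
#' @export
runDMRPipeline <- function(mset, L = 1000, stat_type = c("beta", "t"),
                           upper = 95, lower = 5, K = 100, fdr_cut = 0.05,
                           max_cross_fraction = 0.2, seed = 1,
                           covariates = NULL, max_missing = 0.2,
                           laplace = FALSE, frozen_thresholds = FALSE,
                           thresholds = NULL) {
  stat_type <- match.arg(stat_type)
  manifest <- rowRanges(mset)
  clusters <- clusterProbes(manifest, L)
  clusters <- filterCrossHybridizing(clusters, manifest, max_cross_fraction)
  stats <- fitProbeStatistics(mset, stat_type, covariates, max_missing)
  th <- if (is.null(thresholds))
    percentileThresholds(stats, upper, lower, mode = "signed")
  else thresholds
  cand <- detectCandidates(clusters, stats, th, mode = "dmr", manifest)
  mcols(cand)$area <- regionArea(cand)
  null <- permutationNull(mset, clusters, stat_type, upper, lower, K, seed,
                          frozen = if (frozen_thresholds) th else NULL,
                          covariates = covariates, max_missing = max_missing)
  cand <- empiricalPvalues(cand, null, laplace)
  mcols(cand)$q <- estimateQvalues(cand$p)
  sig <- cand[!is.na(cand$q) & cand$q < fdr_cut]
  n_hyper <- sum(sig$direction == "hyper")
  n_hypo <- sum(sig$direction == "hypo")
  new("RegionScanResult", regions = cand, significant = sig, null = null,
      thresholds = th,
      params = list(mode = "dmr", L = L, stat_type = stat_type,
                    upper = upper, lower = lower, K = K, fdr_cut = fdr_cut,
                    seed = seed, n_hyper = n_hyper, n_hypo = n_hypo,
                    fraction_hypo = if (length(sig))
                      n_hypo / length(sig) else NA_real_,
                    fraction_clustered =
                      metadata(clusters)$fraction_clustered))
}

#' Power of region-level versus single-probe testing
#'
#' Compares the achieved power of a Wilcoxon-Mann-Whitney two-group test at
#' Bonferroni-corrected significance levels when the multiple-testing
#' burden is the full probe count versus the region count. Power is the
#' large-sample normal approximation for the two-sided two-sample location
#' test, with the sample sizes deflated by the asymptotic relative
#' efficiency of the rank test (3/pi for a normal parent; 0.864, the
#' minimum ARE over all parents, as a conservative option).
#'
#' @param d standardized effect size (difference in means / SD), `> 0`.
#' @param n1,n2 group sizes, each at least 2.
#' @param alpha_family family-wise error target, default 0.05.
#' @param m_single number of single-probe tests, default 450000.
#' @param m_region number of region tests, default 55003.
#' @param parent parent distribution assumption for the ARE correction.
#' @return named numeric: `power_single`, `power_region`.
#' @export
powerComparison <- function(d, n1, n2, alpha_family = 0.05,
                            m_single = 450000, m_region = 55003,
                            parent = c("normal", "min_are")) {
  parent <- match.arg(parent)
  stopifnot(d > 0, n1 >= 2, n2 >= 2)
  if (m_single <= 0 || m_region <= 0)
    stop("test counts must be positive", call. = FALSE)
  are <- if (parent == "normal") 3 / pi else 0.864
  pw <- function(alpha) {
    e1 <- are * n1; e2 <- are * n2
    ncp <- d * sqrt(e1 * e2 / (e1 + e2))
    zc <- qnorm(1 - alpha / 2)
    pnorm(ncp - zc) + pnorm(-ncp - zc)
  }
  c(power_single = pw(alpha_family / m_single),
    power_region = pw(alpha_family / m_region))
}
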