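#' Per-probe MAD of methylation within a group
#'
#' The unscaled median absolute deviation (no 1.4826 consistency factor):
#' `median(|x - median(x)|)` across the samples of one group, per probe.
#' Probes with more than `max_missing` missing samples are `NA`.
#'
#' @param mset a [MethylationSet].
#' @param group_samples character vector of sample ids forming the group;
#'   at least 3.
#' @param max_missing per-probe missing-sample tolerance.
#' @return named numeric vector aligned to the manifest,
#'   `attr(, "stat_type") == "mad"`.
#' @export
computeMAD <- function(mset, group_samples, max_missing = 0.2) {
  if (length(group_samples) < 3L)
    stop("group must contain at least 3 samples", call. = FALSE)
  miss <- setdiff(group_samples, colnames(mset))
  if (length(miss))
    stop("unknown sample id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  b <- assay(mset, "beta")[, group_samples, drop = FALSE]
  out <- apply(b, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    median(abs(x - median(x)))
  })
  out[rowMeans(is.na(b)) > max_missing] <- NA_real_
  names(out) <- rownames(b)
  attr(out, "stat_type") <- "mad"
  out
}

#' Order-1 Burg estimate of an AR(1) process
#'
#' Burg's lattice estimator at order 1: with the mean-centred series,
#' forward residuals `f = x[2:n]` and backward residuals `b = x[1:(n-1)]`,
#' `rho = 2 * sum(f*b) / sum(f^2 + b^2)` (the reflection coefficient, which
#' always satisfies `|rho| <= 1`), and the innovation standard deviation
#' `sigma = sqrt((1 - rho^2) * mean(x^2))`. `rho` is clamped infinitesimally
#' inside (-1, 1) so a valid stationary process is always returned.
#'
#' @param series numeric vector, length at least 3, finite, non-constant.
#' @return an [AR1Params].
#' @export
fitAR1Burg <- function(series) {
  x <- as.numeric(series)
  if (length(x) < 3L) stop("series too short (need >= 3)", call. = FALSE)
  if (any(!is.finite(x))) stop("series must be finite", call. = FALSE)
  x <- x - mean(x)
  v0 <- mean(x^2)
  if (v0 == 0) stop("zero-variance series", call. = FALSE)
  n <- length(x)
  f <- x[-1L]
  b <- x[-n]
  rho <- 2 * sum(f * b) / sum(f^2 + b^2)
  rho <- max(min(rho, 1 - 1e-10), -1 + 1e-10)
  AR1Params(rho = rho, sigma = sqrt((1 - rho^2) * v0))
}

#' Pooled AR(1) parameters over large regions
#'
#' Natural-log-transforms the MAD profile (zeros floored at `mad_floor`),
#' fits an order-1 Burg AR model to each region containing at least
#' `min_probes` probes, and returns the arithmetic mean of the coefficient
#' and of the innovation standard deviation.
#'
#' @param mads per-probe MAD vector from [computeMAD()].
#' @param regions cluster `GRanges` from [clusterProbes()].
#' @param min_probes minimum region size to qualify, default 50.
#' @param mad_floor floor applied before the log, default 1e-6.
#' @return an [AR1Params] with `n` = number of regions pooled.
#' @export
poolAR1 <- function(mads, regions, min_probes = 50, mad_floor = 1e-6) {
  big <- which(regions$n_probes >= min_probes)
  if (!length(big))
    stop("no region has >= ", min_probes,
         " probes; reduce min_probes", call. = FALSE)
  fits <- lapply(big, function(r) {
    s <- log(pmax(mads[regions$probe_idx[[r]]], mad_floor))
    s <- s[!is.na(s)]
    fitAR1Burg(s)
  })
  AR1Params(rho = mean(vapply(fits, arRho, 0)),
            sigma = mean(vapply(fits, arSigma, 0)),
            n = length(fits))
}

#' Parametric-bootstrap null distribution of VMR areas
#'
#' For each of `n_sim` simulations, draws a synthetic log-MAD landscape
#' over the real probe layout from the stationary AR(1) process with the
#' pooled parameters (one independent series per distance cluster; probes
#' outside clusters get independent marginal draws), exponentiates it
#' around the level `mu`, takes the simulation's own `upper` percentile as
#' the cut (or `q1_obs` when supplied), reruns VMR candidate detection,
#' randomly selects `x` candidates (all, if fewer) and records their
#' trapezoidal areas. Null areas therefore reflect both the clustering
#' geometry and the spatial autocorrelation of the MAD profile.
#'
#' @param manifest probe manifest `GRanges`.
#' @param regions cluster `GRanges` the detection runs over.
#' @param pooled an [AR1Params] (e.g. from [poolAR1()]).
#' @param x number of null regions to keep per simulation (the observed
#'   VMR count), at least 1.
#' @param n_sim number of simulations, default 100.
#' @param seed integer seed; the whole null is reproducible from it.
#' @param upper percentile cut, default 95.
#' @param q1_obs optional fixed cut reused in every simulation instead of
#'   each simulation's own percentile.
#' @param mu mean log-MAD level around which the landscape is generated
#'   (the observed mean log-MAD keeps null areas on the data's scale).
#' @return a [NullAreaDistribution].
#' @export
simulateNullVMRAreas <- function(manifest, regions, pooled, x, n_sim = 100,
                                 seed = 1, upper = 95, q1_obs = NULL,
                                 mu = 0) {
  if (n_sim < 1L) stop("n_sim must be >= 1", call. = FALSE)
  stopifnot(x >= 1L)
  set.seed(seed)
  n <- length(manifest)
  # cluster membership: probes within a region continue the series,
  # cluster starts and singleton probes restart it at the marginal law
  in_region <- integer(n)
  for (r in seq_along(regions)) in_region[regions$probe_idx[[r]]] <- r
  is_start <- c(TRUE, in_region[-1L] != in_region[-n] | in_region[-1L] == 0L)
  rho <- arRho(pooled)
  sig <- arSigma(pooled)
  marg <- sig / sqrt(1 - rho^2)
  # all landscapes at once: innovations for continuing probes, marginal
  # draws at series starts, then one recursive pass over probes
  E <- matrix(rnorm(n * n_sim, sd = sig), n, n_sim)
  E[is_start, ] <- rnorm(sum(is_start) * n_sim, sd = marg)
  S <- E
  for (i in seq_len(n)[-1L])
    if (!is_start[i]) S[i, ] <- rho * S[i - 1L, ] + E[i, ]
  layout <- .scanLayout(regions)
  pos_all <- start(manifest)
  areas <- vector("list", n_sim)
  for (k in seq_len(n_sim)) {
    madsim <- exp(mu + S[, k])
    q1 <- if (is.null(q1_obs))
      quantile(madsim, upper / 100, names = FALSE, type = 7) else q1_obs
    a <- .runAreas(madsim, layout, pos_all, q1, vmr = TRUE)
    if (length(a)) {
      pick <- if (length(a) > x) sample(length(a), x) else seq_along(a)
      areas[[k]] <- a[pick]
    } else areas[[k]] <- numeric()
  }
  NullAreaDistribution(unlist(areas), vapply(areas, length, 0L))
}

#' Run the full VMR scan for one group
#'
#' Distance clustering, cross-hybridizing filter, per-probe MAD within the
#' group, 95th-percentile cut (harmonized to the lowest cut across groups
#' when `harmonize_with` is given), candidate calling, trapezoidal areas,
#' AR(1) parametric-bootstrap null, empirical p-values, BH q-values, and
#' the `q < fdr_cut` subset.
#'
#' @param mset a [MethylationSet].
#' @param group_samples sample ids of the group to scan.
#' @param harmonize_with optional list of sample-id vectors for other
#'   groups; the applied cut is the lowest of all groups' `upper`
#'   percentiles.
#' @param L distance threshold in bp.
#' @param upper percentile for the MAD cut, default 95.
#' @param K number of bootstrap simulations, default 100.
#' @param fdr_cut FDR cut-off, default 0.05.
#' @param max_cross_fraction cross-hybridizing filter threshold.
#' @param min_probes minimum region size for the AR(1) fit, default 50.
#' @param mad_floor floor for log-MAD, default 1e-6.
#' @param seed integer seed for the bootstrap.
#' @param frozen_cut if `TRUE`, bootstrap simulations reuse the observed
#'   cut instead of their own percentile.
#' @param laplace smoothing for the empirical p.
#' @return a [RegionScanResult].
#' @export
runVMRPipeline <- function(mset, group_samples, harmonize_with = NULL,
                           L = 1000, upper = 95, K = 100, fdr_cut = 0.05,
                           max_cross_fraction = 0.2, min_probes = 50,
                           mad_floor = 1e-6, seed = 1, frozen_cut = FALSE,
                           laplace = FALSE) {
  manifest <- rowRanges(mset)
  clusters <- clusterProbes(manifest, L)
  clusters <- filterCrossHybridizing(clusters, manifest, max_cross_fraction)
  mads <- computeMAD(mset, group_samples)
  q1 <- percentileThresholds(mads, upper, mode = "mad")@q1
  if (!is.null(harmonize_with)) {
    others <- vapply(harmonize_with, function(g)
      percentileThresholds(computeMAD(mset, g), upper, mode = "mad")@q1, 0)
    q1 <- min(q1, others)
  }
  th <- StatThresholds(q1)
  cand <- detectCandidates(clusters, mads, th, mode = "vmr", manifest)
  if (!length(cand)) {
    mcols(cand)$area <- numeric()
    mcols(cand)$p <- numeric()
    mcols(cand)$q <- numeric()
    return(new("RegionScanResult", regions = cand, significant = cand,
               null = NullAreaDistribution(numeric(), integer()),
               thresholds = th,
               params = list(mode = "vmr", L = L, upper = upper, K = K,
                             fdr_cut = fdr_cut, seed = seed)))
  }
  mcols(cand)$area <- regionArea(cand)
  pooled <- poolAR1(mads, clusters, min_probes, mad_floor)
  mu <- mean(log(pmax(mads[!is.na(mads)], mad_floor)))
  null <- simulateNullVMRAreas(manifest, clusters, pooled, x = length(cand),
                               n_sim = K, seed = seed, upper = upper,
                               q1_obs = if (frozen_cut) q1 else NULL,
                               mu = mu)
  cand <- empiricalPvalues(cand, null, laplace)
  mcols(cand)$q <- estimateQvalues(cand$p)
  sig <- cand[!is.na(cand$q) & cand$q < fdr_cut]
  new("RegionScanResult", regions = cand, significant = sig, null = null,
      thresholds = th,
      params = list(mode = "vmr", L = L, upper = upper, K = K,
                    fdr_cut = fdr_cut, seed = seed,
                    ar1 = c(rho = arRho(pooled), sigma = arSigma(pooled)),
                    mu_log_mad = mu))
}

#' Ratio of MAD percentiles between groups
#'
#' Pairwise ratios of the `pct`-th percentile MAD between groups, e.g. how
#' much more variable one age group is than another at the 95th percentile.
#'
#' @param groups named list of per-probe MAD vectors (see [computeMAD()]).
#' @param pct percentile, default 95.
#' @return square matrix `r` with `r[i, j]` = percentile(i) / percentile(j).
#' @export
madPercentileRatio <- function(groups, pct = 95) {
  stopifnot(length(groups) >= 2L)
  q <- vapply(groups, function(m)
    quantile(m[!is.na(m)], pct / 100, names = FALSE, type = 7), 0)
  if (any(q == 0)) stop("zero percentile MAD in a group", call. = FALSE)
  outer(q, q, "/")
}
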