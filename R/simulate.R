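#' Simulation scenario for synthetic methylation data
#'
#' Bundles the parameters of the synthetic-data generators: the probe
#' layout (a two-component gap law: a short-gap exponential component and
#' a long-gap Pareto tail, reproducing the long-tailed inter-probe spacing
#' of the 450K array), the planted effects, and the noise/correlation
#' structure the region method assumes.
#'
#' @param n_probes total number of probes.
#' @param n_chroms number of chromosomes (probes split evenly).
#' @param short_gap_fraction probability a gap is drawn from the short
#'   component, in \[0,1\].
#' @param short_gap_mean mean of the exponential short-gap component (bp).
#' @param long_gap_exponent Pareto tail exponent of the long component.
#' @param long_gap_scale Pareto scale (bp); long gaps exceed this.
#' @param min_gap,max_gap hard bounds on any gap (bp), defaults 2 and 2e7.
#' @param planted_dmrs `data.frame(region, slope)`: distance-cluster
#'   indices (at L = 1000) receiving an age-linear methylation drift of
#'   `slope` per year.
#' @param planted_vmrs `data.frame(region, shift)`: cluster indices whose
#'   log-methylation-SD is raised by `shift` natural-log units in the
#'   designated group (`shift = 1.5` inflates the SD about 4.5-fold).
#' @param noise_sd per-sample measurement noise SD on the beta scale.
#' @param cis_cor share of noise (and of baseline) variance shared within
#'   a cluster; gives neighbouring probes correlated methylation.
#' @param ar1_rho lag-1 autocorrelation of the log-SD field along probes
#'   within clusters, |rho| < 1.
#' @param log_sd_scale marginal SD of the log-SD field.
#' @param log_sd_mean mean log methylation SD (default `log(0.04)`).
#' @param seed base seed; every generator is a pure function of
#'   (scenario, seed).
#' @return an object of class `SimScenario` (a validated list).
#' @export
simScenario <- function(n_probes = 5000, n_chroms = 3,
                        short_gap_fraction = 0.75, short_gap_mean = 300,
                        long_gap_exponent = 1.2, long_gap_scale = 1001,
                        min_gap = 2, max_gap = 2e7,
                        planted_dmrs = NULL, planted_vmrs = NULL,
                        noise_sd = 0.03, cis_cor = 0.45, ar1_rho = 0.5,
                        log_sd_scale = 0.5, log_sd_mean = log(0.04),
                        seed = 1) {
  stopifnot(n_probes >= 2, n_chroms >= 1,
            short_gap_fraction >= 0, short_gap_fraction <= 1,
            short_gap_mean > 0, long_gap_exponent > 0,
            min_gap >= 1, max_gap > min_gap,
            noise_sd >= 0, cis_cor >= 0, cis_cor <= 1,
            abs(ar1_rho) < 1, log_sd_scale > 0)
  scn <- list(n_probes = as.integer(n_probes),
              n_chroms = as.integer(n_chroms),
              short_gap_fraction = short_gap_fraction,
              short_gap_mean = short_gap_mean,
              long_gap_exponent = long_gap_exponent,
              long_gap_scale = long_gap_scale,
              min_gap = min_gap, max_gap = max_gap,
              planted_dmrs = planted_dmrs, planted_vmrs = planted_vmrs,
              noise_sd = noise_sd, cis_cor = cis_cor, ar1_rho = ar1_rho,
              log_sd_scale = log_sd_scale, log_sd_mean = log_sd_mean,
              seed = as.integer(seed))
  class(scn) <- "SimScenario"
  scn
}

#' @export
print.SimScenario <- function(x, ...) {
  cat(sprintf(
    "SimScenario: %d probes on %d chromosome(s), seed %d\n",
    x$n_probes, x$n_chroms, x$seed))
  cat(sprintf("  gap law: %.0f%% exp(mean %g bp) + Pareto(alpha %g)\n",
              100 * x$short_gap_fraction, x$short_gap_mean,
              x$long_gap_exponent))
  cat(sprintf("  planted DMRs: %d, planted VMRs: %d\n",
              NROW(x$planted_dmrs), NROW(x$planted_vmrs)))
  invisible(x)
}

#' Generate a synthetic probe manifest
#'
#' Inter-probe gaps are drawn from the scenario's mixture law; positions
#' accumulate per chromosome. Gene symbols are assigned in blocks of ten
#' probes (one in five blocks intergenic), island categories are sampled
#' with array-like frequencies, and ~1% of probes are flagged
#' cross-hybridizing.
#'
#' @param scn a [simScenario()].
#' @param seed seed; defaults to the scenario's.
#' @return a manifest `GRanges` (see [makeManifest()]).
#' @export
generateManifest <- function(scn, seed = scn$seed) {
  set.seed(seed)
  per <- diff(round(seq(0, scn$n_probes, length.out = scn$n_chroms + 1)))
  pid <- 0L
  parts <- lapply(seq_len(scn$n_chroms), function(c) {
    n <- per[c]
    gaps <- .drawGaps(n - 1L, scn)
    pos <- cumsum(c(10000, gaps))
    ids <- sprintf("cg%07d", pid + seq_len(n))
    pid <<- pid + n
    data.frame(probe_id = ids, chrom = paste0("chr", c), pos = pos)
  })
  df <- do.call(rbind, parts)
  block <- ceiling(seq_len(nrow(df)) / 10)
  has_gene <- (block %% 5L) != 0L
  genes <- ifelse(has_gene, sprintf("GENE%04d", block), "")
  cats <- sample(.ISLAND_CATEGORIES, nrow(df), replace = TRUE,
                 prob = c(0.30, 0.12, 0.12, 0.05, 0.05, 0.36))
  xhyb <- runif(nrow(df)) < 0.01
  makeManifest(df$probe_id, df$chrom, df$pos, genes = genes,
               island_category = cats, cross_hybridizing = xhyb)
}

.drawGaps <- function(n, scn) {
  if (n == 0L) return(numeric())
  short <- runif(n) < scn$short_gap_fraction
  g <- numeric(n)
  g[short] <- pmax(scn$min_gap, round(rexp(sum(short),
                                           1 / scn$short_gap_mean)))
  u <- runif(sum(!short))
  g[!short] <- pmin(scn$max_gap,
                    floor(scn$long_gap_scale * u^(-1 / scn$long_gap_exponent)))
  g
}

#' Pick cluster indices eligible for planting effects
#'
#' Deterministically selects `n` distance clusters with at least
#' `min_probes` probes, spread evenly across the genome, to serve as
#' planted DMR/VMR locations.
#'
#' @param manifest manifest `GRanges`.
#' @param n number of regions wanted.
#' @param L clustering distance (bp), default 1000.
#' @param min_probes minimum cluster size, default 3.
#' @return integer vector of cluster indices (into
#'   `clusterProbes(manifest, L)`).
#' @export
selectPlantRegions <- function(manifest, n, L = 1000, min_probes = 3) {
  cl <- clusterProbes(manifest, L)
  ok <- which(cl$n_probes >= min_probes)
  if (length(ok) < n)
    stop("only ", length(ok), " clusters with >= ", min_probes,
         " probes available", call. = FALSE)
  ok[round(seq(1, length(ok), length.out = n))]
}

.clusterAssignment <- function(manifest, clusters) {
  a <- integer(length(manifest))
  for (r in seq_along(clusters)) a[clusters$probe_idx[[r]]] <- r
  a
}

.baseline <- function(scn, manifest, clusters, assign) {
  # cluster-level baseline plus probe deviation: neighbouring probes share
  # methylation state, giving the short-distance correlation the method
  # exploits
  ncl <- length(clusters)
  B <- if (ncl) runif(ncl, 0.25, 0.75) else 0
  b <- ifelse(assign > 0L,
              B[pmax(assign, 1L)] + rnorm(length(manifest), sd = 0.15),
              runif(length(manifest), 0.1, 0.9))
  pmin(pmax(b, 0.05), 0.95)
}

#' Generate an age-series data set with planted DMRs
#'
#' Per-probe baselines are drawn around a shared cluster level (so
#' neighbouring probes correlate); probes in planted clusters drift
#' linearly with age at the planted slope (their baselines are placed away
#' from the \[0,1\] boundaries so the drift is not clipped); noise is
#' Gaussian with a within-cluster shared component of share `cis_cor`.
#' Values are clipped to \[0,1\].
#'
#' @param scn a [simScenario()] with `planted_dmrs` set (or `NULL` for a
#'   pure-null data set).
#' @param manifest manifest `GRanges` (typically from
#'   [generateManifest()]).
#' @param ages numeric vector of sample ages (years).
#' @param seed seed; defaults to the scenario's plus one.
#' @return list with `mset` (a [MethylationSet] whose `colData` has
#'   `age`), and `truth`, a `GRanges` of the planted clusters with their
#'   slopes.
#' @export
generateAgeSeries <- function(scn, manifest, ages, seed = scn$seed + 1L) {
  set.seed(seed)
  ns <- length(ages)
  np <- length(manifest)
  clusters <- clusterProbes(manifest, 1000)
  assign <- .clusterAssignment(manifest, clusters)
  b <- .baseline(scn, manifest, clusters, assign)
  slope <- numeric(np)
  truth <- GRanges()
  pd <- scn$planted_dmrs
  if (!is.null(pd) && nrow(pd)) {
    stopifnot(all(pd$region >= 1 & pd$region <= length(clusters)))
    for (i in seq_len(nrow(pd))) {
      idx <- clusters$probe_idx[[pd$region[i]]]
      slope[idx] <- pd$slope[i]
      b[idx] <- if (pd$slope[i] > 0) runif(length(idx), 0.2, 0.4)
      else runif(length(idx), 0.6, 0.8)
    }
    truth <- granges(clusters[pd$region])
    mcols(truth)$slope <- pd$slope
    names(truth) <- names(clusters)[pd$region]
    extreme <- abs(slope) * max(ages)
    if (any(extreme > 0.55))
      warning("planted slope drives mean methylation near the boundary")
  }
  mu <- outer(b, rep(1, ns)) + outer(slope, ages)
  shared <- matrix(rnorm(max(length(clusters), 1L) * ns), ncol = ns)
  eps <- matrix(rnorm(np * ns), np, ns)
  w <- ifelse(assign > 0L, scn$cis_cor, 0)
  noise <- sqrt(w) * shared[pmax(assign, 1L), , drop = FALSE] +
    sqrt(1 - w) * eps
  y <- pmin(pmax(mu + scn$noise_sd * noise, 0), 1)
  colnames(y) <- sprintf("S%03d", seq_len(ns))
  rownames(y) <- names(manifest)
  pheno <- data.frame(sample_id = colnames(y), age = ages,
                      row.names = colnames(y))
  list(mset = MethylationSet(y, manifest, pheno), truth = truth)
}

#' Generate a grouped data set with planted VMRs
#'
#' Each group gets its own per-probe methylation SD field:
#' `sd = exp(log_sd_mean + s)` where `s` is a stationary AR(1) process of
#' marginal SD `log_sd_scale` and lag-1 coefficient `ar1_rho` along probes
#' within clusters (independent across clusters and for unclustered
#' probes). Clusters listed in `planted_vmrs` get their log-SD raised by
#' `shift * log_sd_scale` in `vmr_group` only. Samples are drawn
#' independently given the SD field around a shared baseline and clipped
#' to \[0,1\].
#'
#' @param scn a [simScenario()] with `planted_vmrs` set (or `NULL`).
#' @param manifest manifest `GRanges`.
#' @param groups named integer vector of group sizes,
#'   e.g. `c(young = 40, old = 40)`.
#' @param vmr_group name of the group receiving the planted variance
#'   inflation; defaults to the last group.
#' @param seed seed; defaults to the scenario's plus two.
#' @return list with `mset` (colData has `group`), `truth` (planted
#'   clusters `GRanges` with shifts), and `group_samples`, a named list of
#'   sample ids per group.
#' @export
generateGroupSeries <- function(scn, manifest, groups = c(young = 40, old = 40),
                                vmr_group = names(groups)[length(groups)],
                                seed = scn$seed + 2L) {
  stopifnot(!is.null(names(groups)), all(groups >= 3))
  set.seed(seed)
  np <- length(manifest)
  clusters <- clusterProbes(manifest, 1000)
  assign <- .clusterAssignment(manifest, clusters)
  b <- .baseline(scn, manifest, clusters, assign)
  is_start <- c(TRUE, assign[-1L] != assign[-np] | assign[-1L] == 0L)
  rho <- scn$ar1_rho
  tau <- scn$log_sd_scale
  innov_sd <- tau * sqrt(1 - rho^2)
  shift <- numeric(np)
  truth <- GRanges()
  pv <- scn$planted_vmrs
  if (!is.null(pv) && nrow(pv)) {
    stopifnot(all(pv$region >= 1 & pv$region <= length(clusters)))
    for (i in seq_len(nrow(pv)))
      shift[clusters$probe_idx[[pv$region[i]]]] <- pv$shift[i]
    truth <- granges(clusters[pv$region])
    mcols(truth)$shift <- pv$shift
    names(truth) <- names(clusters)[pv$region]
  }
  cols <- list()
  grp <- character()
  for (g in names(groups)) {
    e <- rnorm(np, sd = innov_sd)
    e[is_start] <- rnorm(sum(is_start), sd = tau)
    s <- e
    for (i in seq_len(np)[-1L])
      if (!is_start[i]) s[i] <- rho * s[i - 1L] + e[i]
    lsd <- scn$log_sd_mean + s + if (g == vmr_group) shift else 0
    sdv <- pmin(exp(lsd), 0.25)
    y <- b + matrix(rnorm(np * groups[[g]]), np) * sdv
    cols[[g]] <- pmin(pmax(y, 0), 1)
    grp <- c(grp, rep(g, groups[[g]]))
  }
  y <- do.call(cbind, cols)
  colnames(y) <- sprintf("S%03d", seq_len(ncol(y)))
  rownames(y) <- names(manifest)
  pheno <- data.frame(sample_id = colnames(y), group = grp,
                      row.names = colnames(y))
  list(mset = MethylationSet(y, manifest, pheno), truth = truth,
       group_samples = split(colnames(y), grp)[names(groups)])
}
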