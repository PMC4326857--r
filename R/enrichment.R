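#' One-tailed hypergeometric overlap p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' drawing `n` items from a universe of `N` of which `K` are successes.
#' Computed by exact summation of the point masses.
#'
#' @param k observed overlap.
#' @param n draw size (query size).
#' @param K successes in the universe.
#' @param N universe size.
#' @return the one-tailed enrichment p-value.
#' @export
hypergeomP <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    stop("invalid hypergeometric parameters", call. = FALSE)
  if (k == 0) return(1)
  sum(dhyper(k:min(n, K), K, N - K, n))
}

.probesOf <- function(regions) {
  sort(unique(unlist(regions$probe_idx, use.names = FALSE)))
}

.probeInSet <- function(manifest, idx, genes) {
  genes <- toupper(genes)
  vapply(as.list(manifest$genes[idx]),
         function(g) any(toupper(g) %in% genes), TRUE)
}

#' Probe-weighted gene-set enrichment of a region list
#'
#' Tests whether the query regions are enriched for probes annotated to a
#' gene set, against the probe universe of a background region list. The
#' universe is all probes contained in background regions (`N`); successes
#' are those belonging to a set gene (`K`); the draw is the query regions'
#' probes (`n`) with overlap `k`; `p = P(X >= k)` hypergeometric. Counting
#' probes rather than genes weights each gene by its probe representation.
#'
#' @param region_list query region `GRanges` (e.g. significant DMRs).
#' @param gene_set a list with `name` and `genes` (see [readGeneSet()]).
#' @param background background region `GRanges` (e.g. all clusters).
#' @param manifest manifest `GRanges` carrying the `genes` annotation.
#' @return a one-row `data.frame`: `set_name`, `overlap_k`, `draw_n`,
#'   `success_K`, `background_N`, `p`, plus `genes_overlap` (distinct set
#'   genes hit by the query).
#' @export
probeWeightedGeneEnrichment <- function(region_list, gene_set, background,
                                        manifest) {
  bgp <- .probesOf(background)
  qp <- .probesOf(region_list)
  if (length(setdiff(qp, bgp)))
    warning("query contains probes outside the background universe")
  N <- length(bgp)
  inset_bg <- .probeInSet(manifest, bgp, gene_set$genes)
  K <- sum(inset_bg)
  n <- length(qp)
  inset_q <- .probeInSet(manifest, qp, gene_set$genes)
  k <- sum(inset_q)
  if (K == 0) {
    warning("gene set has no probes in the background; p = 1")
    p <- 1
  } else p <- hypergeomP(k, n, K, N)
  hit <- unique(unlist(manifest$genes[qp[inset_q]]))
  hit <- hit[toupper(hit) %in% toupper(gene_set$genes)]
  data.frame(set_name = gene_set$name, overlap_k = k, draw_n = n,
             success_K = K, background_N = N, p = p,
             genes_overlap = length(hit))
}

#' CpG-island category enrichment
#'
#' Per genomic category (island, north/south shore, north/south shelf,
#' open sea), a one-tailed hypergeometric test of the query regions' probe
#' counts against the background probe universe. Categories absent from
#' the background are skipped (reported with `NA`). Benjamini-Hochberg
#' adjusted q-values are added across the tested categories.
#'
#' @inheritParams probeWeightedGeneEnrichment
#' @param categories categories to test, default all six.
#' @return a `data.frame` with one row per category: `category`,
#'   `overlap_k`, `draw_n`, `success_K`, `background_N`, `p`, `q`.
#' @export
categoryEnrichment <- function(region_list, background, manifest,
                               categories = .ISLAND_CATEGORIES) {
  bgp <- .probesOf(background)
  qp <- .probesOf(region_list)
  catv <- as.character(manifest$island_category)
  rows <- lapply(categories, function(cc) {
    K <- sum(catv[bgp] == cc)
    k <- sum(catv[qp] == cc)
    p <- if (K == 0) NA_real_
    else hypergeomP(k, length(qp), K, length(bgp))
    data.frame(category = cc, overlap_k = k, draw_n = length(qp),
               success_K = K, background_N = length(bgp), p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- p.adjust(out$p[tested], "BH")
  out
}

# overlap helper: chromosome naming harmonized ("chr1" == "1") and strand
# ignored
.overlapsAny <- function(query, subject) {
  GenomeInfoDb::seqlevels(query) <-
    .normalizeChrom(GenomeInfoDb::seqlevels(query))
  GenomeInfoDb::seqlevels(subject) <-
    .normalizeChrom(GenomeInfoDb::seqlevels(subject))
  suppressWarnings(
    countOverlaps(query, subject, ignore.strand = TRUE) > 0L)
}

#' Count regions overlapping an interval set
#'
#' Number of query regions overlapping at least one interval by at least
#' 1 bp.
#'
#' @param regions region `GRanges`.
#' @param intervals interval `GRanges` (e.g. DNase hot spots from
#'   [readIntervals()]).
#' @return integer count.
#' @export
intervalOverlapCount <- function(regions, intervals) {
  if (!length(regions) || !length(intervals)) return(0L)
  sum(.overlapsAny(regions, intervals))
}

#' Region-level enrichment in DNase hot spots (or any interval set)
#'
#' Hypergeometric test on region counts: the universe is the background
#' region list (`N`), successes the background regions overlapping a hot
#' spot (`K`), the draw the query list (`n`) with `k` of them overlapping.
#'
#' @inheritParams probeWeightedGeneEnrichment
#' @param hotspots interval `GRanges`.
#' @return one-row `data.frame` with the counts and `p`.
#' @export
dnaseEnrichment <- function(region_list, background, hotspots) {
  N <- length(background)
  K <- intervalOverlapCount(background, hotspots)
  n <- length(region_list)
  k <- intervalOverlapCount(region_list, hotspots)
  data.frame(overlap_k = k, draw_n = n, success_K = K, background_N = N,
             p = hypergeomP(k, n, K, N))
}

#' Empirical significance of a multi-list region overlap
#'
#' For three or more region lists drawn from a common background, the
#' observed size of the common intersection is compared with the null
#' obtained by repeatedly drawing `|list_i|` regions uniformly without
#' replacement from the background and intersecting. With
#' `direction = "greater"` (enrichment, the default) the p-value is the
#' fraction of simulations whose null overlap is at least the observed
#' one; `direction = "literal"` instead counts simulations whose null
#' overlap strictly exceeds it (the depletion-style reading).
#'
#' @param lists list (length >= 2) of region `GRanges`, each a subset of
#'   `background` (matched by region name).
#' @param background background region `GRanges` with names.
#' @param reps number of simulations, default 1e5; fewer than 100 warns.
#' @param seed integer seed.
#' @param direction `"greater"` or `"literal"`.
#' @return list with `observed` overlap size, `p`, `null_mean`.
#' @export
multiListOverlapP <- function(lists, background, reps = 1e5, seed = 1,
                              direction = c("greater", "literal")) {
  direction <- match.arg(direction)
  stopifnot(length(lists) >= 2L)
  if (reps < 100) warning("fewer than 100 repetitions")
  bg_names <- names(background)
  if (is.null(bg_names)) stop("background regions must be named",
                              call. = FALSE)
  idsets <- lapply(lists, function(l) {
    if (is.null(names(l))) stop("region lists must be named", call. = FALSE)
    if (length(setdiff(names(l), bg_names)))
      stop("list contains regions outside the background", call. = FALSE)
    unique(names(l))
  })
  observed <- length(Reduce(intersect, idsets))
  sizes <- lengths(idsets)
  N <- length(bg_names)
  set.seed(seed)
  nulls <- vapply(seq_len(reps), function(r) {
    draws <- lapply(sizes, function(s) sample.int(N, s))
    length(Reduce(intersect, draws))
  }, 0L)
  p <- if (direction == "greater") mean(nulls >= observed)
  else mean(observed < nulls)
  list(observed = observed, p = p, null_mean = mean(nulls))
}
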