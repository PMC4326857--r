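#' Enumerate probe pairs within a genomic window
#'
#' All unordered pairs of manifest probes on the same chromosome whose
#' anchor distance is at most `window` bp, each pair reported once. An
#' optional `tiling` mode instead restricts pairs to fixed, non-overlapping
#' `window`-sized tiles (pairs straddling a tile boundary are then missed;
#' the all-pairs default is recommended).
#'
#' @param manifest probe manifest `GRanges`.
#' @param window maximum pair distance in bp, default 100000.
#' @param tiling if `TRUE`, pair probes only within fixed windows
#'   `[0,window), [window,2*window), ...` per chromosome.
#' @return a `data.frame` with columns `i`, `j` (manifest row indices,
#'   `i < j`), and `distance` (bp).
#' @export
enumeratePairs <- function(manifest, window = 1e5, tiling = FALSE) {
  validateManifest(manifest)
  ch <- as.character(seqnames(manifest))
  pos <- start(manifest)
  out_i <- integer(); out_j <- integer()
  for (c in unique(ch)) {
    idx <- which(ch == c)
    p <- pos[idx]
    if (tiling) {
      tile <- (p - 1) %/% window
      for (t in unique(tile)) {
        k <- idx[tile == t]
        if (length(k) >= 2L) {
          cmb <- .allPairs(k)
          out_i <- c(out_i, cmb$i); out_j <- c(out_j, cmb$j)
        }
      }
    } else {
      # two-pointer sweep over sorted positions
      lo <- 1L
      for (hi in seq_along(p)) {
        while (p[hi] - p[lo] > window) lo <- lo + 1L
        if (hi > lo) {
          out_i <- c(out_i, idx[lo:(hi - 1L)])
          out_j <- c(out_j, rep(idx[hi], hi - lo))
        }
      }
    }
  }
  data.frame(i = out_i, j = out_j, distance = abs(pos[out_j] - pos[out_i]))
}

.allPairs <- function(k) {
  n <- length(k)
  i <- rep(k[-n], times = (n - 1):1)
  j <- k[unlist(lapply(2:n, function(a) a:n))]
  list(i = i, j = j)
}

#' Distance-binned correlation of methylation between probe pairs
#'
#' Pairs are sorted by distance and split into `n_bins` contiguous chunks
#' of near-equal size (sizes differ by at most one, the earlier bins taking
#' the extras); within each bin the Pearson correlation between the two
#' members' methylation values is computed across pairs, the classic
#' cis-correlation decay profile. By default `values` is a single sample's
#' methylation vector (correlation across pairs within one individual); a
#' matrix may be supplied to average per-pair correlations across samples
#' instead (`per_pair = TRUE`).
#'
#' @param pairs `data.frame` from [enumeratePairs()].
#' @param values numeric vector of one sample's methylation aligned to the
#'   manifest, or a probes x samples matrix when `per_pair = TRUE`.
#' @param n_bins number of distance bins, default 50.
#' @param per_pair if `TRUE`, compute each pair's correlation across
#'   samples and report the bin mean of those instead.
#' @return a `data.frame` with columns `median_distance`, `pearson_r`
#'   (`NA` when a bin has zero variance on either coordinate, flagged by
#'   `defined = FALSE`), `n_pairs`, `defined`; one row per bin, ordered by
#'   `median_distance`.
#' @export
binnedCorrelation <- function(pairs, values, n_bins = 50,
                              per_pair = FALSE) {
  stopifnot(nrow(pairs) >= n_bins)
  ord <- order(pairs$distance)
  pairs <- pairs[ord, , drop = FALSE]
  sizes <- .binSizes(nrow(pairs), n_bins)
  bin <- rep(seq_along(sizes), sizes)
  res <- lapply(split(seq_len(nrow(pairs)), bin), function(rows) {
    d <- median(pairs$distance[rows])
    if (per_pair) {
      rs <- vapply(rows, function(r) {
        a <- values[pairs$i[r], ]; b <- values[pairs$j[r], ]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 3L || sd(a[ok]) == 0 || sd(b[ok]) == 0) NA_real_
        else cor(a[ok], b[ok])
      }, 0)
      r <- mean(rs, na.rm = TRUE)
      if (is.nan(r)) r <- NA_real_
    } else {
      a <- values[pairs$i[rows]]; b <- values[pairs$j[rows]]
      ok <- !is.na(a) & !is.na(b)
      r <- if (sum(ok) < 2L || sd(a[ok]) == 0 || sd(b[ok]) == 0) NA_real_
      else cor(a[ok], b[ok])
    }
    data.frame(median_distance = d, pearson_r = r,
               n_pairs = length(rows), defined = !is.na(r))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$median_distance), , drop = FALSE]
}

.binSizes <- function(n, n_bins) {
  stopifnot(n_bins >= 1L, n >= n_bins)
  base <- n %/% n_bins
  extra <- n %% n_bins
  c(rep(base + 1L, extra), rep(base, n_bins - extra))
}
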