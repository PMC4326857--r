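#' Cluster probes into distance-defined regions
#'
#' Groups manifest probes into maximal runs where every adjacent pair on the
#' same chromosome lies within `L` bp (anchor-to-anchor, boundary
#' inclusive: a gap exactly equal to `L` joins). Runs of a single probe are
#' discarded; a region therefore always has at least two probes. With the
#' default `L = 1000` this is the 1-kb rule used to define candidate
#' DMR/VMR territory.
#'
#' @param manifest probe manifest `GRanges` (see [makeManifest()]).
#' @param L distance threshold in bp, `> 0`.
#' @return a `GRanges` of regions ordered by (chrom, start), spanning the
#'   first to last probe anchor, with metadata columns `n_probes`,
#'   `probe_idx` (IntegerList of manifest row indices) and `probe_ids`
#'   (CharacterList). `metadata()` carries `fraction_clustered`, the
#'   fraction of manifest probes contained in regions, and `L`.
#' @export
clusterProbes <- function(manifest, L = 1000) {
  stopifnot(L > 0)
  validateManifest(manifest)
  n <- length(manifest)
  if (n == 0L) {
    out <- GRanges()
    metadata(out)$fraction_clustered <- NA_real_
    metadata(out)$L <- L
    return(out)
  }
  ch <- as.character(seqnames(manifest))
  pos <- start(manifest)
  newrun <- c(TRUE, ch[-1L] != ch[-n] | diff(pos) > L)
  run_id <- cumsum(newrun)
  len <- tabulate(run_id)
  keep <- which(len[run_id] >= 2L)
  if (!length(keep)) {
    out <- GRanges()
    metadata(out)$fraction_clustered <- 0
    metadata(out)$L <- L
    return(out)
  }
  rid <- run_id[keep]
  first <- keep[!duplicated(rid)]
  last <- keep[!duplicated(rid, fromLast = TRUE)]
  out <- GRanges(ch[first], IRanges(start = pos[first], end = pos[last]))
  mcols(out)$n_probes <- len[len >= 2L]
  idx <- unname(split(keep, rid))
  mcols(out)$probe_idx <- IntegerList(idx)
  mcols(out)$probe_ids <- CharacterList(lapply(idx, function(i)
    names(manifest)[i]))
  names(out) <- sprintf("region_%05d", seq_along(out))
  metadata(out)$fraction_clustered <- length(keep) / n
  metadata(out)$L <- L
  out
}

#' Remove regions with too many cross-hybridizing probes
#'
#' Drops every region whose fraction of cross-hybridizing member probes
#' exceeds `max_fraction` (strictly greater than; a region at exactly the
#' threshold is retained, matching the "more than 20%" rule).
#'
#' @param regions region `GRanges` from [clusterProbes()].
#' @param manifest the manifest the regions index into.
#' @param max_fraction maximum tolerated flagged fraction, default 0.2.
#' @return the filtered `GRanges`.
#' @export
filterCrossHybridizing <- function(regions, manifest, max_fraction = 0.2) {
  if (!length(regions)) return(regions)
  flag <- manifest$cross_hybridizing
  frac <- vapply(regions$probe_idx, function(i) mean(flag[i]), 0)
  regions[frac <= max_fraction]
}

#' Clustering coverage as a function of the distance threshold
#'
#' Reruns [clusterProbes()] for each candidate `L` and tabulates the number
#' of regions and of clustered probes, the trade-off used to pick the
#' distance threshold.
#'
#' @param manifest probe manifest `GRanges`.
#' @param L_values numeric vector of thresholds (bp).
#' @return a `data.frame` with columns `L`, `n_regions`,
#'   `n_clustered_probes`, `fraction_clustered`.
#' @export
sweepL <- function(manifest, L_values) {
  stopifnot(length(L_values) > 0)
  rows <- lapply(L_values, function(L) {
    cl <- clusterProbes(manifest, L)
    data.frame(L = L, n_regions = length(cl),
               n_clustered_probes = if (length(cl))
                 sum(cl$n_probes) else 0L,
               fraction_clustered =
                 if (length(manifest))
                   (if (length(cl)) sum(cl$n_probes) else 0L) /
                     length(manifest)
                 else NA_real_)
  })
  do.call(rbind, rows)
}
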