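#' SNP-free status of probes
#'
#' A probe is SNP free when no common SNP (minor allele frequency strictly
#' above `maf_cut`) lies within the probe body or its flanks. The probe
#' body is taken to extend `probe_len` bp from the anchor (strand is
#' ignored) and the window adds `flank` bp beyond each end: in 1-based
#' closed coordinates, `[pos - flank, pos + probe_len - 1 + flank]`, a
#' 250-bp window at the defaults.
#'
#' @param manifest probe manifest `GRanges` (anchors), or any width-1
#'   `GRanges`.
#' @param snps `GRanges` of SNP positions with a `maf` metadata column.
#' @param maf_cut MAF threshold (strict `>`), default 0.05.
#' @param probe_len probe length in bp, default 50.
#' @param flank flanking width in bp on each side, default 100.
#' @return logical vector, one element per probe.
#' @export
probeSnpFree <- function(manifest, snps, maf_cut = 0.05, probe_len = 50,
                         flank = 100) {
  if (length(snps)) {
    if (is.null(snps$maf)) stop("snps need a 'maf' column", call. = FALSE)
    snps <- snps[snps$maf > maf_cut]
  }
  if (!length(snps)) return(rep(TRUE, length(manifest)))
  win <- GRanges(seqnames(manifest),
                 IRanges(start = start(manifest) - flank,
                         end = start(manifest) + probe_len - 1L + flank))
  !.overlapsAny(win, granges(snps))
}

#' SNP-free status of regions
#'
#' A region is SNP free iff every member probe is SNP free.
#'
#' @param regions region `GRanges` with a `probe_idx` column indexing
#'   `manifest`.
#' @param manifest probe manifest `GRanges`.
#' @inheritParams probeSnpFree
#' @return logical vector, one element per region.
#' @export
regionSnpFree <- function(regions, manifest, snps, maf_cut = 0.05,
                          probe_len = 50, flank = 100) {
  free <- probeSnpFree(manifest, snps, maf_cut, probe_len, flank)
  vapply(regions$probe_idx, function(i) all(free[i]), TRUE)
}

#' SNP-free fraction per region list
#'
#' @param region_lists named list of region `GRanges`.
#' @param manifest probe manifest `GRanges`.
#' @inheritParams probeSnpFree
#' @return `data.frame` with `list_name`, `n_free`, `n_total`,
#'   `fraction_pct` (percent, one decimal; `NA` for an empty list).
#' @export
snpFreeFraction <- function(region_lists, manifest, snps, maf_cut = 0.05,
                            probe_len = 50, flank = 100) {
  rows <- lapply(names(region_lists), function(nm) {
    rl <- region_lists[[nm]]
    n <- length(rl)
    nf <- if (n) sum(regionSnpFree(rl, manifest, snps, maf_cut,
                                   probe_len, flank)) else 0L
    data.frame(list_name = nm, n_free = nf, n_total = n,
               fraction_pct = if (n) round(100 * nf / n, 1) else NA_real_)
  })
  do.call(rbind, rows)
}
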