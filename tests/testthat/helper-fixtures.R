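suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
  library(SummarizedExperiment)
})

toyManifest <- function(pos = c(100, 600, 1500, 4000, 4500),
                        chrom = "chr1", ...) {
  makeManifest(sprintf("cg%03d", seq_along(pos)), chrom, pos, ...)
}

# a scored candidate GRanges built directly (bypassing detection)
makeCandidate <- function(pos, stats, chrom = "chr1",
                          direction = "hyper") {
  gr <- GRanges(chrom, IRanges(min(pos), max(pos)))
  mcols(gr)$n_probes <- length(pos)
  mcols(gr)$probe_idx <- IRanges::IntegerList(list(seq_along(pos)))
  mcols(gr)$probe_ids <- IRanges::CharacterList(
    list(sprintf("cg%03d", seq_along(pos))))
  mcols(gr)$direction <- direction
  mcols(gr)$member_stats <- IRanges::NumericList(list(stats))
  mcols(gr)$member_pos <- IRanges::NumericList(list(pos))
  mcols(gr)$cluster <- "region_00001"
  names(gr) <- "cand_00001"
  gr
}

# small MethylationSet with given beta matrix on a toy manifest
toyMSet <- function(beta, ages = NULL, groups = NULL) {
  n <- nrow(beta)
  m <- toyManifest(pos = seq(100, by = 400, length.out = n))
  rownames(beta) <- names(m)
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("S%02d", seq_len(ncol(beta)))
  pheno <- data.frame(sample_id = colnames(beta),
                      row.names = colnames(beta))
  if (!is.null(ages)) pheno$age <- ages
  if (!is.null(groups)) pheno$group <- groups
  MethylationSet(beta, m, pheno)
}
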