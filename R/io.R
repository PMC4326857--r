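#' Validate a probe manifest
#'
#' Checks the `GRanges` contract used throughout the package: unique probe
#' ids as names, width-1 anchor ranges, strictly increasing positions within
#' each chromosome, and the `genes` / `island_category` /
#' `cross_hybridizing` metadata columns.
#'
#' @param manifest a `GRanges` of probe anchors.
#' @param stop.on.error if `TRUE` (default) problems raise an error;
#'   otherwise a character vector of problems (or `TRUE`) is returned.
#' @return `TRUE` invisibly, or the problem messages.
#' @export
validateManifest <- function(manifest, stop.on.error = TRUE) {
  msg <- character()
  if (!is(manifest, "GRanges")) {
    msg <- "manifest must be a GRanges"
  } else {
    if (is.null(names(manifest)) || anyDuplicated(names(manifest)))
      msg <- c(msg, "probe ids (names) must be present and unique")
    if (length(manifest) && any(width(manifest) != 1L))
      msg <- c(msg, "probe anchors must be width-1 ranges")
    need <- c("genes", "island_category", "cross_hybridizing")
    miss <- setdiff(need, colnames(mcols(manifest)))
    if (length(miss))
      msg <- c(msg, paste("missing manifest column(s):",
                          paste(miss, collapse = ", ")))
    if ("island_category" %in% colnames(mcols(manifest))) {
      bad <- setdiff(unique(as.character(manifest$island_category)),
                     .ISLAND_CATEGORIES)
      if (length(bad))
        msg <- c(msg, paste("unknown island_category:",
                            paste(bad, collapse = ", ")))
    }
    if (length(manifest) > 1L) {
      ch <- as.character(seqnames(manifest))
      pos <- start(manifest)
      same <- ch[-1L] == ch[-length(ch)]
      if (any(same & diff(pos) <= 0))
        msg <- c(msg, "positions must strictly increase within chromosome")
      # chromosome blocks must be contiguous
      if (anyDuplicated(rle(ch)$values))
        msg <- c(msg, "chromosome blocks must be contiguous")
    }
  }
  if (length(msg)) {
    if (stop.on.error) stop(paste(msg, collapse = "; "), call. = FALSE)
    return(msg)
  }
  invisible(TRUE)
}

.normalizeChrom <- function(x) sub("^chr", "", as.character(x))

.normalizeIslandCategory <- function(x) {
  x <- tolower(trimws(as.character(x)))
  map <- c(island = "island", n_shore = "n_shore", s_shore = "s_shore",
           n_shelf = "n_shelf", s_shelf = "s_shelf", open_sea = "open_sea",
           opensea = "open_sea", nshore = "n_shore",
           sshore = "s_shore", nshelf = "n_shelf", sshelf = "s_shelf")
  x[x == ""] <- "open_sea"
  out <- unname(map[x])
  if (anyNA(out))
    stop("unrecognized island category value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Build a probe manifest GRanges
#'
#' @param probe_id character probe ids (unique).
#' @param chrom chromosome labels; a leading `"chr"` is stripped so that
#'   `"chr1"` and `"1"` name the same chromosome.
#' @param pos 1-based probe anchor coordinate (the annotated interrogation
#'   position, e.g. Illumina MAPINFO).
#' @param genes character vector of `;`-separated gene symbols, or a
#'   `CharacterList`; empty means intergenic. Symbols are upper-cased.
#' @param island_category CpG-island relation, one of the six genomic
#'   categories `island`, `n_shore`, `s_shore`, `n_shelf`, `s_shelf`,
#'   `open_sea` (Illumina-style labels are normalized).
#' @param cross_hybridizing logical flag per probe.
#' @return a sorted, validated manifest `GRanges`.
#' @export
makeManifest <- function(probe_id, chrom, pos, genes = "",
                         island_category = "open_sea",
                         cross_hybridizing = FALSE) {
  n <- length(probe_id)
  if (anyDuplicated(probe_id))
    stop("duplicate probe ids in manifest", call. = FALSE)
  pos <- suppressWarnings(as.numeric(pos))
  if (anyNA(pos)) stop("non-numeric probe position", call. = FALSE)
  if (!is(genes, "CharacterList")) {
    genes <- rep_len(as.character(genes), n)
    genes <- CharacterList(lapply(strsplit(toupper(genes), ";"),
                                  function(g) unique(g[nzchar(trimws(g))])))
  }
  gr <- GRanges(.normalizeChrom(rep_len(chrom, n)),
                IRanges(start = pos, width = 1L))
  names(gr) <- probe_id
  mcols(gr)$genes <- genes
  mcols(gr)$island_category <-
    .normalizeIslandCategory(rep_len(island_category, n))
  mcols(gr)$cross_hybridizing <- rep_len(as.logical(cross_hybridizing), n)
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  validateManifest(gr)
  gr
}

#' Read a probe manifest from a delimited file
#'
#' @param path path to a TSV/CSV file.
#' @param columns named character vector mapping manifest fields to file
#'   column names; fields `probe_id`, `chrom`, `pos` are required, `genes`,
#'   `island_category`, `cross_hybridizing` optional.
#' @param sep field separator, default tab.
#' @return a sorted manifest `GRanges` (see [makeManifest()]).
#' @export
readManifest <- function(path,
                         columns = c(probe_id = "probe_id", chrom = "chrom",
                                     pos = "pos", genes = "genes",
                                     island_category = "island_category",
                                     cross_hybridizing = "cross_hybridizing"),
                         sep = "\t") {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("probe_id", "chrom", "pos")
  for (f in need)
    if (!columns[[f]] %in% colnames(df))
      stop("manifest file lacks required column '", columns[[f]],
           "' (field ", f, ")", call. = FALSE)
  getcol <- function(f, default) {
    cn <- if (f %in% names(columns)) columns[[f]] else NA_character_
    if (!is.na(cn) && cn %in% colnames(df)) df[[cn]] else default
  }
  makeManifest(probe_id = as.character(df[[columns[["probe_id"]]]]),
               chrom = df[[columns[["chrom"]]]],
               pos = df[[columns[["pos"]]]],
               genes = getcol("genes", ""),
               island_category = getcol("island_category", "open_sea"),
               cross_hybridizing = getcol("cross_hybridizing", FALSE))
}

#' Construct a MethylationSet
#'
#' @param beta numeric matrix of fractional methylation, probes x samples;
#'   rownames are probe ids, colnames sample ids. `NA` marks missing.
#' @param manifest probe manifest `GRanges`; `beta` rows are reordered to
#'   manifest order and probes absent from the manifest are dropped (with a
#'   message giving the count).
#' @param pheno optional `data.frame` of phenotypes with rownames (or a
#'   `sample_id` column) matching the matrix columns; an `age` column must
#'   be non-negative.
#' @return a [MethylationSet].
#' @export
MethylationSet <- function(beta, manifest, pheno = NULL) {
  validateManifest(manifest)
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    stop("beta matrix needs probe ids as rownames", call. = FALSE)
  if (anyDuplicated(colnames(beta)))
    stop("sample id collision in beta matrix columns", call. = FALSE)
  keep <- rownames(beta) %in% names(manifest)
  if (any(!keep)) {
    message(sum(!keep), " probe(s) absent from manifest dropped")
    beta <- beta[keep, , drop = FALSE]
  }
  miss <- setdiff(names(manifest), rownames(beta))
  if (length(miss))
    stop(length(miss), " manifest probe(s) missing from matrix", call. = FALSE)
  beta <- beta[names(manifest), , drop = FALSE]
  bad <- !is.na(beta) & (beta < -1e-9 | beta > 1 + 1e-9)
  if (any(bad))
    stop(sum(bad), " beta value(s) outside [0,1]", call. = FALSE)
  if (is.null(pheno)) {
    pheno <- DataFrame(row.names = colnames(beta))
  } else {
    pheno <- as(pheno, "DataFrame")
    if ("sample_id" %in% colnames(pheno) && is.null(rownames(pheno)))
      rownames(pheno) <- pheno$sample_id
    if (!setequal(rownames(pheno), colnames(beta)))
      stop("phenotype sample ids do not match matrix columns", call. = FALSE)
    pheno <- pheno[colnames(beta), , drop = FALSE]
    if ("age" %in% colnames(pheno) && any(pheno$age < 0, na.rm = TRUE))
      stop("ages must be non-negative", call. = FALSE)
  }
  se <- SummarizedExperiment(assays = list(beta = beta),
                             rowRanges = manifest, colData = pheno)
  new("MethylationSet", se)
}

#' Read a methylation matrix into a MethylationSet
#'
#' First column holds probe ids, remaining columns one sample each. Cells
#' `NA`/empty are recorded as missing, never as zero.
#'
#' @inheritParams MethylationSet
#' @param path path to the delimited matrix file.
#' @param sep field separator.
#' @return a [MethylationSet]; the number of probes dropped for not being in
#'   the manifest is reported via `message()`.
#' @export
readBetaMatrix <- function(path, manifest, pheno = NULL, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(colnames(df)[-1L]))
    stop("sample id collision in matrix header", call. = FALSE)
  beta <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(beta)) {
    beta <- suppressWarnings(apply(df[, -1L, drop = FALSE], 2, as.numeric))
    nonnum <- is.na(beta) &
      !(is.na(df[, -1L, drop = FALSE]) |
          toupper(trimws(as.matrix(df[, -1L, drop = FALSE]))) %in%
          c("NA", "NAN", ""))
    if (any(nonnum)) stop("non-numeric methylation value(s)", call. = FALSE)
  }
  rownames(beta) <- as.character(df[[1L]])
  MethylationSet(beta, manifest, pheno)
}

#' Read a phenotype table
#'
#' @param path delimited file with a sample id column plus `age` and/or
#'   `group` (and arbitrary covariate columns).
#' @param sample_col name of the sample id column.
#' @param sep field separator.
#' @return a `data.frame` with sample ids as rownames.
#' @export
readPhenotype <- function(path, sample_col = "sample_id", sep = "\t") {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!sample_col %in% colnames(df))
    stop("phenotype file lacks column '", sample_col, "'", call. = FALSE)
  if (anyDuplicated(df[[sample_col]]))
    stop("duplicate sample ids in phenotype table", call. = FALSE)
  rownames(df) <- as.character(df[[sample_col]])
  if ("age" %in% colnames(df) && any(df$age < 0, na.rm = TRUE))
    stop("ages must be non-negative", call. = FALSE)
  df
}

#' Read genomic intervals (BED or TSV) as GRanges
#'
#' BED input (0-based half-open) is converted to the 1-based closed
#' convention of `GRanges`; a `maf` or `score` column is kept when present.
#' TSV input must carry `chrom` and either `start`/`end` (0-based half-open)
#' or `pos` (1-based point), plus optional `maf`.
#'
#' @param path interval file; `.bed` is parsed with `rtracklayer`.
#' @param sep separator for TSV input.
#' @return a `GRanges` sorted within chromosome.
#' @export
readIntervals <- function(path, sep = "\t") {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to read BED files", call. = FALSE)
    gr <- rtracklayer::import(path, format = "BED")
    GenomeInfoDb::seqlevels(gr) <- .normalizeChrom(GenomeInfoDb::seqlevels(gr))
  } else {
    df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
    if (!"chrom" %in% colnames(df))
      stop("interval file lacks 'chrom' column", call. = FALSE)
    if (all(c("start", "end") %in% colnames(df))) {
      if (any(df$start >= df$end))
        stop("intervals must satisfy start < end", call. = FALSE)
      gr <- GRanges(.normalizeChrom(df$chrom),
                    IRanges(start = df$start + 1L, end = df$end))
    } else if ("pos" %in% colnames(df)) {
      gr <- GRanges(.normalizeChrom(df$chrom),
                    IRanges(start = df$pos, width = 1L))
    } else stop("interval file needs start/end or pos", call. = FALSE)
    if ("maf" %in% colnames(df)) mcols(gr)$maf <- df$maf
    if ("score" %in% colnames(df)) mcols(gr)$score <- df$score
  }
  gr[order(as.character(seqnames(gr)), start(gr))]
}

#' Read a plain-text gene set (one symbol per line)
#'
#' @param path text file, one gene symbol per line; blanks skipped.
#' @param name set name; defaults to the file name.
#' @return a list with elements `name` and `genes` (unique, upper-cased).
#' @export
readGeneSet <- function(path, name = basename(path)) {
  g <- toupper(trimws(readLines(path, warn = FALSE)))
  g <- unique(g[nzchar(g)])
  if (!length(g)) stop("gene set is empty: ", path, call. = FALSE)
  list(name = name, genes = g)
}

#' Write a scored region table (TSV + BED6)
#'
#' Writes a TSV with columns chrom, start, end (1-based closed span from the
#' first to the last probe anchor), n_probes, probe_ids, area, direction, p,
#' q, and a companion BED6 file (`<path minus .tsv>.bed`) whose score is
#' `min(1000, round(-10 log10(max(p, 1e-100))))`.
#'
#' @param regions scored region `GRanges` (with `area`, `direction`, `p`,
#'   `q`, `n_probes`, `probe_ids` metadata).
#' @param path output TSV path.
#' @return invisibly, the two paths written.
#' @export
writeRegionTable <- function(regions, path) {
  need <- c("n_probes", "probe_ids", "area", "direction", "p", "q")
  miss <- setdiff(need, colnames(mcols(regions)))
  if (length(miss))
    stop("regions are not scored: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(regions) && anyNA(regions$p))
    stop("regions are not scored: p contains NA", call. = FALSE)
  ids <- if (is.null(names(regions)) && length(regions))
    sprintf("region_%05d", seq_along(regions)) else names(regions)
  df <- data.frame(
    region_id = ids,
    chrom = as.character(seqnames(regions)),
    start = start(regions),
    end = end(regions),
    n_probes = regions$n_probes,
    probe_ids = vapply(regions$probe_ids, paste, "", collapse = ","),
    area = format(regions$area, digits = 15, trim = TRUE,
                  scientific = FALSE),
    direction = as.character(regions$direction),
    p = format(regions$p, digits = 15, trim = TRUE),
    q = format(regions$q, digits = 15, trim = TRUE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_path <- paste0(sub("\\.tsv$", "", path), ".bed")
  score <- if (length(regions))
    pmin(1000, round(-10 * log10(pmax(regions$p, 1e-100)))) else integer()
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = df$region_id, score = score,
                    strand = rep(".", length(regions)))
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(tsv = path, bed = bed_path))
}

#' Read back a region table written by [writeRegionTable()]
#'
#' @param path TSV path.
#' @return a `GRanges` with the scored-region metadata columns.
#' @export
readRegionTable <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(probe_ids = "character"))
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  names(gr) <- df$region_id
  mcols(gr)$n_probes <- as.integer(df$n_probes)
  mcols(gr)$probe_ids <- CharacterList(strsplit(df$probe_ids, ","))
  mcols(gr)$area <- as.numeric(df$area)
  mcols(gr)$direction <- df$direction
  mcols(gr)$p <- as.numeric(df$p)
  mcols(gr)$q <- as.numeric(df$q)
  gr
}
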