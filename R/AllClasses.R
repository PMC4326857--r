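#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame Rle
#' @importFrom IRanges IRanges IntegerList CharacterList NumericList
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#'   countOverlaps findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData
#' @importFrom stats quantile median sd cor filter rnorm runif rexp rbinom
#'   pnorm qnorm dhyper p.adjust lm coef complete.cases setNames
#' @importFrom utils read.delim write.table head tail
NULL

.ISLAND_CATEGORIES <- c("island", "n_shore", "s_shore", "n_shelf", "s_shelf",
                        "open_sea")

#' Probe-level methylation container
#'
#' `MethylationSet` couples a fractional-methylation matrix (probes x
#' samples, values in \[0,1\], `NA` allowed) with a probe manifest held as
#' the `rowRanges` and a phenotype table held as the `colData`. It extends
#' [SummarizedExperiment::RangedSummarizedExperiment] so all the usual
#' subsetting and accessor machinery applies.
#'
#' The manifest `GRanges` carries one anchor position per probe (width-1
#' ranges at the annotated probe coordinate) with metadata columns
#' `genes` (a `CharacterList` of gene symbols, possibly empty),
#' `island_category` (one of island, n_shore, s_shore, n_shelf, s_shelf,
#' open_sea) and `cross_hybridizing` (logical). Probe ids are the range
#' names and must be unique; within each chromosome positions strictly
#' increase.
#'
#' @slot .. inherits all slots from `RangedSummarizedExperiment`; the single
#'   assay is named `"beta"`.
#' @seealso [MethylationSet()], [readManifest()], [readBetaMatrix()]
#' @export
setClass("MethylationSet",
         contains = "RangedSummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    bad <- !is.na(b) & (b < -1e-9 | b > 1 + 1e-9)
    if (any(bad))
      msg <- c(msg, sprintf("%d beta values outside [0,1]", sum(bad)))
    if (any(!is.na(b) & !is.finite(b)))
      msg <- c(msg, "non-finite beta values present")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids are not unique")
  mm <- validateManifest(rowRanges(object), stop.on.error = FALSE)
  if (!isTRUE(mm)) msg <- c(msg, mm)
  if (length(msg)) msg else TRUE
})

#' First-order autoregressive parameters
#'
#' Holds the lag-1 coefficient `rho` and the innovation standard deviation
#' `sigma` of an AR(1) process, as estimated by [fitAR1Burg()] or pooled
#' across regions by [poolAR1()].
#'
#' @slot rho numeric(1), in (-1, 1).
#' @slot sigma numeric(1), positive innovation standard deviation.
#' @slot n integer(1), number of series (regions) the estimate is based on.
#' @export
setClass("AR1Params",
         representation(rho = "numeric", sigma = "numeric", n = "integer"),
         prototype(rho = 0, sigma = 1, n = 1L))

setValidity("AR1Params", function(object) {
  msg <- character()
  if (length(object@rho) != 1L || !is.finite(object@rho) ||
      abs(object@rho) >= 1)
    msg <- c(msg, "rho must be a single finite value with |rho| < 1")
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive finite value")
  if (length(msg)) msg else TRUE
})

#' @describeIn AR1Params constructor.
#' @param rho,sigma,n see slot descriptions.
#' @export
AR1Params <- function(rho, sigma, n = 1L)
  new("AR1Params", rho = as.numeric(rho), sigma = as.numeric(sigma),
      n = as.integer(n))

setMethod("show", "AR1Params", function(object) {
  cat(sprintf("AR1Params: rho = %.4f, sigma = %.4f (pooled over %d series)\n",
              object@rho, object@sigma, object@n))
})

#' @describeIn AR1Params accessor for the lag-1 coefficient.
#' @param x an `AR1Params` object.
#' @export
arRho <- function(x) x@rho

#' @describeIn AR1Params accessor for the innovation standard deviation.
#' @export
arSigma <- function(x) x@sigma

#' Percentile thresholds on a per-probe statistic
#'
#' `q1` is the upper cut (95th percentile of the positive statistics by
#' default) and `q2` the lower cut (5th percentile of the negatives). In MAD
#' mode only `q1` is defined and `q2` is `NA`.
#'
#' @slot q1 numeric(1) upper cut.
#' @slot q2 numeric(1) lower cut, `NA` in MAD mode.
#' @export
setClass("StatThresholds",
         representation(q1 = "numeric", q2 = "numeric"),
         prototype(q1 = NA_real_, q2 = NA_real_))

setValidity("StatThresholds", function(object) {
  msg <- character()
  if (length(object@q1) != 1L || !is.finite(object@q1))
    msg <- c(msg, "q1 must be a single finite value")
  if (length(object@q2) != 1L)
    msg <- c(msg, "q2 must have length 1")
  if (!is.na(object@q2)) {
    if (!(object@q1 > 0)) msg <- c(msg, "q1 must be > 0 when q2 is set")
    if (!(object@q2 < 0)) msg <- c(msg, "q2 must be < 0 when set")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn StatThresholds constructor.
#' @param q1,q2 see slot descriptions.
#' @export
StatThresholds <- function(q1, q2 = NA_real_)
  new("StatThresholds", q1 = as.numeric(q1), q2 = as.numeric(q2))

setMethod("show", "StatThresholds", function(object) {
  if (is.na(object@q2))
    cat(sprintf("StatThresholds: q1 = %.6g (MAD mode)\n", object@q1))
  else
    cat(sprintf("StatThresholds: q1 = %.6g, q2 = %.6g\n",
                object@q1, object@q2))
})

#' Pooled null distribution of region areas
#'
#' Areas of regions found under the null (phenotype permutation for DMRs,
#' AR(1) parametric bootstrap for VMRs), pooled across all simulations
#' together with the per-simulation counts.
#'
#' @slot areas numeric, all null areas pooled.
#' @slot n_per_sim integer, number of null areas contributed by each
#'   simulation; `sum(n_per_sim) == length(areas)`.
#' @export
setClass("NullAreaDistribution",
         representation(areas = "numeric", n_per_sim = "integer"))

setValidity("NullAreaDistribution", function(object) {
  msg <- character()
  if (any(!is.finite(object@areas)) || any(object@areas < 0))
    msg <- c(msg, "all null areas must be finite and >= 0")
  if (sum(object@n_per_sim) != length(object@areas))
    msg <- c(msg, "per-simulation counts do not sum to the pooled size")
  if (length(msg)) msg else TRUE
})

#' @describeIn NullAreaDistribution constructor.
#' @param areas,n_per_sim see slot descriptions.
#' @export
NullAreaDistribution <- function(areas, n_per_sim)
  new("NullAreaDistribution", areas = as.numeric(areas),
      n_per_sim = as.integer(n_per_sim))

setMethod("show", "NullAreaDistribution", function(object) {
  cat(sprintf(
    "NullAreaDistribution: %d areas from %d simulations (mean %.4g)\n",
    length(object@areas), length(object@n_per_sim),
    if (length(object@areas)) mean(object@areas) else NA_real_))
})

#' @describeIn NullAreaDistribution accessor for the pooled areas.
#' @param x a `NullAreaDistribution`.
#' @export
nullAreas <- function(x) x@areas

#' @describeIn NullAreaDistribution number of simulations pooled.
#' @export
nSimulations <- function(x) length(x@n_per_sim)

#' Result of a region-level scan
#'
#' Returned by [runDMRPipeline()] and [runVMRPipeline()]. `regions` holds
#' every scored candidate (with `area`, `direction`, `p`, `q` metadata
#' columns); `significant` is the subset passing the FDR cut.
#'
#' @slot regions GRanges of all scored candidate regions.
#' @slot significant GRanges, the `q < fdr_cut` subset.
#' @slot null the [NullAreaDistribution] used for the empirical p-values.
#' @slot thresholds the [StatThresholds] applied.
#' @slot params list of run parameters (L, K, fdr_cut, seed, ...).
#' @export
setClass("RegionScanResult",
         representation(regions = "GRanges", significant = "GRanges",
                        null = "NullAreaDistribution",
                        thresholds = "StatThresholds", params = "list"))

setMethod("show", "RegionScanResult", function(object) {
  dirs <- table(factor(object@significant$direction,
                       levels = c("hyper", "hypo", "variable")))
  cat(sprintf("RegionScanResult: %d candidate regions, %d significant (q < %g)\n",
              length(object@regions), length(object@significant),
              object@params$fdr_cut))
  cat(sprintf("  hyper: %d  hypo: %d  variable: %d\n",
              dirs[["hyper"]], dirs[["hypo"]], dirs[["variable"]]))
})

#' @describeIn RegionScanResult all scored candidate regions.
#' @param x a `RegionScanResult`.
#' @export
scannedRegions <- function(x) x@regions

#' @describeIn RegionScanResult the significant subset.
#' @export
significantRegions <- function(x) x@significant

#' @describeIn RegionScanResult the pooled null area distribution.
#' @export
nullDistribution <- function(x) x@null

#' @describeIn RegionScanResult the thresholds used for candidate calling.
#' @export
scanThresholds <- function(x) x@thresholds

#' @describeIn RegionScanResult the run parameter list.
#' @export
scanParams <- function(x) x@params
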