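#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom stats median quantile rnorm runif rbeta rpois rmultinom optim
#'   prcomp rank sd IQR cor setNames predict coef
#' @importFrom utils read.table write.table head
NULL

#' Parameters of the HOT-region caller
#'
#' Bundles the tunable constants of summit-density HOT-region calling:
#' the sliding-window width, the window step, the local-maximum
#' suppression span, and the percentile cut-offs used to label regions
#' and to bound the control pool.
#'
#' @slot windowSize integer(1). Width in bp of the sliding windows over
#'   which pooled peak summits are counted (default 500).
#' @slot step integer(1). Distance in bp between consecutive window
#'   starts (default 50, i.e. 10x oversampling of the window width).
#' @slot suppressionSpan integer(1). Total width in bp of the
#'   suppression neighbourhood around a retained local maximum: a kept
#'   window must dominate every window whose start lies within
#'   +/- \code{suppressionSpan/2} of its own (default 2000, the human
#'   setting; 1000 suits smaller genomes with fewer experiments).
#' @slot hotPercentile numeric(1). Occupancy percentile above which a
#'   region is labelled HOT (default 99; 99.5 is used for human model
#'   training).
#' @slot mildPercentile numeric(1). Lower edge of the MILD band:
#'   regions with percentile above this value but not HOT are MILD,
#'   the rest COLD (default 75).
#' @slot controlCeiling numeric(1). Occupancy percentile below which
#'   regions are eligible as model controls (default 85).
#'
#' @examples
#' HotCallerParam()
#' HotCallerParam(suppressionSpan = 1000)
#' @name HotCallerParam-class
#' @rdname HotCallerParam
#' @exportClass HotCallerParam
setClass("HotCallerParam",
    representation(
        windowSize = "integer",
        step = "integer",
        suppressionSpan = "integer",
        hotPercentile = "numeric",
        mildPercentile = "numeric",
        controlCeiling = "numeric"
    )
)

setValidity("HotCallerParam", function(object) {
    msg <- character()
    if (object@windowSize < 1L)
        msg <- c(msg, "windowSize must be >= 1")
    if (object@step < 1L)
        msg <- c(msg, "step must be >= 1")
    if (object@suppressionSpan < object@windowSize)
        msg <- c(msg, "suppressionSpan must be >= windowSize")
    if (object@hotPercentile <= 0 || object@hotPercentile >= 100)
        msg <- c(msg, "hotPercentile must lie in (0, 100)")
    if (object@mildPercentile < 0 || object@mildPercentile >= object@hotPercentile)
        msg <- c(msg, "mildPercentile must lie in [0, hotPercentile)")
    if (object@controlCeiling <= 0 || object@controlCeiling > 100)
        msg <- c(msg, "controlCeiling must lie in (0, 100]")
    if (length(msg)) msg else TRUE
})

#' @param windowSize,step,suppressionSpan,hotPercentile,mildPercentile,controlCeiling
#'   See the slot documentation.
#' @return \code{HotCallerParam()} returns a validated parameter object.
#' @rdname HotCallerParam
#' @export
HotCallerParam <- function(windowSize = 500, step = 50,
                           suppressionSpan = 2000, hotPercentile = 99,
                           mildPercentile = 75, controlCeiling = 85) {
    new("HotCallerParam",
        windowSize = as.integer(windowSize),
        step = as.integer(step),
        suppressionSpan = as.integer(suppressionSpan),
        hotPercentile = as.numeric(hotPercentile),
        mildPercentile = as.numeric(mildPercentile),
        controlCeiling = as.numeric(controlCeiling))
}

setMethod("show", "HotCallerParam", function(object) {
    cat("HotCallerParam\n")
    cat(sprintf("  windowSize: %d bp   step: %d bp   suppressionSpan: %d bp\n",
        object@windowSize, object@step, object@suppressionSpan))
    cat(sprintf("  hotPercentile: %g   mildPercentile: %g   controlCeiling: %g\n",
        object@hotPercentile, object@mildPercentile, object@controlCeiling))
})

#' Called occupancy regions
#'
#' The result of HOT-region calling: one genomic window per retained
#' local maximum of the pooled summit density, annotated with its
#' occupancy (summit count), its mean-rank occupancy percentile over
#' all retained regions, and its HOT/MILD/COLD label.
#'
#' @slot ranges a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{occupancy} (integer), \code{percentile} (numeric in
#'   [0, 100]) and \code{label} (factor with levels COLD, MILD, HOT),
#'   sorted by (chromosome, start).
#' @slot param the \linkS4class{HotCallerParam} used for the call.
#'
#' @seealso \code{\link{callHotRegions}}, \code{\link{occupancy}},
#'   \code{\link{percentileRank}}, \code{\link{regionLabel}},
#'   \code{\link{binByPercentile}}
#' @name OccupancyRegions-class
#' @rdname OccupancyRegions-class
#' @exportClass OccupancyRegions
setClass("OccupancyRegions",
    representation(ranges = "GRanges", param = "HotCallerParam")
)

setValidity("OccupancyRegions", function(object) {
    mc <- S4Vectors::mcols(object@ranges)
    need <- c("occupancy", "percentile", "label")
    if (!all(need %in% colnames(mc)))
        return(sprintf("ranges must carry metadata columns %s",
                       paste(need, collapse = ", ")))
    if (length(object@ranges)) {
        if (any(mc$occupancy < 1L))
            return("occupancy must be >= 1 for every region")
        if (any(mc$percentile < 0 | mc$percentile > 100))
            return("percentile must lie in [0, 100]")
        if (!all(levels(mc$label) == c("COLD", "MILD", "HOT")))
            return("label must be a factor with levels COLD, MILD, HOT")
    }
    TRUE
})

#' Per-region sequence feature matrix
#'
#' Rows are regions, columns the 339 named sequence features used by
#' the HOT-region discriminators: all 2-, 3- and 4-mer frequencies
#' (16 + 64 + 256), plus \code{cpg_freq} (GC content of the window),
#' \code{cpg_oe} (observed/expected CpG) and \code{gc_skew}.
#'
#' @slot features numeric matrix, one row per region, named columns.
#' @slot regions \link[GenomicRanges]{GRanges} of the windows the rows
#'   were computed on (same order as the rows).
#' @slot standardized logical(1); \code{TRUE} after
#'   \code{\link{standardizeFeatureMatrix}} (columns have mean 0 and
#'   unit population variance, zero-variance columns left at 0).
#' @slot zeroVariance character vector of column names that had zero
#'   variance at standardization time (empty before standardization).
#'
#' @seealso \code{\link{buildFeatureMatrix}}
#' @name RegionFeatureMatrix-class
#' @rdname RegionFeatureMatrix-class
#' @exportClass RegionFeatureMatrix
setClass("RegionFeatureMatrix",
    representation(
        features = "matrix",
        regions = "GRanges",
        standardized = "logical",
        zeroVariance = "character"
    )
)

setValidity("RegionFeatureMatrix", function(object) {
    if (nrow(object@features) != length(object@regions))
        return("number of feature rows must equal number of regions")
    if (is.null(colnames(object@features)))
        return("feature columns must be named")
    TRUE
})

#' Elastic-net discriminator of HOT versus control regions
#'
#' A fitted penalized logistic model together with its cross-validated
#' accuracy. Coefficients are on the standardized feature scale.
#'
#' @slot coefficients named numeric vector over exactly the feature
#'   names of the training matrix.
#' @slot intercept numeric(1).
#' @slot alpha numeric(1), elastic-net mixing parameter.
#' @slot lambda numeric(1), the selected penalty (CV-minimum deviance).
#' @slot cvAUC numeric(1) in [0, 1]: mean out-of-fold rank-based AUC.
#' @slot foldAUC numeric vector of per-fold out-of-fold AUCs.
#' @slot nfolds integer(1).
#' @slot seed integer(1) used for the stratified fold assignment.
#'
#' @seealso \code{\link{trainElasticNet}}, \code{\link{variableImportance}}
#' @name HotElasticNet-class
#' @rdname HotElasticNet-class
#' @exportClass HotElasticNet
setClass("HotElasticNet",
    representation(
        coefficients = "numeric",
        intercept = "numeric",
        alpha = "numeric",
        lambda = "numeric",
        cvAUC = "numeric",
        foldAUC = "numeric",
        nfolds = "integer",
        seed = "integer"
    )
)

setValidity("HotElasticNet", function(object) {
    if (is.na(object@cvAUC) || object@cvAUC < 0 || object@cvAUC > 1)
        return("cvAUC must lie in [0, 1]")
    if (is.null(names(object@coefficients)))
        return("coefficients must be named")
    TRUE
})

setMethod("show", "HotElasticNet", function(object) {
    nz <- sum(object@coefficients != 0)
    cat("HotElasticNet fit\n")
    cat(sprintf("  alpha: %g   lambda: %.4g   nonzero coefficients: %d/%d\n",
        object@alpha, object@lambda, nz, length(object@coefficients)))
    cat(sprintf("  cross-validated AUC: %.3f (%d folds)\n",
        object@cvAUC, object@nfolds))
})

#' @describeIn HotElasticNet-class coefficients of the fitted model
#'   (named vector, no intercept).
#' @param object a \code{HotElasticNet}.
#' @param ... ignored.
#' @export
setMethod("coef", "HotElasticNet", function(object, ...) object@coefficients)
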