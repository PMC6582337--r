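#' Accessors for OccupancyRegions
#'
#' @param x an \linkS4class{OccupancyRegions} object.
#' @return \code{occupancy} returns the integer summit count per
#'   region; \code{percentileRank} the mean-rank occupancy percentile
#'   in [0, 100]; \code{regionLabel} the COLD/MILD/HOT factor;
#'   \code{regionRanges} the annotated \link[GenomicRanges]{GRanges};
#'   \code{callerParam} the \linkS4class{HotCallerParam} used;
#'   \code{hotRegions} the subset of regions labelled HOT (as
#'   \code{GRanges}).
#' @name OccupancyRegions-accessors
#' @examples
#' dens <- summitDensity(
#'     GenomicRanges::GRanges("chr1", IRanges::IRanges(c(900, 950, 5000),
#'                                                     width = 1)),
#'     c(chr1 = 10000), HotCallerParam(suppressionSpan = 1000))
#' occ <- callHotRegions(localMaxima(dens, 1000), HotCallerParam())
#' occupancy(occ)
#' percentileRank(occ)
#' regionLabel(occ)
NULL

#' @rdname OccupancyRegions-accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname OccupancyRegions-accessors
#' @export
setGeneric("percentileRank", function(x) standardGeneric("percentileRank"))

#' @rdname OccupancyRegions-accessors
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))

#' @rdname OccupancyRegions-accessors
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))

#' @rdname OccupancyRegions-accessors
#' @export
setGeneric("callerParam", function(x) standardGeneric("callerParam"))

#' @rdname OccupancyRegions-accessors
#' @export
setGeneric("hotRegions", function(x) standardGeneric("hotRegions"))

#' Accessor for feature matrices
#'
#' @param x a \linkS4class{RegionFeatureMatrix}.
#' @return the numeric feature matrix (regions x features).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname OccupancyRegions-accessors
#' @export
setMethod("occupancy", "OccupancyRegions", function(x)
    S4Vectors::mcols(x@ranges)$occupancy)

#' @rdname OccupancyRegions-accessors
#' @export
setMethod("percentileRank", "OccupancyRegions", function(x)
    S4Vectors::mcols(x@ranges)$percentile)

#' @rdname OccupancyRegions-accessors
#' @export
setMethod("regionLabel", "OccupancyRegions", function(x)
    S4Vectors::mcols(x@ranges)$label)

#' @rdname OccupancyRegions-accessors
#' @export
setMethod("regionRanges", "OccupancyRegions", function(x) x@ranges)

#' @rdname OccupancyRegions-accessors
#' @export
setMethod("callerParam", "OccupancyRegions", function(x) x@param)

#' @rdname OccupancyRegions-accessors
#' @export
setMethod("hotRegions", "OccupancyRegions", function(x)
    x@ranges[S4Vectors::mcols(x@ranges)$label == "HOT"])

#' @export
setMethod("length", "OccupancyRegions", function(x) length(x@ranges))

#' Subset occupancy regions
#'
#' Subsetting keeps occupancy, percentile and label as computed on the
#' full region set; percentiles are not recomputed.
#' @param x an \code{OccupancyRegions}; \code{i} an index vector.
#' @param i,j,...,drop index and standard subset arguments (only
#'   \code{i} is used).
#' @export
setMethod("[", "OccupancyRegions", function(x, i, j, ..., drop = FALSE) {
    initialize(x, ranges = x@ranges[i])
})

setMethod("show", "OccupancyRegions", function(object) {
    tab <- table(regionLabel(object))
    cat(sprintf("OccupancyRegions with %d regions (window %d bp)\n",
        length(object), object@param@windowSize))
    cat(sprintf("  HOT: %d   MILD: %d   COLD: %d   (hotPercentile > %g)\n",
        tab[["HOT"]], tab[["MILD"]], tab[["COLD"]],
        object@param@hotPercentile))
    if (length(object)) {
        occ <- occupancy(object)
        cat(sprintf("  occupancy: min %d, median %g, max %d\n",
            min(occ), stats::median(occ), max(occ)))
    }
})

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "RegionFeatureMatrix", function(x) x@features)

#' @export
setMethod("dim", "RegionFeatureMatrix", function(x) dim(x@features))

setMethod("show", "RegionFeatureMatrix", function(object) {
    cat(sprintf("RegionFeatureMatrix: %d regions x %d features%s\n",
        nrow(object@features), ncol(object@features),
        if (object@standardized) " (standardized)" else ""))
    if (length(object@zeroVariance))
        cat(sprintf("  zero-variance columns left at 0: %d\n",
            length(object@zeroVariance)))
})
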