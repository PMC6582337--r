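#' Mean methylation per region
#'
#' Unweighted mean of the per-CpG methylated fractions at CpG
#' positions falling inside each region (half-open: a CpG exactly at
#' the region end coordinate is excluded). Regions covering no CpG
#' yield \code{NA} and are excluded from downstream summaries.
#'
#' @param calls \code{GRanges} of per-CpG methylation fractions
#'   (metadata column \code{fraction}) for one cell type, e.g. from
#'   \code{\link{readMethylationBedGraph}}.
#' @param regions \code{GRanges} or \linkS4class{OccupancyRegions}.
#' @return numeric vector, one mean (or \code{NA}) per region.
#' @export
regionMeanMethylation <- function(calls, regions) {
    gr <- if (is(regions, "OccupancyRegions")) regionRanges(regions)
          else regions
    frac <- S4Vectors::mcols(calls)$fraction
    if (is.null(frac))
        stop("calls must carry a 'fraction' metadata column")
    hits <- GenomicRanges::findOverlaps(gr, calls, ignore.strand = TRUE)
    out <- rep(NA_real_, length(gr))
    if (length(hits)) {
        sums <- tapply(frac[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits), mean)
        out[as.integer(names(sums))] <- as.numeric(sums)
    }
    out
}

#' Median and IQR of per-region methylation
#'
#' For one region set in one cell type: the median and interquartile
#' range (linear-interpolation, type-7 quantiles) of the non-missing
#' per-region mean methylation values.
#'
#' @param means numeric vector of per-region means (\code{NA} for
#'   regions without covered CpGs); at least one non-missing value.
#' @return named numeric vector \code{c(median = , iqr = )}.
#' @export
dispersionSummary <- function(means) {
    v <- means[!is.na(means)]
    if (!length(v))
        stop("all region means are missing: no covered CpGs")
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(median = q[2L], iqr = q[3L] - q[1L])
}

#' Methylation summary across cell types
#'
#' Convenience wrapper: per-region means and their median/IQR for each
#' region set in each cell type.
#'
#' @param regionSets named list of \code{GRanges}.
#' @param callsList named list of per-cell-type methylation
#'   \code{GRanges} (metadata column \code{fraction}).
#' @return data.frame with columns set, cell_type, n_regions,
#'   median, iqr.
#' @export
methylationSummaryTable <- function(regionSets, callsList) {
    if (is.null(names(regionSets)) || is.null(names(callsList)))
        stop("regionSets and callsList must be named")
    do.call(rbind, lapply(names(regionSets), function(set) {
        do.call(rbind, lapply(names(callsList), function(ct) {
            means <- regionMeanMethylation(callsList[[ct]],
                                           regionSets[[set]])
            s <- dispersionSummary(means)
            data.frame(set = set, cell_type = ct,
                       n_regions = sum(!is.na(means)),
                       median = unname(s["median"]),
                       iqr = unname(s["iqr"]))
        }))
    }))
}

#' CpG islands not associated with HOT regions
#'
#' The CpG islands with zero overlap with any HOT region (1 bp of
#' overlap excludes an island).
#'
#' @param cgi \code{GRanges} of CpG island intervals.
#' @param hot \code{GRanges} of HOT regions.
#' @return the non-HOT subset of \code{cgi}.
#' @export
nonHotCgi <- function(cgi, hot) {
    cgi[!IRanges::overlapsAny(cgi, hot, ignore.strand = TRUE)]
}

#' Compare methylation dynamics of HOT regions and non-HOT CpG islands
#'
#' Pairs the per-cell-type (median, IQR) summaries of the two region
#' sets and reports the cross-cell-type dispersion ratio
#' \code{median(IQR[non-HOT CGI]) / median(IQR[HOT])}: how many times
#' more variable methylation is on non-HOT CpG islands than on HOT
#' regions across cell types. A zero denominator flags the ratio
#' infinite.
#'
#' @param hotSummary,nonhotSummary data.frames with columns
#'   \code{cell_type}, \code{median}, \code{iqr} (e.g. subsets of
#'   \code{\link{methylationSummaryTable}} output), over the same cell
#'   types.
#' @return a list with \code{table} (per-cell-type medians and IQRs of
#'   both sets) and \code{iqr_ratio} (possibly \code{Inf}).
#' @export
hotVsNonhotCgi <- function(hotSummary, nonhotSummary) {
    if (!setequal(hotSummary$cell_type, nonhotSummary$cell_type))
        stop("cell-type sets differ between the two summaries")
    o <- order(hotSummary$cell_type)
    hs <- hotSummary[o, ]
    ns <- nonhotSummary[match(hs$cell_type, nonhotSummary$cell_type), ]
    tab <- data.frame(
        cell_type = hs$cell_type,
        hot_median = hs$median, hot_iqr = hs$iqr,
        nonhot_median = ns$median, nonhot_iqr = ns$iqr)
    denom <- median(tab$hot_iqr)
    ratio <- if (denom == 0) Inf else median(tab$nonhot_iqr) / denom
    list(table = tab, iqr_ratio = ratio)
}
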