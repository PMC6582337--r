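#' Peak summit positions
#'
#' Returns the summit of each peak: \code{start + peak} when the
#' narrowPeak summit offset is present (\code{peak >= 0}), otherwise
#' the interval midpoint (floor of the mean of the half-open
#' endpoints).
#'
#' @param peaks a \code{GRanges} of peaks, typically from
#'   \code{\link{readNarrowPeak}}; a \code{peak} metadata column is
#'   used as the summit offset if present.
#' @return a width-1 \code{GRanges} of summit positions, preserving
#'   any \code{experiment} metadata column.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'                              peak = 50L)
#' GenomicRanges::start(peakSummits(gr))  # 151, i.e. 0-based 150
#' @export
peakSummits <- function(peaks) {
    mc <- S4Vectors::mcols(peaks)
    offset <- if ("peak" %in% colnames(mc)) mc$peak else
        rep(-1L, length(peaks))
    s <- GenomicRanges::start(peaks)
    e <- GenomicRanges::end(peaks)
    # midpoint of the 0-based half-open interval, back to 1-based
    mid <- (s - 1L + e) %/% 2L + 1L
    pos <- ifelse(offset >= 0L, s + offset, mid)
    out <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(peaks),
        IRanges::IRanges(start = pos, width = 1L))
    if ("experiment" %in% colnames(mc))
        S4Vectors::mcols(out)$experiment <- mc$experiment
    out
}

#' Pool summits from many peak experiments
#'
#' @param peakSets a named list of peak \code{GRanges} (one per
#'   ChIP-seq experiment).
#' @return a width-1 \code{GRanges} of all summits with an
#'   \code{experiment} metadata column.
#' @seealso \code{\link{summitDensity}}
#' @export
poolSummits <- function(peakSets) {
    if (is.null(names(peakSets)))
        names(peakSets) <- sprintf("experiment_%03d", seq_along(peakSets))
    summits <- lapply(names(peakSets), function(id) {
        s <- peakSummits(peakSets[[id]])
        S4Vectors::mcols(s)$experiment <- rep(id, length(s))
        s
    })
    suppressWarnings(do.call(c, unname(summits)))
}

#' Summit density over sliding windows
#'
#' Counts pooled peak summits in sliding windows of
#' \code{param@windowSize} bp advanced by \code{param@step} bp along
#' each chromosome. The last windows are truncated at the chromosome
#' end.
#'
#' @param summits a width-1 \code{GRanges} of summit positions pooled
#'   over all experiments (see \code{\link{poolSummits}}); an
#'   \code{experiment} metadata column improves error messages.
#' @param chromSizes named vector of chromosome lengths in bp.
#' @param param a \linkS4class{HotCallerParam}.
#' @return a \code{GRanges} of windows, sorted by (chromosome, start),
#'   with metadata column \code{count}; \code{seqlengths} are set.
#' @details A summit on a chromosome absent from \code{chromSizes}, or
#'   beyond its declared length, is an error naming the experiment
#'   when known.
#' @export
summitDensity <- function(summits, chromSizes, param = HotCallerParam()) {
    .checkChromSizes(chromSizes)
    chr <- as.character(GenomicRanges::seqnames(summits))
    bad <- which(!chr %in% names(chromSizes))
    if (length(bad))
        stop(sprintf("summit on unknown chromosome '%s'%s", chr[bad[1L]],
                     .summitWho(summits, bad[1L])))
    pos <- GenomicRanges::start(summits)
    bad <- which(pos > chromSizes[chr] | pos < 1L)
    if (length(bad))
        stop(sprintf("summit at %s:%d beyond chromosome length %d%s",
                     chr[bad[1L]], pos[bad[1L]] - 1L,
                     chromSizes[[chr[bad[1L]]]],
                     .summitWho(summits, bad[1L])))
    W <- param@windowSize
    step <- param@step
    wins <- lapply(names(chromSizes), function(cn) {
        len <- chromSizes[[cn]]
        starts0 <- seq.int(0L, len - 1L, by = step)
        GenomicRanges::GRanges(cn,
            IRanges::IRanges(start = starts0 + 1L,
                             end = pmin(starts0 + W, len)))
    })
    windows <- suppressWarnings(do.call(c, wins))
    suppressWarnings(GenomeInfoDb::seqlengths(windows) <-
        chromSizes[as.character(GenomeInfoDb::seqlevels(windows))])
    S4Vectors::mcols(windows)$count <- GenomicRanges::countOverlaps(
        windows, summits, ignore.strand = TRUE)
    windows
}

.summitWho <- function(summits, i) {
    mc <- S4Vectors::mcols(summits)
    if ("experiment" %in% colnames(mc))
        sprintf(" (experiment %s)", mc$experiment[i]) else ""
}

#' Suppressed local maxima of a summit-density track
#'
#' Retains density windows that dominate their neighbourhood: a kept
#' window has a count greater than or equal to that of every window
#' whose start lies within +/- \code{suppressionSpan/2} of its own,
#' and no two kept windows lie within that distance of each other.
#' Equal-count ties within one span keep the leftmost window. Windows
#' with zero count are never returned.
#'
#' @param density window \code{GRanges} with \code{count} column from
#'   \code{\link{summitDensity}}.
#' @param suppressionSpan total suppression width in bp (2000 for the
#'   human setting, 1000 for smaller genomes).
#' @return the retained subset of \code{density}, sorted by
#'   (chromosome, start).
#' @details The operation is idempotent: re-running it on its own
#'   output changes nothing.
#' @export
localMaxima <- function(density, suppressionSpan) {
    count <- S4Vectors::mcols(density)$count
    if (is.null(count))
        stop("density must carry a 'count' metadata column")
    keep <- logical(length(density))
    chr <- as.character(GenomicRanges::seqnames(density))
    for (cn in unique(chr)) {
        idx <- which(chr == cn)
        starts <- GenomicRanges::start(density)[idx]
        o <- order(starts)
        idx <- idx[o]
        starts <- starts[o]
        x <- count[idx]
        step <- if (length(starts) > 1L) min(diff(starts)) else 1L
        radiusBp <- suppressionSpan / 2
        radiusW <- as.integer(floor(radiusBp / step))
        dominant <- which(x > 0L & x == .runningMax(x, radiusW))
        if (!length(dominant))
            next
        # greedy non-maximum suppression over the dominant windows:
        # highest count first, leftmost on ties
        ord <- dominant[order(-x[dominant], starts[dominant])]
        blocked <- logical(length(x))
        for (i in ord) {
            if (blocked[i])
                next
            keep[idx[i]] <- TRUE
            lo <- max(1L, i - radiusW)
            hi <- min(length(x), i + radiusW)
            blocked[lo:hi] <- TRUE
        }
    }
    BiocGenerics::sort(density[keep], ignore.strand = TRUE)
}

#' Call occupancy regions from retained density maxima
#'
#' Ranks the retained local maxima by their summit count (the TF
#' occupancy), converts ranks to mean-rank percentiles on the
#' [0, 100] scale (Hazen scaling, ties averaged), and labels each
#' region HOT (percentile strictly above \code{param@hotPercentile}),
#' MILD (above \code{param@mildPercentile} but not HOT) or COLD.
#'
#' @param maxima window \code{GRanges} with \code{count} column, as
#'   returned by \code{\link{localMaxima}}.
#' @param param a \linkS4class{HotCallerParam}.
#' @return an \linkS4class{OccupancyRegions}, sorted by
#'   (chromosome, start).
#' @examples
#' ## 200 regions with occupancies 1..200 at the default 99th
#' ## percentile threshold: exactly the top two are HOT
#' gr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(seq(1, by = 5000, length.out = 200), width = 500),
#'     count = 1:200)
#' sum(regionLabel(callHotRegions(gr, HotCallerParam())) == "HOT")
#' @export
callHotRegions <- function(maxima, param = HotCallerParam()) {
    if (length(maxima) == 0L)
        stop("no retained maxima: cannot call regions from an empty input")
    occ <- S4Vectors::mcols(maxima)$count
    if (is.null(occ))
        stop("maxima must carry a 'count' metadata column")
    pct <- .meanRankPercentile(occ)
    label <- ifelse(pct > param@hotPercentile, "HOT",
             ifelse(pct > param@mildPercentile, "MILD", "COLD"))
    gr <- GenomicRanges::granges(maxima)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        occupancy = as.integer(occ),
        percentile = pct,
        label = factor(label, levels = c("COLD", "MILD", "HOT")))
    gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
    new("OccupancyRegions", ranges = gr, param = param)
}

#' Bin regions by occupancy percentile
#'
#' Partitions regions into half-open percentile intervals
#' \code{[0, e1), [e1, e2), ..., [ek, 100]} (the last interval is
#' closed at 100).
#'
#' @param regions an \linkS4class{OccupancyRegions}.
#' @param edges strictly increasing percentile cut points within
#'   (0, 100).
#' @return a named list of \code{OccupancyRegions} subsets, one per
#'   bin, names like \code{"[75,99)"}. The bins partition the input.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(seq(1, by = 5000, length.out = 100), width = 500),
#'     count = 1:100)
#' occ <- callHotRegions(gr, HotCallerParam())
#' lengths(lapply(binByPercentile(occ, c(75, 99)), regionRanges))
#' @export
binByPercentile <- function(regions, edges = c(75, 99)) {
    edges <- as.numeric(edges)
    if (any(diff(edges) <= 0) || any(edges <= 0) || any(edges >= 100))
        stop("edges must be strictly increasing and lie inside (0, 100)")
    pct <- percentileRank(regions)
    bin <- findInterval(pct, edges) + 1L
    bounds <- c(0, edges, 100)
    labels <- vapply(seq_len(length(edges) + 1L), function(i) {
        if (i <= length(edges))
            sprintf("[%g,%g)", bounds[i], bounds[i + 1L])
        else
            sprintf("[%g,%g]", bounds[i], bounds[i + 1L])
    }, character(1L))
    out <- lapply(seq_along(labels), function(i) regions[bin == i])
    names(out) <- labels
    out
}
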