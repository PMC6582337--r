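#' Counts-per-million scaling
#'
#' \code{cpmScale(counts, librarySize)} returns
#' \code{counts / librarySize * 1e6}. Scaling a library k-fold while
#' keeping per-region proportions leaves the result unchanged.
#'
#' @param counts numeric vector of read counts.
#' @param librarySize total reads in the library (> 0).
#' @return numeric vector of CPM values.
#' @export
cpmScale <- function(counts, librarySize) {
    if (librarySize <= 0)
        stop("librarySize must be positive")
    counts / librarySize * 1e6
}

#' Per-region log2 IP/control enrichment
#'
#' For each region, counts the IP and control reads overlapping it by
#' any intersection (>= 1 bp), scales both counts to CPM, and reports
#' \code{log2((ip_cpm + epsilon) / (control_cpm + epsilon))}. The
#' pseudocount \code{epsilon} (default 1 CPM, i.e. one read in a
#' million-read library) keeps zero-control regions finite; the
#' estimate stays monotone in the IP count for fixed control. When a
#' true control is unavailable an RNaseH-treated IP may stand in as
#' control; record that via \code{controlKind}.
#'
#' @param ip,control \code{GRanges} of aligned-read intervals.
#' @param regions \code{GRanges} or \linkS4class{OccupancyRegions};
#'   non-empty.
#' @param ipLibrarySize,controlLibrarySize library sizes; default the
#'   number of read intervals supplied.
#' @param epsilon pseudocount in CPM units (default 1).
#' @param controlKind one of \code{"input"}, \code{"IgG"},
#'   \code{"RNaseH"}.
#' @return a \code{data.frame} with one row per region: region id,
#'   \code{ip_count}, \code{control_count}, \code{ip_cpm},
#'   \code{control_cpm}, \code{log2_ratio}; attributes
#'   \code{epsilon} and \code{control_kind}.
#' @examples
#' regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' ip <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:100, width = 36))
#' ctrl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:25, width = 36))
#' regionLog2Enrichment(ip, ctrl, regions,
#'     ipLibrarySize = 1e6, controlLibrarySize = 1e6)$log2_ratio
#' @export
regionLog2Enrichment <- function(ip, control, regions,
                                 ipLibrarySize = length(ip),
                                 controlLibrarySize = length(control),
                                 epsilon = 1,
                                 controlKind = c("input", "IgG", "RNaseH")) {
    controlKind <- match.arg(controlKind)
    gr <- if (is(regions, "OccupancyRegions")) regionRanges(regions)
          else regions
    if (length(gr) == 0L)
        stop("regions must be non-empty")
    if (ipLibrarySize <= 0 || controlLibrarySize <= 0)
        stop("library sizes must be positive")
    ipCount <- GenomicRanges::countOverlaps(gr, ip, ignore.strand = TRUE)
    ctrlCount <- GenomicRanges::countOverlaps(gr, control,
                                              ignore.strand = TRUE)
    ipCpm <- cpmScale(ipCount, ipLibrarySize)
    ctrlCpm <- cpmScale(ctrlCount, controlLibrarySize)
    out <- data.frame(
        region = .regionId(gr),
        ip_count = ipCount, control_count = ctrlCount,
        ip_cpm = ipCpm, control_cpm = ctrlCpm,
        log2_ratio = log2((ipCpm + epsilon) / (ctrlCpm + epsilon)))
    attr(out, "epsilon") <- epsilon
    attr(out, "control_kind") <- controlKind
    out
}

#' Per-base-pair log2(IP/control) track
#'
#' Elementwise \code{log2((ip + epsilon) / (control + epsilon))} over
#' CPM-scaled coverage tracks on the same chromosome grid.
#'
#' @param ipCoverage,controlCoverage \link[IRanges]{RleList} coverage
#'   (CPM-scaled), same chromosome names and lengths.
#' @param epsilon pseudocount in CPM units (default 1).
#' @return an \code{RleList} of per-bp log2 ratios.
#' @seealso \code{\link{coverageCpm}}, \code{\link{profileMatrix}}
#' @export
perBpLog2Track <- function(ipCoverage, controlCoverage, epsilon = 1) {
    if (!identical(sort(names(ipCoverage)), sort(names(controlCoverage))))
        stop("coverage grid mismatch: chromosome sets differ")
    controlCoverage <- controlCoverage[names(ipCoverage)]
    if (!identical(unname(lengths(ipCoverage)),
                   unname(lengths(controlCoverage))))
        stop("coverage grid mismatch: chromosome lengths differ")
    log2((ipCoverage + epsilon) / (controlCoverage + epsilon))
}

#' CPM-scaled read coverage
#'
#' @param reads \code{GRanges} of read intervals.
#' @param chromSizes named chromosome lengths (fixes the grid).
#' @param librarySize library size (default number of reads).
#' @return an \code{RleList} of per-bp CPM coverage.
#' @export
coverageCpm <- function(reads, chromSizes, librarySize = length(reads)) {
    .checkChromSizes(chromSizes)
    if (librarySize <= 0)
        stop("librarySize must be positive")
    missing <- setdiff(GenomeInfoDb::seqlevels(reads), names(chromSizes))
    if (length(missing))
        stop("reads on chromosomes absent from chromSizes: ",
             paste(missing, collapse = ", "))
    reads <- GenomeInfoDb::`seqlevels<-`(reads, value = names(chromSizes))
    cov <- GenomicRanges::coverage(reads,
        width = as.list(setNames(as.integer(chromSizes),
                                 names(chromSizes))))
    cov / librarySize * 1e6
}

#' Stratified sampling of regions by occupancy percentile
#'
#' Draws a uniform without-replacement sample from each occupancy
#' stratum (defaults: 3000 windows from percentiles [0, 75), 3000
#' from [75, 99) and 3000 from [99, 100]). A stratum smaller than its
#' requested size is taken in full and the shortfall recorded.
#'
#' @param regions an \linkS4class{OccupancyRegions}.
#' @param strata data.frame with columns \code{lo}, \code{hi}
#'   (percentiles; the last stratum is closed at 100) and \code{n}.
#' @param seed integer seed or \code{NULL}.
#' @return a \code{GRanges} of sampled windows with metadata columns
#'   \code{occupancy}, \code{percentile} and \code{stratum}; attribute
#'   \code{shortfall} is a data.frame of requested versus obtained
#'   sizes per stratum.
#' @export
stratifiedWindowSample <- function(regions,
        strata = data.frame(lo = c(0, 75, 99), hi = c(75, 99, 100),
                            n = 3000),
        seed = NULL) {
    pct <- percentileRank(regions)
    gr <- regionRanges(regions)
    picks <- .withSeed(seed, {
        lapply(seq_len(nrow(strata)), function(i) {
            lo <- strata$lo[i]; hi <- strata$hi[i]
            member <- if (hi >= 100) pct >= lo & pct <= 100
                      else pct >= lo & pct < hi
            idx <- which(member)
            if (length(idx) > strata$n[i]) sort(sample(idx, strata$n[i]))
            else idx
        })
    })
    labels <- sprintf("[%g,%g%s", strata$lo, strata$hi,
                      ifelse(strata$hi >= 100, "]", ")"))
    out <- gr[unlist(picks)]
    S4Vectors::mcols(out)$stratum <- rep(labels, lengths(picks))
    attr(out, "shortfall") <- data.frame(
        stratum = labels, requested = strata$n,
        obtained = lengths(picks))
    out
}

#' Binned metaregion profile matrix
#'
#' Builds the heatmap matrix of a per-bp signal over a set of
#' equal-width windows: each window is divided into \code{nbins} bins
#' along its length, the per-bp values are averaged within each bin,
#' and the whole matrix is winsorized at its own low/high percentiles
#' (defaults 0.5 and 99) to limit extreme values. Window widths not
#' divisible by \code{nbins} are padded symmetrically to the next
#' multiple; positions off the chromosome are missing (\code{NA}) and
#' fully-missing bins stay \code{NA}.
#'
#' @param track \code{RleList} of per-bp values (e.g. from
#'   \code{\link{perBpLog2Track}}).
#' @param windows equal-width \code{GRanges}; an \code{occupancy}
#'   metadata column, when present, orders the rows by descending
#'   occupancy.
#' @param nbins number of bins (default 50).
#' @param winsor low/high winsorization percentiles (default
#'   \code{c(0.5, 99)}); \code{NULL} skips winsorization.
#' @return numeric matrix (windows x bins) with attributes
#'   \code{winsorLimits} (the clip values, when applied) and
#'   \code{binWidth}.
#' @export
profileMatrix <- function(track, windows, nbins = 50,
                          winsor = c(0.5, 99)) {
    if (length(windows) == 0L)
        stop("windows must be non-empty")
    w <- unique(GenomicRanges::width(windows))
    if (length(w) != 1L)
        stop("windows must all have the same width")
    target <- as.integer(nbins * ceiling(w / nbins))
    if (target != w) {
        extra <- target - w
        left <- extra %/% 2L
        windows <- GenomicRanges::resize(
            GenomicRanges::resize(windows, w + left, fix = "end"),
            target, fix = "start")
        w <- target
    }
    binWidth <- w %/% as.integer(nbins)
    chr <- as.character(GenomicRanges::seqnames(windows))
    bad <- which(!chr %in% names(track))
    if (length(bad))
        stop(sprintf("window %s lies on a chromosome absent from the track",
                     .regionId(windows[bad[1L]])))
    vals <- matrix(NA_real_, nrow = length(windows), ncol = w)
    for (cn in unique(chr)) {
        x <- as.numeric(track[[cn]])
        len <- length(x)
        for (i in which(chr == cn)) {
            s <- GenomicRanges::start(windows)[i]
            e <- GenomicRanges::end(windows)[i]
            ss <- max(1L, s); ee <- min(len, e)
            if (ss <= ee)
                vals[i, (ss - s + 1L):(ee - s + 1L)] <- x[ss:ee]
        }
    }
    bins <- rep(seq_len(nbins), each = binWidth)
    mat <- vapply(seq_len(nbins), function(b)
        rowMeans(vals[, bins == b, drop = FALSE], na.rm = TRUE),
        numeric(length(windows)))
    mat <- matrix(mat, nrow = length(windows), ncol = nbins)
    mat[is.nan(mat)] <- NA_real_
    occ <- S4Vectors::mcols(windows)$occupancy
    if (!is.null(occ))
        mat <- mat[order(-occ), , drop = FALSE]
    colnames(mat) <- sprintf("bin%02d", seq_len(nbins))
    attr(mat, "binWidth") <- binWidth
    if (!is.null(winsor)) {
        q <- quantile(mat, winsor / 100, na.rm = TRUE, type = 7,
                      names = FALSE)
        mat[!is.na(mat) & mat < q[1L]] <- q[1L]
        mat[!is.na(mat) & mat > q[2L]] <- q[2L]
        attr(mat, "winsorLimits") <- q
    }
    mat
}

#' Extend reads to a fixed length in a stranded fashion
#'
#' Plus-strand reads become \code{[start, start + L)}, minus-strand
#' reads \code{[end - L, end)}, clipped at chromosome bounds;
#' the library size is unaffected. Used to turn single-end IgG/input
#' read starts into fragment-length intervals before per-million
#' normalization.
#'
#' @param reads stranded \code{GRanges}; an unstranded read
#'   (\code{*}) is an error.
#' @param targetLength fragment length in bp (default 200).
#' @param chromSizes optional named lengths used for right-end
#'   clipping (taken from \code{seqlengths(reads)} when set).
#' @return the extended \code{GRanges}.
#' @export
extendReads <- function(reads, targetLength = 200, chromSizes = NULL) {
    strand <- as.character(GenomicRanges::strand(reads))
    if (any(strand == "*"))
        stop("unstranded read: stranded extension requires + or - on every read")
    out <- GenomicRanges::resize(reads, as.integer(targetLength),
                                 fix = "start")
    out <- IRanges::restrict(out, start = 1L)
    if (!is.null(chromSizes))
        suppressWarnings(GenomeInfoDb::seqlengths(out) <-
            chromSizes[GenomeInfoDb::seqlevels(out)])
    if (!any(is.na(GenomeInfoDb::seqlengths(out))))
        out <- GenomicRanges::trim(out)
    out
}

#' Rank correlation of two per-region score vectors
#'
#' Spearman correlation with midrank ties, e.g. for comparing
#' wild-type and knockout ChIP-seq scores over HOT regions.
#'
#' @param a,b equal-length numeric vectors (n >= 3).
#' @return the correlation; \code{NA} with attribute
#'   \code{constant = TRUE} (and a warning) when either vector is
#'   constant.
#' @export
scoreCorrelation <- function(a, b) {
    if (length(a) != length(b))
        stop("score vectors must have equal length")
    if (length(a) < 3L)
        stop("need at least 3 paired scores")
    if (max(a) == min(a) || max(b) == min(b)) {
        warning("constant score vector: rank correlation undefined")
        out <- NA_real_
        attr(out, "constant") <- TRUE
        return(out)
    }
    cor(a, b, method = "spearman")
}

#' Per-stratum enrichment summary
#'
#' The boxplot numbers: median and quartiles of per-region log2
#' enrichment within each occupancy-percentile bin.
#'
#' @param enrichment data.frame from
#'   \code{\link{regionLog2Enrichment}}.
#' @param percentiles per-region occupancy percentiles (same order).
#' @param edges percentile bin edges (default \code{c(75, 99)}).
#' @return data.frame with bin, n, q1, median, q3.
#' @export
stratumSummary <- function(enrichment, percentiles, edges = c(75, 99)) {
    if (nrow(enrichment) != length(percentiles))
        stop("percentiles must match enrichment rows")
    bin <- findInterval(percentiles, edges) + 1L
    bounds <- c(0, edges, 100)
    labels <- vapply(seq_len(length(edges) + 1L), function(i)
        sprintf("[%g,%g%s", bounds[i], bounds[i + 1L],
                if (i <= length(edges)) ")" else "]"), character(1L))
    do.call(rbind, lapply(seq_along(labels), function(i) {
        v <- enrichment$log2_ratio[bin == i]
        data.frame(bin = labels[i], n = length(v),
                   q1 = if (length(v)) quantile(v, 0.25, names = FALSE)
                        else NA_real_,
                   median = if (length(v)) median(v) else NA_real_,
                   q3 = if (length(v)) quantile(v, 0.75, names = FALSE)
                        else NA_real_)
    }))
}
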