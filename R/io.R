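#' Read a narrowPeak (or BED6) file
#'
#' Parses the ENCODE 10-column narrowPeak format. Plain 6-column BED
#' lines are accepted, with the missing statistics defaulted
#' (\code{signalValue = 0}, \code{pValue = qValue = -1}) and the summit
#' offset set to \code{-1} (absent). Coordinates on disk are 0-based
#' half-open and are converted to the 1-based closed convention of
#' \link[GenomicRanges]{GRanges}.
#'
#' @param path path to a narrowPeak/BED file.
#' @return a \code{GRanges} with metadata columns \code{name},
#'   \code{score}, \code{signalValue}, \code{pValue}, \code{qValue}
#'   and \code{peak} (summit offset from start in bp, \code{-1} when
#'   absent). Input order is preserved.
#' @details Malformed lines (a column count other than 6 or 10,
#'   non-numeric coordinates, \code{start >= end}, or a summit offset
#'   outside the peak) raise an error naming the offending line.
#' @seealso \code{\link{writeNarrowPeak}}, \code{\link{peakSummits}}
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tp1\t0\t.\t5.0\t-1\t-1\t50", f)
#' readNarrowPeak(f)
#' @export
readNarrowPeak <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            name = character(), score = integer(),
            signalValue = numeric(), pValue = numeric(),
            qValue = numeric(), peak = integer())
        return(gr)
    }
    fields <- strsplit(trimws(lines), "[ \t]+")
    nc <- lengths(fields)
    bad <- which(!(nc %in% c(6L, 10L)))
    if (length(bad))
        stop(sprintf("narrowPeak parse error at line %d: expected 6 or 10 columns, found %d",
                     bad[1L], nc[bad[1L]]))
    get_col <- function(i) vapply(fields, `[`, character(1L), i)
    chrom <- get_col(1L)
    start0 <- suppressWarnings(as.integer(get_col(2L)))
    end0 <- suppressWarnings(as.integer(get_col(3L)))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
        stop(sprintf("narrowPeak parse error at line %d: non-integer coordinates",
                     bad[1L]))
    bad <- which(start0 >= end0)
    if (length(bad))
        stop(sprintf("narrowPeak parse error at line %d: start (%d) must be < end (%d)",
                     bad[1L], start0[bad[1L]], end0[bad[1L]]))
    name <- get_col(4L)
    score <- suppressWarnings(as.integer(get_col(5L)))
    score[is.na(score)] <- 0L
    strand <- get_col(6L)
    strand[!strand %in% c("+", "-")] <- "*"
    ten <- nc == 10L
    signalValue <- numeric(length(lines))
    pValue <- rep(-1, length(lines))
    qValue <- rep(-1, length(lines))
    peak <- rep(-1L, length(lines))
    if (any(ten)) {
        signalValue[ten] <- suppressWarnings(
            as.numeric(vapply(fields[ten], `[`, character(1L), 7L)))
        pValue[ten] <- suppressWarnings(
            as.numeric(vapply(fields[ten], `[`, character(1L), 8L)))
        qValue[ten] <- suppressWarnings(
            as.numeric(vapply(fields[ten], `[`, character(1L), 9L)))
        peak[ten] <- suppressWarnings(
            as.integer(vapply(fields[ten], `[`, character(1L), 10L)))
    }
    bad <- which(is.na(signalValue) | is.na(pValue) | is.na(qValue) |
                 is.na(peak))
    if (length(bad))
        stop(sprintf("narrowPeak parse error at line %d: non-numeric statistics columns",
                     bad[1L]))
    width <- end0 - start0
    bad <- which(peak != -1L & (peak < 0L | peak >= width))
    if (length(bad))
        stop(sprintf("narrowPeak parse error at line %d: summit offset %d outside peak of width %d",
                     bad[1L], peak[bad[1L]], width[bad[1L]]))
    GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
        strand = strand,
        name = name, score = score, signalValue = signalValue,
        pValue = pValue, qValue = qValue, peak = peak)
}

#' Write peaks as 10-column narrowPeak
#'
#' Coordinates are emitted 0-based half-open. Missing metadata columns
#' are defaulted (\code{signalValue = 0}, \code{pValue = qValue = -1},
#' \code{peak = -1}).
#'
#' @param gr a \code{GRanges}, e.g. from \code{\link{readNarrowPeak}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNarrowPeak <- function(gr, path) {
    mc <- S4Vectors::mcols(gr)
    pull <- function(col, default) {
        if (col %in% colnames(mc)) mc[[col]] else rep(default, length(gr))
    }
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "."
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = pull("name", "."),
        score = pull("score", 0L),
        strand = strand,
        signalValue = pull("signalValue", 0),
        pValue = pull("pValue", -1),
        qValue = pull("qValue", -1),
        peak = pull("peak", -1L))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a tab- or space-separated file with chromosome
#'   name and length.
#' @return a named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    df <- read.table(path, header = FALSE, sep = "",
                     col.names = c("chrom", "size"),
                     colClasses = c("character", "integer"))
    sizes <- setNames(df$size, df$chrom)
    .checkChromSizes(sizes)
    sizes
}

#' @rdname readChromSizes
#' @param chromSizes named integer vector.
#' @export
writeChromSizes <- function(chromSizes, path) {
    .checkChromSizes(chromSizes)
    writeLines(sprintf("%s\t%d", names(chromSizes),
                       as.integer(chromSizes)), path)
    invisible(path)
}

#' Read stranded intervals from a BED6 file
#'
#' Used for aligned-read intervals (IP/control libraries) and CpG
#' island annotations. 0-based half-open on disk, converted to
#' \code{GRanges}.
#'
#' @param path path to a BED file with at least 3 columns; strand is
#'   taken from column 6 when present.
#' @return a \code{GRanges} (with \code{name} and \code{score} when
#'   the columns exist).
#' @export
readBed <- function(path) {
    df <- read.table(path, header = FALSE, sep = "",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
        stop("BED file must have at least 3 columns: ", path)
    bad <- which(df[[2L]] >= df[[3L]])
    if (length(bad))
        stop(sprintf("BED parse error at line %d: start >= end", bad[1L]))
    strand <- if (ncol(df) >= 6L) {
        s <- as.character(df[[6L]])
        s[!s %in% c("+", "-")] <- "*"
        s
    } else "*"
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(df[[1L]]),
        ranges = IRanges::IRanges(start = df[[2L]] + 1L, end = df[[3L]]),
        strand = strand)
    if (ncol(df) >= 4L) S4Vectors::mcols(gr)$name <- as.character(df[[4L]])
    if (ncol(df) >= 5L) S4Vectors::mcols(gr)$score <- df[[5L]]
    gr
}

#' @rdname readBed
#' @param gr a \code{GRanges}.
#' @export
writeBed <- function(gr, path) {
    mc <- S4Vectors::mcols(gr)
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "."
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = if ("name" %in% colnames(mc)) mc$name else ".",
        score = if ("score" %in% colnames(mc)) mc$score else 0L,
        strand = strand)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read per-CpG methylation fractions from a bedGraph-like table
#'
#' Expects four columns: chrom, 0-based start, end, methylated
#' fraction in [0, 1]; one row per CpG.
#'
#' @param path path to the table.
#' @return a width-1 (or interval) \code{GRanges} with metadata column
#'   \code{fraction}.
#' @export
readMethylationBedGraph <- function(path) {
    df <- read.table(path, header = FALSE, sep = "",
                     col.names = c("chrom", "start", "end", "fraction"),
                     colClasses = c("character", "integer", "integer",
                                    "numeric"))
    bad <- which(df$fraction < 0 | df$fraction > 1)
    if (length(bad))
        stop(sprintf("methylation parse error at line %d: fraction outside [0, 1]",
                     bad[1L]))
    GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = df$start + 1L, end = df$end),
        fraction = df$fraction)
}

#' @rdname readMethylationBedGraph
#' @param calls a \code{GRanges} with metadata column \code{fraction}.
#' @export
writeMethylationBedGraph <- function(calls, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(calls)),
        start = GenomicRanges::start(calls) - 1L,
        end = GenomicRanges::end(calls),
        fraction = S4Vectors::mcols(calls)$fraction)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Export called regions
#'
#' \code{writeRegionsBed} writes BED6+2: the six BED columns (score =
#' occupancy capped at 1000) plus occupancy and percentile.
#' \code{writeRegionsTsv} writes a headered table with chrom, 0-based
#' start, end, occupancy, percentile and label. Both are ordered by
#' (chrom, start).
#'
#' @param regions an \linkS4class{OccupancyRegions}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
    gr <- regionRanges(regions)
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = sprintf("region_%05d", seq_along(gr)),
        score = pmin(occupancy(regions), 1000L),
        strand = ".",
        occupancy = occupancy(regions),
        percentile = round(percentileRank(regions), 4))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeRegionsBed
#' @export
writeRegionsTsv <- function(regions, path) {
    gr <- regionRanges(regions)
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        occupancy = occupancy(regions),
        percentile = round(percentileRank(regions), 4),
        label = as.character(regionLabel(regions)))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    invisible(path)
}
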