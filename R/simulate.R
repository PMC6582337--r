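#' Simulate a genome with planted CpG-rich loci
#'
#' Background sequence is i.i.d. at the requested GC content with CpG
#' dinucleotides depleted (each CpG retained with probability
#' \code{cpgRetention}, otherwise its G is resampled from A/C/T),
#' which reproduces the CpG observed/expected ratio of roughly
#' 0.2-0.3 typical of vertebrate bulk genome. Planted loci are
#' i.i.d. at a higher GC content with no CpG depletion, so their
#' realized CpG O/E sits near 1, well above the background
#' distribution - the sequence signature of CpG-island-like HOT loci.
#' Deterministic under \code{seed}.
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param gc background GC content (default 0.41, human-like).
#' @param cpgRetention background CpG retention probability (default
#'   0.25).
#' @param nLoci number of loci to plant, spread over chromosomes
#'   proportionally to length (ignored when \code{loci} is given).
#' @param lociWidth width of each planted locus in bp (default 2000).
#' @param lociGC GC content of planted loci (default 0.60).
#' @param loci optional \code{GRanges} of loci to plant
#'   (non-overlapping, inside the chromosomes).
#' @param seed integer seed.
#' @return a list with \code{genome} (named
#'   \link[Biostrings]{DNAStringSet}), \code{chromSizes} and
#'   \code{loci} (\code{GRanges} with a \code{locus} id column).
#' @examples
#' g <- simGenome(c(chr1 = 50000), nLoci = 3, seed = 1)
#' cpgOE(regionWindows(g$loci, g$genome)[[1]])  # near 1
#' @export
simGenome <- function(chromLengths, gc = 0.41, cpgRetention = 0.25,
                      nLoci = 10, lociWidth = 2000, lociGC = 0.60,
                      loci = NULL, seed = 1) {
    .checkChromSizes(chromLengths)
    .withSeed(seed, {
        if (is.null(loci))
            loci <- .placeLoci(chromLengths, nLoci, lociWidth)
        .checkLoci(loci, chromLengths)
        seqs <- lapply(names(chromLengths), function(cn) {
            s <- .simBackground(chromLengths[[cn]], gc, cpgRetention)
            here <- loci[as.character(
                GenomicRanges::seqnames(loci)) == cn]
            for (i in seq_along(here)) {
                w <- GenomicRanges::width(here)[i]
                s[GenomicRanges::start(here)[i]:
                  GenomicRanges::end(here)[i]] <- .simCpgRich(w, lociGC)
            }
            paste(s, collapse = "")
        })
        genome <- Biostrings::DNAStringSet(unlist(seqs))
        names(genome) <- names(chromLengths)
        if (length(loci))
            S4Vectors::mcols(loci)$locus <-
                sprintf("locus_%03d", seq_along(loci))
        list(genome = genome, chromSizes = chromLengths, loci = loci)
    })
}

# Non-overlapping loci: one random position inside each of nLoci
# equal slots, slots allocated to chromosomes proportionally.
.placeLoci <- function(chromLengths, nLoci, lociWidth) {
    if (nLoci == 0L)
        return(GenomicRanges::GRanges())
    alloc <- .allocateProportional(nLoci, chromLengths)
    parts <- lapply(names(chromLengths), function(cn) {
        k <- alloc[[cn]]
        if (k == 0L)
            return(GenomicRanges::GRanges())
        len <- chromLengths[[cn]]
        slot <- len %/% k
        if (slot < lociWidth * 2L)
            stop(sprintf("chromosome %s too short for %d loci of %d bp",
                         cn, k, lociWidth))
        offs <- floor(runif(k, min = slot * 0.1,
                            max = slot * 0.9 - lociWidth))
        starts <- (seq_len(k) - 1L) * slot + offs + 1L
        GenomicRanges::GRanges(cn,
            IRanges::IRanges(start = starts, width = lociWidth))
    })
    suppressWarnings(do.call(c, parts))
}

.allocateProportional <- function(n, weights) {
    share <- weights / sum(weights) * n
    alloc <- floor(share)
    left <- n - sum(alloc)
    if (left > 0) {
        o <- order(share - alloc, decreasing = TRUE)
        alloc[o[seq_len(left)]] <- alloc[o[seq_len(left)]] + 1L
    }
    setNames(as.integer(alloc), names(weights))
}

.checkLoci <- function(loci, chromLengths) {
    if (!length(loci))
        return(invisible())
    red <- GenomicRanges::reduce(loci, ignore.strand = TRUE)
    if (length(red) != length(loci))
        stop("planted loci must not overlap")
    chr <- as.character(GenomicRanges::seqnames(loci))
    if (any(!chr %in% names(chromLengths)) ||
        any(GenomicRanges::end(loci) > chromLengths[chr]) ||
        any(GenomicRanges::start(loci) < 1L))
        stop("planted loci must lie inside the declared chromosomes")
    invisible()
}

.simBackground <- function(len, gc, cpgRetention) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- sample(names(p), len, replace = TRUE, prob = p)
    cg <- which(s[-len] == "C" & s[-1L] == "G")
    drop <- cg[runif(length(cg)) > cpgRetention]
    if (length(drop)) {
        repl <- c("A", "C", "T")
        s[drop + 1L] <- sample(repl, length(drop), replace = TRUE,
                               prob = p[repl] / sum(p[repl]))
    }
    s
}

.simCpgRich <- function(len, gc) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    sample(names(p), len, replace = TRUE, prob = p)
}

#' Simulate peak experiments concentrating summits at planted loci
#'
#' Each pseudo-experiment independently places a summit at each
#' planted locus with probability \code{pHot} (jittered around the
#' locus center by a normal truncated to the locus), plus background
#' summits from a homogeneous Poisson process over the genome. Peaks
#' are fixed-width intervals around the summits with the narrowPeak
#' summit offset set, so the files round-trip through
#' \code{\link{readNarrowPeak}} without loss.
#'
#' @param truth result of \code{\link{simGenome}} (or a list with
#'   \code{chromSizes} and \code{loci}).
#' @param nExperiments number of pseudo-experiments (default 100).
#' @param pHot per-experiment probability of a summit at each planted
#'   locus (default 0.6).
#' @param jitterSd SD in bp of the summit jitter (default 50).
#' @param backgroundPerMb expected background summits per Mb per
#'   experiment (default 10).
#' @param peakWidth width of the emitted peaks in bp (default 200).
#' @param seed integer seed.
#' @return named list of peak \code{GRanges} (one per experiment) with
#'   narrowPeak metadata columns.
#' @export
simPeakExperiments <- function(truth, nExperiments = 100, pHot = 0.6,
                               jitterSd = 50, backgroundPerMb = 10,
                               peakWidth = 200, seed = 1) {
    chromSizes <- truth$chromSizes
    loci <- truth$loci
    .checkChromSizes(chromSizes)
    if (nExperiments < 1L)
        stop("nExperiments must be >= 1")
    totalMb <- sum(chromSizes) / 1e6
    half <- as.integer(peakWidth) %/% 2L
    lociChr <- as.character(GenomicRanges::seqnames(loci))
    lociMid <- (GenomicRanges::start(loci) +
                GenomicRanges::end(loci)) %/% 2L
    .withSeed(seed, {
        out <- lapply(seq_len(nExperiments), function(e) {
            hit <- runif(length(loci)) < pHot
            jit <- round(rnorm(sum(hit), sd = jitterSd))
            halfW <- (GenomicRanges::width(loci)[hit] %/% 2L) - 1L
            jit <- pmax(pmin(jit, halfW), -halfW)
            plantedPos <- lociMid[hit] + jit
            plantedChr <- lociChr[hit]
            nBg <- rpois(1L, backgroundPerMb * totalMb)
            bg <- .uniformPositions(nBg, chromSizes)
            chr <- c(plantedChr, bg$chrom)
            pos <- c(plantedPos, bg$pos)
            start <- pmax(1L, pos - half)
            end <- pmin(chromSizes[chr], pos + half)
            gr <- GenomicRanges::GRanges(chr,
                IRanges::IRanges(start = start, end = end),
                strand = "*",
                name = sprintf("peak_%d_%d", e, seq_along(chr)),
                score = as.integer(round(runif(length(chr), 200, 1000))),
                signalValue = round(runif(length(chr), 1, 20), 3),
                pValue = -1, qValue = -1,
                peak = as.integer(pos - start))
            BiocGenerics::sort(gr, ignore.strand = TRUE)
        })
        names(out) <- sprintf("experiment_%03d", seq_len(nExperiments))
        out
    })
}

# n positions uniform over the concatenated genome.
.uniformPositions <- function(n, chromSizes) {
    if (n == 0L)
        return(list(chrom = character(), pos = integer()))
    cum <- cumsum(as.numeric(chromSizes))
    u <- ceiling(runif(n) * sum(chromSizes))
    ci <- findInterval(u - 1, c(0, cum))
    pos <- as.integer(u - c(0, cum)[ci])
    list(chrom = names(chromSizes)[ci], pos = pmax(1L, pos))
}

#' Simulate IP and control read sets with planted fold changes
#'
#' Control reads are uniform over the genome. IP reads are allocated
#' so that the expected CPM ratio over each planted region equals the
#' planted fold change exactly: a read of length L overlaps a region
#' of width w iff its start falls in a window of w + L - 1 bp, so
#' each region receives IP reads with multinomial probability
#' \code{2^log2fc * (w + L - 1) / G} (starts uniform within that
#' window) and the remaining reads fall uniformly outside the
#' expanded regions. Strands are Bernoulli(0.5). Library sizes are
#' exactly as requested.
#'
#' @param regions \code{GRanges} of planted regions.
#' @param chromSizes named chromosome lengths.
#' @param log2fc planted log2 fold change, scalar or one per region.
#' @param ipLibrarySize,controlLibrarySize read counts (default 1e6).
#' @param readLength read length in bp (default 36).
#' @param seed integer seed.
#' @return list with \code{ip} and \code{control} (\code{GRanges} of
#'   stranded read intervals) and \code{truth} (data.frame of region
#'   and planted log2fc).
#' @export
simReads <- function(regions, chromSizes, log2fc = 2,
                     ipLibrarySize = 1e6, controlLibrarySize = 1e6,
                     readLength = 36, seed = 1) {
    .checkChromSizes(chromSizes)
    if (any(!is.finite(log2fc)))
        stop("planted fold changes must be finite")
    if (ipLibrarySize <= 0 || controlLibrarySize <= 0)
        stop("library sizes must be positive")
    fc <- rep_len(2^log2fc, length(regions))
    G <- sum(as.numeric(chromSizes))
    rl <- as.integer(readLength)
    effW <- GenomicRanges::width(regions) + rl - 1
    pReg <- fc * effW / G
    if (sum(pReg) >= 1)
        stop("planted fold changes too large: region read mass exceeds the library")
    .withSeed(seed, {
        ctrlU <- .uniformPositions(controlLibrarySize, chromSizes)
        control <- .readsFromStarts(ctrlU$chrom, ctrlU$pos, rl,
                                    chromSizes)
        counts <- as.vector(rmultinom(1L, ipLibrarySize,
                                      c(pReg, 1 - sum(pReg))))
        nBg <- counts[length(counts)]
        regChr <- as.character(GenomicRanges::seqnames(regions))
        ipChr <- character(0); ipPos <- integer(0)
        for (i in seq_along(regions)) {
            k <- counts[i]
            if (k == 0L) next
            lo <- GenomicRanges::start(regions)[i] - rl + 1L
            hi <- GenomicRanges::end(regions)[i]
            ipChr <- c(ipChr, rep(regChr[i], k))
            ipPos <- c(ipPos, as.integer(floor(runif(k, lo, hi + 1))))
        }
        expanded <- GenomicRanges::GRanges(regChr, IRanges::IRanges(
            start = pmax(1L, GenomicRanges::start(regions) - rl + 1L),
            end = GenomicRanges::end(regions)))
        bg <- .uniformOutside(nBg, chromSizes, expanded)
        ip <- .readsFromStarts(c(ipChr, bg$chrom), c(ipPos, bg$pos),
                               rl, chromSizes)
        list(ip = ip, control = control,
             truth = data.frame(region = .regionId(regions),
                                log2fc = log2(fc)))
    })
}

.readsFromStarts <- function(chrom, pos, readLength, chromSizes) {
    pos <- pmax(1L, pos)
    end <- pmin(chromSizes[chrom], pos + readLength - 1L)
    strand <- ifelse(runif(length(pos)) < 0.5, "+", "-")
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = pos, end = end), strand = strand)
    suppressWarnings(GenomeInfoDb::seqlengths(gr) <-
        chromSizes[GenomeInfoDb::seqlevels(gr)])
    gr
}

# n positions uniform over the complement of `exclude`.
.uniformOutside <- function(n, chromSizes, exclude) {
    if (n == 0L)
        return(list(chrom = character(), pos = integer()))
    whole <- GenomicRanges::GRanges(names(chromSizes), IRanges::IRanges(
        start = 1L, end = as.integer(chromSizes)))
    comp <- GenomicRanges::setdiff(whole, exclude, ignore.strand = TRUE)
    w <- GenomicRanges::width(comp)
    pick <- sample.int(length(comp), n, replace = TRUE, prob = w)
    off <- floor(runif(n) * w[pick])
    list(chrom = as.character(GenomicRanges::seqnames(comp))[pick],
         pos = as.integer(GenomicRanges::start(comp)[pick] + off))
}

#' Simulate per-CpG methylation tables with planted dispersion
#'
#' For each region set, per-region per-cell-type mean methylation is
#' drawn from a Beta distribution whose median and interquartile
#' range match the planted values (parameters found numerically);
#' per-CpG fractions add Gaussian noise around the region mean,
#' clipped to [0, 1]. CpG positions are fixed across cell types.
#' Deterministic under \code{seed}.
#'
#' @param regionSets named list of \code{GRanges}.
#' @param planted data.frame with columns \code{set}, \code{median},
#'   \code{iqr} (one row per region set).
#' @param nCellTypes number of cell types (default 10).
#' @param cpgPerRegion CpGs placed per region (default 10).
#' @param noiseSd per-CpG noise SD around the region mean (default
#'   0.02); 0 makes every CpG equal its region mean.
#' @param seed integer seed.
#' @return list with \code{cells} (named list of per-cell-type
#'   \code{GRanges} with \code{fraction}), \code{betaParams}
#'   (fitted shape parameters per set) and \code{planted}.
#' @export
simMethylation <- function(regionSets, planted, nCellTypes = 10,
                           cpgPerRegion = 10, noiseSd = 0.02,
                           seed = 1) {
    if (is.null(names(regionSets)))
        stop("regionSets must be named")
    if (!all(planted$set %in% names(regionSets)))
        stop("planted table names a set absent from regionSets")
    if (any(planted$median < 0 | planted$median > 1))
        stop("planted medians must lie in [0, 1]")
    pars <- lapply(seq_len(nrow(planted)), function(i)
        .betaFromMedianIqr(planted$median[i], planted$iqr[i]))
    names(pars) <- planted$set
    .withSeed(seed, {
        cpgs <- lapply(names(regionSets), function(set) {
            gr <- regionSets[[set]]
            pos <- lapply(seq_along(gr), function(i) {
                s <- GenomicRanges::start(gr)[i]
                e <- GenomicRanges::end(gr)[i]
                sort(sample(seq.int(s, e), min(cpgPerRegion, e - s + 1L)))
            })
            GenomicRanges::GRanges(
                rep(as.character(GenomicRanges::seqnames(gr)),
                    lengths(pos)),
                IRanges::IRanges(start = unlist(pos), width = 1L),
                set = set,
                region = rep(seq_along(gr), lengths(pos)))
        })
        names(cpgs) <- names(regionSets)
        cellNames <- sprintf("cell_%02d", seq_len(nCellTypes))
        cells <- lapply(cellNames, function(ct) {
            parts <- lapply(names(regionSets), function(set) {
                gr <- cpgs[[set]]
                nReg <- length(regionSets[[set]])
                p <- pars[[set]]
                means <- rbeta(nReg, p[["shape1"]], p[["shape2"]])
                frac <- means[S4Vectors::mcols(gr)$region]
                if (noiseSd > 0)
                    frac <- frac + rnorm(length(frac), sd = noiseSd)
                out <- GenomicRanges::granges(gr)
                S4Vectors::mcols(out)$fraction <- pmin(1, pmax(0, frac))
                out
            })
            BiocGenerics::sort(suppressWarnings(do.call(c, parts)),
                               ignore.strand = TRUE)
        })
        names(cells) <- cellNames
        list(cells = cells, betaParams = pars, planted = planted)
    })
}

# Beta shape parameters matching a target median and IQR, by
# Nelder-Mead on the log-shapes from a moment-based start.
.betaFromMedianIqr <- function(m, iqr) {
    if (m <= 0 || m >= 1)
        stop("target median must lie strictly inside (0, 1)")
    sdGuess <- max(iqr / 1.349, 1e-3)
    v <- min(sdGuess^2, m * (1 - m) * 0.99)
    ab <- max(m * (1 - m) / v - 1, 0.05)
    start <- log(c(max(m * ab, 1e-3), max((1 - m) * ab, 1e-3)))
    obj <- function(par) {
        a <- exp(par[1L]); b <- exp(par[2L])
        q <- stats::qbeta(c(0.25, 0.5, 0.75), a, b)
        (q[2L] - m)^2 + (q[3L] - q[1L] - iqr)^2
    }
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-12))
    c(shape1 = exp(fit$par[1L]), shape2 = exp(fit$par[2L]))
}
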