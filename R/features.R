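#' k-mer frequencies of a sequence
#'
#' Counts every k-mer over all length-k windows of the sequence that
#' contain no \code{N}, and divides by the number of such windows.
#' Returns the all-zero vector when no valid window exists.
#'
#' @param sequence a character string or \link[Biostrings]{DNAString}
#'   over \{A, C, G, T, N\}.
#' @param k word length, one of 2, 3, 4.
#' @return named numeric vector of length \code{4^k} (names in
#'   Biostrings lexicographic order, AA..TT); sums to 1 when any valid
#'   window exists.
#' @examples
#' kmerFrequencies("ACGT", 2)[c("AC", "CG", "GT")]  # each 1/3
#' @export
kmerFrequencies <- function(sequence, k) {
    if (!k %in% 2:4)
        stop("k must be 2, 3 or 4")
    seq <- .asDNAString(sequence)
    counts <- Biostrings::oligonucleotideFrequency(seq, width = k)
    total <- sum(counts)
    if (total == 0L)
        return(counts * 0)
    counts / total
}

.asDNAString <- function(sequence) {
    if (is(sequence, "DNAString"))
        return(sequence)
    Biostrings::DNAString(as.character(sequence))
}

#' GC content of a window ("CpG frequency" feature)
#'
#' The fraction (count(C) + count(G)) / L. In the discriminator this
#' feature is named \code{cpg_freq} and uses the nominal window length
#' (2000 bp) as L even when the window is clipped at a chromosome end;
#' stand-alone, L defaults to the sequence length. Despite the name
#' this is GC content, not CpG dinucleotide frequency; the naming
#' follows the feature set the models were built on.
#'
#' @param sequence character or \code{DNAString}; non-empty.
#' @param nominalLength the denominator L (default: sequence length).
#' @return numeric in [0, 1] (relative to \code{nominalLength}).
#' @examples
#' cpgFrequency("CCGG")  # 1
#' cpgFrequency("ACGT")  # 0.5
#' @export
cpgFrequency <- function(sequence, nominalLength = NULL) {
    seq <- .asDNAString(sequence)
    if (length(seq) == 0L)
        stop("sequence must be non-empty")
    if (is.null(nominalLength))
        nominalLength <- length(seq)
    gc <- sum(Biostrings::letterFrequency(seq, c("C", "G")))
    as.numeric(gc / nominalLength)
}

#' GC skew of a sequence
#'
#' (G - C) / (G + C); defined as 0 when the sequence contains neither
#' G nor C. Associated with R-loop-forming sequence.
#'
#' @param sequence character or \code{DNAString}.
#' @return numeric in [-1, 1].
#' @examples
#' gcSkew("GGGC")  # 0.5
#' @export
gcSkew <- function(sequence) {
    seq <- .asDNAString(sequence)
    f <- Biostrings::letterFrequency(seq, c("C", "G"))
    denom <- sum(f)
    if (denom == 0)
        return(0)
    as.numeric((f[["G"]] - f[["C"]]) / denom)
}

#' Observed/expected CpG ratio
#'
#' The Gardiner-Garden form N(CG) x L / (N(C) x N(G)) with
#' dinucleotide and mononucleotide counts over the sequence and L its
#' length; 0 when the sequence has no C or no G. Values near 1 typify
#' CpG islands; bulk vertebrate genomic background sits near 0.2-0.3
#' because of CpG depletion.
#'
#' @param sequence character or \code{DNAString}; non-empty.
#' @return numeric, non-negative.
#' @examples
#' cpgOE("CGCG")  # 2 * 4 / (2 * 2) = 2
#' cpgOE("CCGG")  # 1 * 4 / (2 * 2) = 1
#' @export
cpgOE <- function(sequence) {
    seq <- .asDNAString(sequence)
    if (length(seq) == 0L)
        stop("sequence must be non-empty")
    nC <- as.numeric(Biostrings::letterFrequency(seq, "C"))
    nG <- as.numeric(Biostrings::letterFrequency(seq, "G"))
    if (nC == 0 || nG == 0)
        return(0)
    nCG <- as.numeric(
        Biostrings::oligonucleotideFrequency(seq, width = 2L)[["CG"]])
    nCG * length(seq) / (nC * nG)
}

#' Names of the 339 discriminator features
#'
#' All 2-, 3- and 4-mers (prefixed \code{kmer.}) followed by
#' \code{cpg_freq}, \code{cpg_oe} and \code{gc_skew}, in the fixed
#' column order of \code{\link{buildFeatureMatrix}}.
#'
#' @return character vector of length 339.
#' @export
hotFeatureNames <- function() {
    km <- unlist(lapply(2:4, function(k)
        Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)))
    c(paste0("kmer.", km), "cpg_freq", "cpg_oe", "gc_skew")
}

#' Extract sequence windows centered on regions
#'
#' A window of \code{window} bp centered on each region midpoint,
#' clipped at chromosome ends.
#'
#' @param regions \code{GRanges} or \linkS4class{OccupancyRegions}.
#' @param genome a named \link[Biostrings]{DNAStringSet} of chromosome
#'   sequences.
#' @param window nominal window width in bp (default 2000).
#' @return a \code{DNAStringSet}, one (possibly clipped) window per
#'   region, named by region coordinates.
#' @export
regionWindows <- function(regions, genome, window = 2000) {
    gr <- if (is(regions, "OccupancyRegions")) regionRanges(regions)
          else regions
    chr <- as.character(GenomicRanges::seqnames(gr))
    bad <- which(!chr %in% names(genome))
    if (length(bad))
        stop(sprintf("region %s lies on a chromosome absent from the genome",
                     .regionId(gr[bad[1L]])))
    mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
    half <- as.integer(window) %/% 2L
    lens <- setNames(Biostrings::width(genome), names(genome))
    s <- pmax(1L, mid - half + 1L)
    e <- pmin(lens[chr], mid - half + as.integer(window))
    out <- Biostrings::DNAStringSet(rep("", length(gr)))
    for (cn in unique(chr)) {
        i <- which(chr == cn)
        out[i] <- Biostrings::extractAt(genome[[cn]],
            IRanges::IRanges(start = s[i], end = e[i]))
    }
    names(out) <- .regionId(gr)
    out
}

#' Build the per-region sequence feature matrix
#'
#' Computes the 339 discriminator features on a \code{window}-bp
#' window centered on each region: 2-/3-/4-mer frequencies (windows
#' containing N skipped), GC content (\code{cpg_freq}; denominator is
#' the nominal window length), CpG observed/expected (\code{cpg_oe})
#' and \code{gc_skew} (both over the actual, possibly clipped,
#' window). Feature extraction is deterministic.
#'
#' @inheritParams regionWindows
#' @return a \linkS4class{RegionFeatureMatrix} (not yet standardized).
#' @seealso \code{\link{standardizeFeatureMatrix}},
#'   \code{\link{trainElasticNet}}
#' @export
buildFeatureMatrix <- function(regions, genome, window = 2000) {
    gr <- if (is(regions, "OccupancyRegions")) regionRanges(regions)
          else regions
    seqs <- regionWindows(gr, genome, window = window)
    n <- length(seqs)
    kmers <- lapply(2:4, function(k) {
        counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
        tot <- rowSums(counts)
        tot[tot == 0] <- 1  # all-zero rows stay all-zero
        counts / tot
    })
    widths <- Biostrings::width(seqs)
    mono <- Biostrings::letterFrequency(seqs, c("C", "G"))
    nCG <- Biostrings::dinucleotideFrequency(seqs)[, "CG"]
    cpg_freq <- (mono[, "C"] + mono[, "G"]) / window
    denom <- mono[, "C"] * mono[, "G"]
    cpg_oe <- ifelse(denom == 0, 0, nCG * widths / denom)
    gcTot <- mono[, "C"] + mono[, "G"]
    gc_skew <- ifelse(gcTot == 0, 0, (mono[, "G"] - mono[, "C"]) / gcTot)
    mat <- cbind(do.call(cbind, kmers), cpg_freq = cpg_freq,
                 cpg_oe = cpg_oe, gc_skew = gc_skew)
    colnames(mat) <- hotFeatureNames()
    rownames(mat) <- names(seqs)
    new("RegionFeatureMatrix", features = mat, regions = gr,
        standardized = FALSE, zeroVariance = character())
}

#' Standardize a feature matrix
#'
#' Centers every column to mean 0 and scales to unit population
#' (divide-by-n) variance. Columns with zero variance are left at 0
#' and recorded in the \code{zeroVariance} slot.
#'
#' @param x a \linkS4class{RegionFeatureMatrix} (or plain matrix).
#' @return the standardized object (same class as the input).
#' @export
standardizeFeatureMatrix <- function(x) {
    mat <- if (is(x, "RegionFeatureMatrix")) x@features else x
    mu <- colMeans(mat)
    centered <- sweep(mat, 2L, mu)
    popSd <- sqrt(colMeans(centered^2))
    zero <- popSd <= 1e-12
    popSd[zero] <- 1
    std <- sweep(centered, 2L, popSd, "/")
    std[, zero] <- 0
    if (is(x, "RegionFeatureMatrix"))
        new("RegionFeatureMatrix", features = std, regions = x@regions,
            standardized = TRUE,
            zeroVariance = colnames(mat)[zero])
    else
        std
}
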