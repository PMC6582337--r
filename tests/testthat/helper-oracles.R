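# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the package's own code paths (and
# Biostrings counting) so the two routes stay independent.

suppressMessages({
    library(GenomicRanges)
    library(IRanges)
})

# Brute-force per-window summit count: positions are 1-based summit
# coordinates, windows are [start0, start0 + W) in 0-based terms.
bruteWindowCounts <- function(positions, chromLen, windowSize, step) {
    starts0 <- seq.int(0L, chromLen - 1L, by = step)
    vapply(starts0, function(s0) {
        lo <- s0 + 1L
        hi <- min(s0 + windowSize, chromLen)
        sum(positions >= lo & positions <= hi)
    }, integer(1L))
}

# Brute-force k-mer frequencies by substring extraction and hashing;
# windows containing characters outside ACGT are skipped.
bruteKmerFreq <- function(sequence, k) {
    alphabet <- c("A", "C", "G", "T")
    words <- sort(apply(expand.grid(rep(list(alphabet), k))[, k:1,
                                                            drop = FALSE],
                        1L, paste, collapse = ""))
    n <- nchar(sequence)
    out <- setNames(numeric(length(words)), words)
    if (n < k)
        return(out)
    subs <- substring(sequence, seq_len(n - k + 1L),
                      seq_len(n - k + 1L) + k - 1L)
    valid <- subs[!grepl("[^ACGT]", subs)]
    if (!length(valid))
        return(out)
    tab <- table(valid)
    out[names(tab)] <- as.numeric(tab) / length(valid)
    out
}

bruteLetterCount <- function(sequence, letter) {
    lengths(regmatches(sequence,
                       gregexpr(letter, sequence, fixed = TRUE)))
}

bruteCpgOE <- function(sequence) {
    nC <- bruteLetterCount(sequence, "C")
    nG <- bruteLetterCount(sequence, "G")
    if (nC == 0 || nG == 0)
        return(0)
    n <- nchar(sequence)
    subs <- substring(sequence, seq_len(n - 1L), seq_len(n - 1L) + 1L)
    sum(subs == "CG") * n / (nC * nG)
}

randomSequence <- function(n, letters = c("A", "C", "G", "T")) {
    paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Brute-force per-bin means of a per-bp numeric vector split into
# nbins equal bins.
bruteBinMeans <- function(values, nbins) {
    binWidth <- length(values) / nbins
    vapply(seq_len(nbins), function(b) {
        mean(values[((b - 1L) * binWidth + 1L):(b * binWidth)])
    }, numeric(1L))
}
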