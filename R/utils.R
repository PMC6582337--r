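# Internal helpers shared across modules.

# Evaluate `code` under `seed` without disturbing the caller's RNG
# stream. seed = NULL evaluates as-is.
.withSeed <- function(seed, code) {
    if (is.null(seed))
        return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    force(code)
}

# Running maximum of x over a symmetric window of `radius` elements on
# each side; boundaries behave as if padded with -Inf.
.runningMax <- function(x, radius) {
    n <- length(x)
    out <- x
    if (n == 0L || radius <= 0L)
        return(out)
    for (d in seq_len(min(radius, n - 1L))) {
        lead <- c(x[-seq_len(d)], rep(-Inf, d))
        lag <- c(rep(-Inf, d), x[seq_len(n - d)])
        out <- pmax(out, lead, lag)
    }
    out
}

# Rank-based (Mann-Whitney) area under the ROC curve. `positive` is a
# logical vector; midranks handle ties. NA when one class is absent.
.rankAUC <- function(scores, positive) {
    stopifnot(length(scores) == length(positive))
    n1 <- sum(positive)
    n0 <- sum(!positive)
    if (n1 == 0L || n0 == 0L)
        return(NA_real_)
    r <- rank(scores)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Mean-rank percentile with Hazen scaling: 100 * (r - 0.5) / n, ties
# averaged. Maps n equally spaced ranks into (0, 100) symmetrically.
.meanRankPercentile <- function(x) {
    n <- length(x)
    100 * (rank(x, ties.method = "average") - 0.5) / n
}

.checkChromSizes <- function(chromSizes) {
    if (is.null(names(chromSizes)) || any(!nzchar(names(chromSizes))))
        stop("chromSizes must be a named vector of chromosome lengths")
    if (any(chromSizes < 1))
        stop("chromosome lengths must be positive")
    invisible(chromSizes)
}

# GRanges region ids "chrom:start-end" (1-based, closed; display only).
.regionId <- function(gr) {
    sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr), GenomicRanges::end(gr))
}
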