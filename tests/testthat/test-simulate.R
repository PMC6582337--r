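test_that("simulated genomes are seeded, CpG-depleted, with CpG-rich loci", {
    g1 <- simGenome(c(chr1 = 50000), nLoci = 2, seed = 7)
    g2 <- simGenome(c(chr1 = 50000), nLoci = 2, seed = 7)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    g3 <- simGenome(c(chr1 = 50000), nLoci = 2, seed = 8)
    expect_false(identical(as.character(g1$genome),
                           as.character(g3$genome)))
    # zero planted loci: pure background
    g0 <- simGenome(c(chr1 = 20000), nLoci = 0, seed = 7)
    expect_length(g0$loci, 0L)
    # overlapping loci rejected
    bad <- GRanges("chr1", IRanges(c(100, 1000), width = 2000))
    expect_error(simGenome(c(chr1 = 50000), loci = bad, seed = 1),
                 "overlap")
    outside <- GRanges("chr1", IRanges(49000, width = 2000))
    expect_error(simGenome(c(chr1 = 50000), loci = outside, seed = 1),
                 "inside")
})

test_that("planted loci exceed the background CpG O/E distribution", {
    hits <- vapply(1:10, function(s) {
        g <- simGenome(c(chr1 = 2e5), nLoci = 2, seed = s)
        bg <- GRanges("chr1", IRanges(seq(1, 2e5 - 2000, by = 2000),
                                      width = 2000))
        bg <- bg[!overlapsAny(bg, g$loci, maxgap = 2000)]
        oeBg <- featureMatrix(
            buildFeatureMatrix(bg, g$genome))[, "cpg_oe"]
        oeLoci <- featureMatrix(
            buildFeatureMatrix(g$loci, g$genome))[, "cpg_oe"]
        all(oeLoci > quantile(oeBg, 0.95))
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("pseudo-experiments hit planted loci at the binomial rate", {
    g <- simGenome(c(chr1 = 5e5, chr2 = 5e5), nLoci = 10, seed = 51)
    peaks <- simPeakExperiments(g, nExperiments = 100, pHot = 0.6,
                                backgroundPerMb = 10, seed = 52)
    expect_length(peaks, 100L)
    summits <- poolSummits(peaks)
    hits <- countOverlaps(g$loci, summits, ignore.strand = TRUE)
    # 3-SD binomial band around 60 for >= 95% of loci
    expect_gte(mean(abs(hits - 60) <= 15), 0.95)
    # pHot = 0: planted loci sit at the background rate
    cold <- simPeakExperiments(g, nExperiments = 100, pHot = 0,
                               backgroundPerMb = 10, seed = 53)
    coldHits <- countOverlaps(g$loci, poolSummits(cold),
                              ignore.strand = TRUE)
    # background: 10/Mb * 100 experiments -> ~2 summits per 2 kb locus
    expect_lt(max(coldHits), 15)
    # determinism
    again <- simPeakExperiments(g, nExperiments = 100, pHot = 0.6,
                                backgroundPerMb = 10, seed = 52)
    expect_identical(as.data.frame(again[[5L]]),
                     as.data.frame(peaks[[5L]]))
})

test_that("simulated reads have exact library sizes and planted enrichment", {
    g <- simGenome(c(chr1 = 1e6), nLoci = 8, seed = 61)
    r <- simReads(g$loci, g$chromSizes, log2fc = 2,
                  ipLibrarySize = 3e5, controlLibrarySize = 3e5,
                  seed = 62)
    expect_length(r$ip, 3e5)
    expect_length(r$control, 3e5)
    enr <- regionLog2Enrichment(r$ip, r$control, g$loci)
    expect_equal(mean(enr$log2_ratio), 2, tolerance = 0.1)
    # planted log2fc = 0 centers on zero
    r0 <- simReads(g$loci, g$chromSizes, log2fc = 0,
                   ipLibrarySize = 3e5, controlLibrarySize = 3e5,
                   seed = 63)
    enr0 <- regionLog2Enrichment(r0$ip, r0$control, g$loci)
    expect_lt(abs(mean(enr0$log2_ratio)), 0.1)
    expect_error(simReads(g$loci, g$chromSizes, log2fc = Inf),
                 "finite")
})

test_that("simulated methylation matches its planted dispersion plan", {
    gr1 <- GRanges("chr1", IRanges(seq(1, by = 3000,
                                       length.out = 100), width = 2000))
    gr2 <- GenomicRanges::shift(gr1, 400000)
    plan <- data.frame(set = c("stable", "variable"),
                       median = c(0.05, 0.05), iqr = c(0.05, 0.18))
    m <- simMethylation(list(stable = gr1, variable = gr2),
                        planted = plan, nCellTypes = 5, seed = 71)
    expect_length(m$cells, 5L)
    # zero noise: every CpG equals its region mean
    m0 <- simMethylation(list(stable = gr1), plan[1L, ],
                         nCellTypes = 1, noiseSd = 0, seed = 72)
    means <- regionMeanMethylation(m0$cells[[1L]], gr1)
    calls <- m0$cells[[1L]]
    hits <- findOverlaps(gr1, calls)
    perCpG <- S4Vectors::mcols(calls)$fraction[
        S4Vectors::subjectHits(hits)]
    expect_equal(perCpG, means[S4Vectors::queryHits(hits)])
    # determinism
    mAgain <- simMethylation(list(stable = gr1, variable = gr2),
                             planted = plan, nCellTypes = 5, seed = 71)
    expect_identical(as.data.frame(mAgain$cells[[2L]]),
                     as.data.frame(m$cells[[2L]]))
    # fitted Beta parameters reproduce median and IQR
    for (i in 1:2) {
        p <- m$betaParams[[plan$set[i]]]
        q <- qbeta(c(0.25, 0.5, 0.75), p[["shape1"]], p[["shape2"]])
        expect_equal(q[2L], plan$median[i], tolerance = 1e-3)
        expect_equal(q[3L] - q[1L], plan$iqr[i], tolerance = 1e-3)
    }
})
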