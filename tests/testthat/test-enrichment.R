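test_that("region enrichment reproduces the CPM arithmetic", {
    regions <- GRanges("chr1", IRanges(1, 1000))
    ip <- GRanges("chr1", IRanges(seq(1, 900, length.out = 100),
                                  width = 36))
    ctrl <- GRanges("chr1", IRanges(seq(1, 900, length.out = 25),
                                    width = 36))
    # 100 vs 25 reads at equal library size: log2 = 2 as epsilon -> 0
    enr <- regionLog2Enrichment(ip, ctrl, regions,
        ipLibrarySize = 1e6, controlLibrarySize = 1e6,
        epsilon = 1e-9)
    expect_equal(enr$log2_ratio, 2, tolerance = 1e-6)
    expect_equal(enr$ip_cpm, 100)
    expect_equal(enr$control_cpm, 25)
    # identical IP and control -> exactly 0
    same <- regionLog2Enrichment(ip, ip, regions,
        ipLibrarySize = 1e6, controlLibrarySize = 1e6)
    expect_equal(same$log2_ratio, 0)
    # zero control reads: finite, monotone in the IP count
    far <- GRanges("chr1", IRanges(1e5, width = 36))
    e1 <- regionLog2Enrichment(ip[1:10], far, regions,
        ipLibrarySize = 1e6, controlLibrarySize = 1e6)
    e2 <- regionLog2Enrichment(ip[1:50], far, regions,
        ipLibrarySize = 1e6, controlLibrarySize = 1e6)
    expect_true(is.finite(e1$log2_ratio))
    expect_gt(e2$log2_ratio, e1$log2_ratio)
    expect_error(regionLog2Enrichment(ip, ctrl, GRanges()),
                 "non-empty")
    expect_error(regionLog2Enrichment(ip, ctrl, regions,
                                      ipLibrarySize = 0), "positive")
})

test_that("CPM is invariant to proportional library scaling", {
    counts <- c(10, 250, 3)
    expect_identical(cpmScale(counts, 1e6),
                     cpmScale(counts * 7, 7e6))
    expect_error(cpmScale(counts, 0), "positive")
})

test_that("the per-bp log2 track follows the elementwise formula", {
    flat <- IRanges::RleList(chr1 = S4Vectors::Rle(5, 1000))
    expect_true(all(perBpLog2Track(flat, flat) == 0))
    # ip = 2x control everywhere -> ~1 at epsilon -> 0
    double <- IRanges::RleList(chr1 = S4Vectors::Rle(10, 1000))
    tr <- perBpLog2Track(double, flat, epsilon = 1e-9)
    expect_equal(unique(as.numeric(tr[["chr1"]])), 1,
                 tolerance = 1e-6)
    # doubling both tracks changes nothing at epsilon -> 0
    tr2 <- perBpLog2Track(double * 2, flat * 2, epsilon = 1e-9)
    expect_equal(as.numeric(tr2[["chr1"]]), as.numeric(tr[["chr1"]]),
                 tolerance = 1e-6)
    # grid mismatch is an error
    other <- IRanges::RleList(chr2 = S4Vectors::Rle(5, 1000))
    expect_error(perBpLog2Track(flat, other), "grid mismatch")
    short <- IRanges::RleList(chr1 = S4Vectors::Rle(5, 999))
    expect_error(perBpLog2Track(flat, short), "grid mismatch")
})

test_that("stratified window sampling fills strata and records shortfall", {
    gr <- GRanges("chr1",
        IRanges(seq(1L, by = 3000L, length.out = 1000), width = 500),
        count = 1:1000)
    occ <- callHotRegions(gr, HotCallerParam())
    strata <- data.frame(lo = c(0, 75, 99), hi = c(75, 99, 100),
                         n = c(100, 100, 100))
    s <- stratifiedWindowSample(occ, strata, seed = 5)
    sf <- attr(s, "shortfall")
    expect_equal(sf$obtained, c(100L, 100L, 10L))  # top stratum has 10
    expect_equal(sum(sf$obtained), length(s))
    s2 <- stratifiedWindowSample(occ, strata, seed = 5)
    expect_identical(GenomicRanges::start(s2), GenomicRanges::start(s))
})

test_that("profile matrices equal brute-force bin means before winsorization", {
    # worked example: 100 bp window over values 1..100, 50 bins of 2 bp
    track <- IRanges::RleList(chr1 = S4Vectors::Rle(as.numeric(1:200)))
    win <- GRanges("chr1", IRanges(1, 100))
    pm <- profileMatrix(track, win, nbins = 50, winsor = NULL)
    expect_equal(as.numeric(pm), 2 * (1:50) - 0.5)
    # constant track -> constant matrix
    const <- IRanges::RleList(chr1 = S4Vectors::Rle(3.5, 5000))
    wins <- GRanges("chr1", IRanges(c(1, 1001, 2001), width = 1000))
    expect_true(all(profileMatrix(const, wins, winsor = NULL) == 3.5))
    # random tracks, bit-exact against the brute-force bin average
    set.seed(13)
    for (i in 1:20) {
        vals <- rnorm(2000)
        tr <- IRanges::RleList(chrR = S4Vectors::Rle(vals))
        w <- GRanges("chrR", IRanges(c(1, 501, 1001), width = 500))
        pm <- profileMatrix(tr, w, nbins = 50, winsor = NULL)
        for (j in 1:3) {
            expect_equal(unname(pm[j, ]),
                bruteBinMeans(vals[(GenomicRanges::start(w)[j]):
                                   (GenomicRanges::end(w)[j])], 50))
        }
    }
})

test_that("winsorization clips exactly at the matrix percentiles", {
    set.seed(29)
    vals <- rnorm(10000)
    tr <- IRanges::RleList(chrR = S4Vectors::Rle(vals))
    w <- GRanges("chrR", IRanges(seq(1, 9001, by = 500), width = 500))
    pre <- profileMatrix(tr, w, winsor = NULL)
    post <- profileMatrix(tr, w, winsor = c(0.5, 99))
    q <- quantile(pre, c(0.005, 0.99), type = 7, names = FALSE)
    expect_equal(max(post), q[2L])
    expect_equal(min(post), q[1L])
    expect_true(all(post >= q[1L] & post <= q[2L]))
    expect_equal(attr(post, "winsorLimits"), q)
})

test_that("stranded read extension follows the 200 bp rule with clipping", {
    reads <- GRanges("chr1",
        IRanges(c(101, 101, 101), width = c(36, 36, 200)),
        strand = c("+", "-", "+"))
    out <- extendReads(reads, 200, chromSizes = c(chr1 = 100000L))
    # + read [100,136) -> [100,300) in 0-based terms
    expect_equal(GenomicRanges::start(out)[1L] - 1L, 100L)
    expect_equal(GenomicRanges::end(out)[1L], 300L)
    # - read [100,136) -> end-200 < 0, clipped to [0,136)
    expect_equal(GenomicRanges::start(out)[2L] - 1L, 0L)
    expect_equal(GenomicRanges::end(out)[2L], 136L)
    # already 200 bp: unchanged
    expect_equal(GenomicRanges::width(out)[3L], 200L)
    expect_equal(GenomicRanges::start(out)[3L], 101L)
    # right-end clipping at the chromosome bound
    nearEnd <- GRanges("chr1", IRanges(99990, width = 5), strand = "+")
    clipped <- extendReads(nearEnd, 200, chromSizes = c(chr1 = 100000L))
    expect_equal(GenomicRanges::end(clipped), 100000L)
    expect_error(
        extendReads(GRanges("chr1", IRanges(1, 36), strand = "*")),
        "unstranded")
})

test_that("rank correlation behaves at the boundary cases", {
    expect_equal(scoreCorrelation(1:10, 1:10), 1)
    expect_equal(scoreCorrelation(1:10, 10:1), -1)
    expect_error(scoreCorrelation(1:2, 1:2), "at least 3")
    expect_warning(out <- scoreCorrelation(rep(1, 5), 1:5),
                   "constant")
    expect_true(is.na(out))
    # independent vectors have near-zero correlation
    set.seed(37)
    rhos <- vapply(1:50, function(i)
        scoreCorrelation(rnorm(1000), rnorm(1000)), numeric(1))
    expect_gte(mean(abs(rhos) < 0.1), 0.95)
})
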