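test_that("peak summits use the offset when present, midpoint otherwise", {
    gr <- GRanges("chr1", IRanges(rep(101, 3), rep(200, 3)),
                  peak = c(50L, -1L, 0L))
    # 0-based: start=100, end=200 -> offset 50 => 150; midpoint => 150;
    # offset 0 => 100
    expect_equal(GenomicRanges::start(peakSummits(gr)) - 1L,
                 c(150L, 150L, 100L))
    # midpoint fallback also applies when the column is absent
    noPeak <- GRanges("chr1", IRanges(101, 200))
    expect_equal(GenomicRanges::start(peakSummits(noPeak)) - 1L, 150L)
})

test_that("summit density matches the worked sliding-window example", {
    # summits at 0-based 1000, 1010, 3000; window [750, 1250) holds 2
    summits <- GRanges("chr1",
        IRanges(c(1000, 1010, 3000) + 1L, width = 1))
    param <- HotCallerParam(windowSize = 500, step = 50,
                            suppressionSpan = 1000)
    dens <- summitDensity(summits, c(chr1 = 10000L), param)
    win <- dens[GenomicRanges::start(dens) == 751L]
    expect_equal(S4Vectors::mcols(win)$count, 2L)
    # no summits -> all zero
    empty <- summitDensity(GRanges(), c(chr1 = 5000L), param)
    expect_true(all(S4Vectors::mcols(empty)$count == 0L))
    # one interior summit covers exactly windowSize/step windows
    one <- summitDensity(GRanges("chr1", IRanges(5001, width = 1)),
                         c(chr1 = 10000L), param)
    expect_equal(sum(S4Vectors::mcols(one)$count == 1L),
                 ceiling(param@windowSize / param@step))
})

test_that("summit density equals the brute-force window count on random genomes", {
    set.seed(42)
    for (i in 1:25) {
        len <- sample(2000:40000, 1L)
        step <- sample(c(50L, 100L, 250L), 1L)
        nSummits <- sample(0:80, 1L)
        pos <- sort(sample.int(len, nSummits, replace = TRUE))
        param <- HotCallerParam(windowSize = 500, step = step,
                                suppressionSpan = 1000)
        dens <- summitDensity(
            GRanges("chrS", IRanges(pos, width = 1)),
            c(chrS = len), param)
        expect_identical(S4Vectors::mcols(dens)$count,
                         bruteWindowCounts(pos, len, 500L, step))
    }
})

test_that("summits outside the declared genome are rejected naming the experiment", {
    s <- GRanges("chr1", IRanges(6001, width = 1), experiment = "expA")
    expect_error(summitDensity(s, c(chr1 = 5000L), HotCallerParam()),
                 "beyond chromosome length.*expA")
    s2 <- GRanges("chrX", IRanges(10, width = 1), experiment = "expB")
    expect_error(summitDensity(s2, c(chr1 = 5000L), HotCallerParam()),
                 "unknown chromosome.*expB")
})

test_that("local maxima keep the dominant window and suppress neighbours", {
    mk <- function(counts, step = 100L) {
        GRanges("chr1",
            IRanges(seq(1L, by = step, length.out = length(counts)),
                    width = 500),
            count = counts)
    }
    # single peak inside one span
    out <- localMaxima(mk(c(0L, 1L, 3L, 1L, 0L)), 2000)
    expect_length(out, 1L)
    expect_equal(S4Vectors::mcols(out)$count, 3L)
    # equal maxima within one span: leftmost retained
    out <- localMaxima(mk(c(0L, 2L, 0L, 2L, 0L)), 2000)
    expect_length(out, 1L)
    expect_equal(GenomicRanges::start(out), 101L)
    # all-zero track -> empty
    expect_length(localMaxima(mk(rep(0L, 5L)), 2000), 0L)
    # two peaks farther apart than the span both survive
    counts <- integer(60); counts[10] <- 5L; counts[50] <- 4L
    out <- localMaxima(mk(counts), 2000)
    expect_equal(S4Vectors::mcols(out)$count, c(5L, 4L))
})

test_that("local-maximum suppression is idempotent and dominance holds", {
    set.seed(7)
    for (i in 1:10) {
        counts <- as.integer(rpois(200, 0.7))
        dens <- GRanges("chr1",
            IRanges(seq(1L, by = 50L, length.out = 200), width = 500),
            count = counts)
        span <- sample(c(1000, 2000), 1L)
        out <- localMaxima(dens, span)
        again <- localMaxima(out, span)
        expect_identical(as.data.frame(again), as.data.frame(out))
        # every kept window dominates its +/- span/2 neighbourhood
        starts <- GenomicRanges::start(dens)
        for (j in seq_along(out)) {
            s <- GenomicRanges::start(out)[j]
            nb <- which(abs(starts - s) <= span / 2)
            expect_true(S4Vectors::mcols(out)$count[j] >=
                        max(counts[nb]))
        }
        if (length(out) > 1L)
            expect_true(all(diff(GenomicRanges::start(out)) > span / 2))
    }
})

test_that("percentile ranking labels exactly the top fraction HOT", {
    mk <- function(occ) {
        GRanges("chr1",
            IRanges(seq(1L, by = 5000L, length.out = length(occ)),
                    width = 500), count = occ)
    }
    # 200 regions, occupancies 1..200, threshold 99 -> top 2 HOT
    occ <- callHotRegions(mk(1:200), HotCallerParam())
    expect_equal(sum(regionLabel(occ) == "HOT"), 2L)
    expect_equal(occupancy(occ)[regionLabel(occ) == "HOT"],
                 c(199L, 200L))
    # all occupancies equal -> strict threshold labels none HOT
    tied <- callHotRegions(mk(rep(5L, 50L)), HotCallerParam())
    expect_equal(sum(regionLabel(tied) == "HOT"), 0L)
    # occupancies 1..4 at threshold 74: only occupancy 4 exceeds it
    four <- callHotRegions(mk(1:4), HotCallerParam(hotPercentile = 74,
                                                   mildPercentile = 50))
    expect_equal(occupancy(four)[regionLabel(four) == "HOT"], 4L)
    # empty input is an error
    none <- GRanges(count = integer(0))
    expect_error(callHotRegions(none, HotCallerParam()), "empty")
})

test_that("HOT count is bounded by the top percentile fraction plus ties", {
    set.seed(11)
    for (i in 1:10) {
        n <- sample(200:2000, 1L)
        occ <- as.integer(rpois(n, 3) + 1L)
        gr <- GRanges("chr1",
            IRanges(seq(1L, by = 2000L, length.out = n), width = 500),
            count = occ)
        called <- callHotRegions(gr, HotCallerParam())
        nHot <- sum(regionLabel(called) == "HOT")
        ties <- if (nHot > 0)
            sum(occ == min(occupancy(called)[
                regionLabel(called) == "HOT"])) else 0L
        expect_lte(nHot, ceiling(0.01 * n) + ties)
        # labels partition the regions
        expect_equal(sum(table(regionLabel(called))), n)
    }
})

test_that("percentile bins partition the regions with half-open edges", {
    gr <- GRanges("chr1",
        IRanges(seq(1L, by = 5000L, length.out = 100), width = 500),
        count = 1:100)
    occ <- callHotRegions(gr, HotCallerParam())
    bins <- binByPercentile(occ, c(75, 99))
    expect_equal(sum(vapply(bins, length, integer(1L))), 100L)
    expect_named(bins, c("[0,75)", "[75,99)", "[99,100]"))
    # a region exactly at percentile 75 belongs to the middle bin
    pct <- percentileRank(occ)
    mid <- bins[["[75,99)"]]
    expect_true(all(percentileRank(mid) >= 75 &
                    percentileRank(mid) < 99))
    low <- bins[["[0,75)"]]
    expect_true(all(percentileRank(low) < 75))
    expect_error(binByPercentile(occ, c(99, 75)), "increasing")
})
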