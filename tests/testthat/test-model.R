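test_that("control sampling respects the percentile ceiling and the seed", {
    gr <- GRanges("chr1",
        IRanges(seq(1L, by = 5000L, length.out = 100), width = 500),
        count = 1:100)
    occ <- callHotRegions(gr, HotCallerParam())
    ctrl <- sampleControls(occ, 4, ceilingPercentile = 85, seed = 3)
    expect_length(ctrl, 4L)
    expect_true(all(percentileRank(ctrl) < 85))
    ctrl2 <- sampleControls(occ, 4, ceilingPercentile = 85, seed = 3)
    expect_identical(regionRanges(ctrl2), regionRanges(ctrl))
    expect_error(sampleControls(occ, 95, ceilingPercentile = 85),
                 "pool too small.*8[0-9] regions")
})

test_that("CpG-matched sampling reproduces the HOT island-overlap fraction", {
    mkRegions <- function(n, chrom = "chr1", by = 3000L)
        GRanges(chrom, IRanges(seq(1L, by = by, length.out = n),
                               width = 500))
    hot <- mkRegions(100)
    cgi <- hot[1:90] + 10     # islands over 90% of HOT regions
    pool <- mkRegions(400, by = 3000L)
    pool <- GenomicRanges::shift(pool, 400000L)
    poolCgi <- pool[1:200] + 10
    allCgi <- c(cgi, poolCgi)
    ctrl <- cpgMatchedSampling(hot, pool, allCgi, seed = 9)
    expect_length(ctrl, length(hot))
    expect_equal(sum(overlapsAny(ctrl, allCgi)), 90L, tolerance = 0)
    # zero HOT overlap: plain uniform sampling still works
    hotFar <- GenomicRanges::shift(mkRegions(20), 2000000L)
    ctrl0 <- cpgMatchedSampling(hotFar, pool, allCgi, seed = 9)
    expect_length(ctrl0, 20L)
    # pool without island overlap but HOT fraction > 0 is an error
    poolBare <- GenomicRanges::shift(mkRegions(150), 4000000L)
    expect_error(cpgMatchedSampling(hot, poolBare, allCgi, seed = 9),
                 "90 required, 0 available")
})

test_that("the elastic net separates planted signal and fails on noise", {
    set.seed(17)
    n <- 200
    x <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, sprintf("f%02d", 1:20)))
    y <- x[, 1] + rnorm(n, sd = 0.2) > 0
    labels <- ifelse(y, "HOT", "CONTROL")
    fit <- trainElasticNet(x, labels, seed = 1)
    expect_gte(fit@cvAUC, 0.95)
    expect_true(abs(coef(fit)[["f01"]]) ==
                max(abs(coef(fit))))
    # permuted labels carry no information
    aucNull <- vapply(1:5, function(s) {
        perm <- sample(labels)
        trainElasticNet(x, perm, seed = s)@cvAUC
    }, numeric(1))
    expect_true(all(abs(aucNull - 0.5) <= 0.12))
    expect_lte(abs(mean(aucNull) - 0.5), 0.1)
    # all-constant features -> chance AUC, zero coefficients
    const <- matrix(1, n, 5, dimnames = list(NULL, paste0("c", 1:5)))
    fit0 <- trainElasticNet(const, labels, seed = 1)
    expect_equal(fit0@cvAUC, 0.5)
    expect_true(all(coef(fit0) == 0))
    # degenerate labels are an error
    expect_error(trainElasticNet(x, rep("HOT", n), seed = 1),
                 "degenerate")
})

test_that("fold AUC agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(23)
    scores <- rnorm(150)
    pos <- runif(150) < plogis(scores * 1.5)
    ours <- hotRegions:::.rankAUC(scores, pos)
    theirs <- as.numeric(pROC::auc(pROC::roc(
        response = pos, predictor = scores, quiet = TRUE,
        direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("importance scaling and cross-model averaging follow the 0-100 rule", {
    fit <- new("HotElasticNet",
        coefficients = c(a = -2, b = 1, c = 0), intercept = 0,
        alpha = 0.5, lambda = 0.1, cvAUC = 0.9,
        foldAUC = rep(0.9, 10), nfolds = 10L, seed = 1L)
    imp <- variableImportance(fit)
    expect_equal(unname(imp[c("a", "b", "c")]), c(100, 50, 0))
    # invariant to positive rescaling of the coefficients
    fit2 <- initialize(fit, coefficients = fit@coefficients * 7.3)
    expect_equal(variableImportance(fit2), imp)
    # single nonzero coefficient -> that feature is 100
    fit3 <- initialize(fit, coefficients = c(a = 0, b = 0.01, c = 0))
    expect_equal(unname(variableImportance(fit3)[["b"]]), 100)
    # all-zero -> all zero
    fit4 <- initialize(fit, coefficients = c(a = 0, b = 0, c = 0))
    expect_true(all(variableImportance(fit4) == 0))

    avg <- averageImportance(list(c(a = 100, b = 0), c(a = 50, b = 50)))
    expect_equal(unname(avg[c("a", "b")]), c(75, 25))
    expect_equal(averageImportance(list(c(a = 30, b = 60))),
                 c(a = 30, b = 60))
    # a feature missing from one table counts as 0 there
    half <- averageImportance(list(c(a = 100), c(b = 40)))
    expect_equal(unname(half[c("a", "b")]), c(50, 20))
    expect_error(averageImportance(list()), "at least one")
    expect_equal(topFeatures(c(z = 50, a = 50, m = 80), k = 2),
                 c("m", "a"))   # lexicographic tie-break
})

test_that("PCA on top features separates planted classes", {
    ps <- plantedFeatureSet()
    fit <- trainElasticNet(ps$features, ps$labels, seed = 2)
    top <- topFeatures(variableImportance(fit))
    pca <- pcaTopFeatures(ps$features, top, labels = ps$labels,
                          seed = 4)
    expect_equal(ncol(pca$scores), 2L)
    expect_equal(sum(pca$explained), 1, tolerance = 1e-9)
    hotPc1 <- pca$scores[pca$labels == "HOT", 1L]
    coldPc1 <- pca$scores[pca$labels == "CONTROL", 1L]
    pooledSd <- sqrt((var(hotPc1) + var(coldPc1)) / 2)
    expect_gt(abs(mean(hotPc1) - mean(coldPc1)), 2 * pooledSd)
    # identical rows -> zero variance -> error
    flat <- matrix(1, 10, 3, dimnames = list(NULL, c("x", "y", "z")))
    expect_error(pcaTopFeatures(flat, c("x", "y")), "zero variance")
    expect_error(pcaTopFeatures(ps$features, "not_a_feature"),
                 "absent")
})
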