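#' Sample control regions below an occupancy ceiling
#'
#' Uniform sample without replacement from the regions whose occupancy
#' percentile is strictly below \code{ceilingPercentile}, reproducible
#' under \code{seed}. Typically \code{n} is the number of HOT regions.
#'
#' @param regions an \linkS4class{OccupancyRegions}.
#' @param n number of controls to draw.
#' @param ceilingPercentile occupancy-percentile ceiling for the
#'   control pool (default 85).
#' @param seed integer seed, or \code{NULL} to use the current RNG
#'   stream.
#' @return an \code{OccupancyRegions} subset of size \code{n}.
#' @export
sampleControls <- function(regions, n, ceilingPercentile = 85,
                           seed = NULL) {
    pool <- which(percentileRank(regions) < ceilingPercentile)
    if (length(pool) < n)
        stop(sprintf("control pool too small: %d regions below the %gth percentile, %d requested",
                     length(pool), ceilingPercentile, n))
    picked <- .withSeed(seed, sample(pool, n))
    regions[sort(picked)]
}

#' CpG-island-matched control sampling
#'
#' Samples controls from the pool so that the fraction of controls
#' overlapping a CpG island equals the fraction among the HOT regions
#' (to within rounding of one region), removing CpG-island overlap as
#' a trivial discriminator.
#'
#' @param hot \code{GRanges} (or \code{OccupancyRegions}) of HOT
#'   regions.
#' @param pool \code{GRanges} (or \code{OccupancyRegions}) of eligible
#'   control regions (e.g. below the 85th occupancy percentile).
#' @param cgi \code{GRanges} of CpG island intervals.
#' @param seed integer seed or \code{NULL}.
#' @return controls of the same class as \code{pool}, as many as there
#'   are HOT regions.
#' @export
cpgMatchedSampling <- function(hot, pool, cgi, seed = NULL) {
    hotGr <- if (is(hot, "OccupancyRegions")) regionRanges(hot) else hot
    poolGr <- if (is(pool, "OccupancyRegions")) regionRanges(pool) else pool
    n <- length(hotGr)
    if (n == 0L)
        stop("no HOT regions to match")
    hotIn <- IRanges::overlapsAny(hotGr, cgi, ignore.strand = TRUE)
    nCgi <- round(mean(hotIn) * n)
    poolIn <- IRanges::overlapsAny(poolGr, cgi, ignore.strand = TRUE)
    inIdx <- which(poolIn)
    outIdx <- which(!poolIn)
    if (length(inIdx) < nCgi)
        stop(sprintf("insufficient CpG-island-overlapping controls: %d required, %d available",
                     nCgi, length(inIdx)))
    if (length(outIdx) < n - nCgi)
        stop(sprintf("insufficient non-CpG-island controls: %d required, %d available",
                     n - nCgi, length(outIdx)))
    picked <- .withSeed(seed, {
        c(if (nCgi > 0L) sample(inIdx, nCgi) else integer(),
          if (n - nCgi > 0L) sample(outIdx, n - nCgi) else integer())
    })
    pool[sort(picked)]
}

#' Train the elastic-net HOT discriminator
#'
#' Fits a penalized logistic regression (elastic-net penalty, mixing
#' parameter \code{alpha}) of HOT versus control labels on a
#' standardized feature matrix, with class-stratified k-fold
#' cross-validation. The penalty \code{lambda} is chosen at the CV
#' deviance minimum; accuracy is reported as the mean out-of-fold
#' rank-based (Mann-Whitney) AUC.
#'
#' @param x a standardized \linkS4class{RegionFeatureMatrix} or plain
#'   numeric matrix (rows = regions, named columns). An
#'   unstandardized \code{RegionFeatureMatrix} is standardized first.
#' @param labels factor/character/logical per row: \code{"HOT"} (or
#'   \code{TRUE}) versus control.
#' @param alpha elastic-net mixing parameter in [0, 1] (default 0.5;
#'   1 = lasso, 0 = ridge).
#' @param nfolds number of CV folds (default 10).
#' @param seed integer seed for the stratified fold assignment.
#' @return a \linkS4class{HotElasticNet}.
#' @details Both classes must be present with at least \code{nfolds}
#'   rows each. If every feature column is constant the model is
#'   intercept-only with all coefficients 0 and cvAUC 0.5 (no
#'   information).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 5), 200, 5,
#'             dimnames = list(NULL, paste0("f", 1:5)))
#' y <- x[, 1] + rnorm(200, sd = 0.3) > 0  # feature f1 carries signal
#' fit <- trainElasticNet(x, ifelse(y, "HOT", "CONTROL"), seed = 1)
#' fit
#' @export
trainElasticNet <- function(x, labels, alpha = 0.5, nfolds = 10,
                            seed = 1) {
    if (is(x, "RegionFeatureMatrix")) {
        if (!x@standardized)
            x <- standardizeFeatureMatrix(x)
        mat <- x@features
    } else {
        mat <- as.matrix(x)
    }
    if (is.null(colnames(mat)))
        stop("feature columns must be named")
    pos <- if (is.logical(labels)) labels else
        as.character(labels) == "HOT"
    if (length(pos) != nrow(mat))
        stop("labels must have one entry per feature-matrix row")
    if (all(pos) || all(!pos))
        stop("degenerate labels: both HOT and control rows are required")
    if (min(sum(pos), sum(!pos)) < nfolds)
        stop(sprintf("each class needs at least %d rows for %d-fold CV",
                     nfolds, nfolds))
    featNames <- colnames(mat)
    constant <- apply(mat, 2L, function(col) max(col) - min(col) == 0)
    if (all(constant)) {
        # no usable information: intercept-only model
        p <- mean(pos)
        return(new("HotElasticNet",
            coefficients = setNames(numeric(ncol(mat)), featNames),
            intercept = log(p / (1 - p)), alpha = alpha,
            lambda = Inf, cvAUC = 0.5,
            foldAUC = rep(0.5, nfolds), nfolds = as.integer(nfolds),
            seed = as.integer(seed)))
    }
    foldid <- .withSeed(seed, .stratifiedFolds(pos, nfolds))
    cvfit <- glmnet::cv.glmnet(mat, factor(pos, levels = c(FALSE, TRUE)),
        family = "binomial", alpha = alpha, foldid = foldid,
        type.measure = "deviance", keep = TRUE, standardize = FALSE)
    iMin <- which.min(cvfit$cvm)
    preval <- cvfit$fit.preval[, iMin]
    foldAUC <- vapply(seq_len(nfolds), function(k) {
        sel <- foldid == k
        .rankAUC(preval[sel], pos[sel])
    }, numeric(1L))
    cf <- as.matrix(coef(cvfit, s = cvfit$lambda[iMin]))
    new("HotElasticNet",
        coefficients = setNames(cf[featNames, 1L], featNames),
        intercept = cf["(Intercept)", 1L],
        alpha = alpha, lambda = cvfit$lambda[iMin],
        cvAUC = mean(foldAUC, na.rm = TRUE), foldAUC = foldAUC,
        nfolds = as.integer(nfolds), seed = as.integer(seed))
}

# Class-stratified fold labels 1..nfolds (call inside .withSeed).
.stratifiedFolds <- function(pos, nfolds) {
    foldid <- integer(length(pos))
    for (cls in c(TRUE, FALSE)) {
        idx <- which(pos == cls)
        foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    foldid
}

#' Variable importance of a fitted discriminator
#'
#' The absolute value of each coefficient scaled so the largest equals
#' 100. All-zero coefficient vectors give all-zero scores. The scaling
#' is invariant to multiplying every coefficient by a positive
#' constant.
#'
#' @param fit a \linkS4class{HotElasticNet}.
#' @return named numeric vector of scores in [0, 100].
#' @examples
#' \dontrun{variableImportance(fit)}
#' @export
variableImportance <- function(fit) {
    v <- abs(coef(fit))
    m <- max(v)
    if (m == 0)
        return(v)
    100 * v / m
}

#' Average importance across species-specific models
#'
#' Per-feature arithmetic mean over the union of feature names; a
#' feature absent from a table contributes 0 for that table.
#'
#' @param tables a non-empty list of named importance vectors (from
#'   \code{\link{variableImportance}}).
#' @return named numeric vector over the union of features.
#' @export
averageImportance <- function(tables) {
    if (!length(tables))
        stop("at least one importance table is required")
    feats <- Reduce(union, lapply(tables, names))
    acc <- setNames(numeric(length(feats)), feats)
    for (tab in tables)
        acc[names(tab)] <- acc[names(tab)] + tab
    acc / length(tables)
}

#' Top-k features by importance
#'
#' @param importance named importance vector.
#' @param k number of features (default 10).
#' @return character vector of feature names, sorted by descending
#'   score with lexicographic tie-break.
#' @export
topFeatures <- function(importance, k = 10) {
    o <- order(-importance, names(importance))
    names(importance)[o][seq_len(min(k, length(importance)))]
}

#' PCA on the top discriminative features
#'
#' Principal components of the standardized submatrix restricted to
#' the given features, used to visualize HOT/COLD separation. When
#' \code{labels} are supplied with \code{balance = TRUE}, the larger
#' class is subsampled to the size of the smaller before the PCA (the
#' usual HOT-versus-COLD display).
#'
#' @param x a \linkS4class{RegionFeatureMatrix} or matrix.
#' @param features feature names to use (e.g. from
#'   \code{\link{topFeatures}}); all must be present.
#' @param labels optional per-row class labels.
#' @param balance subsample the larger class to the smaller
#'   (default \code{TRUE} when labels are given).
#' @param seed integer seed for the subsampling.
#' @return a list with \code{scores} (n x 2 matrix of PC1/PC2
#'   coordinates), \code{explained} (variance fractions, all
#'   components; sums to 1) and \code{labels} (possibly subsampled).
#' @export
pcaTopFeatures <- function(x, features, labels = NULL, balance = TRUE,
                           seed = NULL) {
    mat <- if (is(x, "RegionFeatureMatrix")) x@features else as.matrix(x)
    missing <- setdiff(features, colnames(mat))
    if (length(missing))
        stop("features absent from the matrix: ",
             paste(missing, collapse = ", "))
    keep <- seq_len(nrow(mat))
    if (!is.null(labels) && balance) {
        labels <- as.character(labels)
        tab <- table(labels)
        nMin <- min(tab)
        keep <- .withSeed(seed, {
            unlist(lapply(names(tab), function(cl) {
                idx <- which(labels == cl)
                if (length(idx) > nMin) sort(sample(idx, nMin)) else idx
            }))
        })
        labels <- labels[keep]
    }
    sub <- mat[keep, features, drop = FALSE]
    if (nrow(sub) < 3L)
        stop("need at least 3 rows for a 2-component PCA")
    sub <- standardizeFeatureMatrix(sub)
    if (all(abs(sub) < 1e-12))
        stop("zero variance in every selected feature: PCA undefined")
    pc <- prcomp(sub, center = TRUE, scale. = FALSE)
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    list(scores = pc$x[, 1:2, drop = FALSE], explained = expl,
         labels = labels)
}

#' Serialize a fitted discriminator to JSON
#'
#' @param fit a \linkS4class{HotElasticNet}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeModelJson <- function(fit, path) {
    obj <- list(
        alpha = fit@alpha, lambda = fit@lambda,
        cv_auc = fit@cvAUC, fold_auc = fit@foldAUC,
        nfolds = fit@nfolds, seed = fit@seed,
        intercept = fit@intercept,
        coefficients = as.list(coef(fit)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
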