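#' Pipeline configuration
#'
#' Collects paths and parameters for \code{\link{runHotPipeline}}.
#' Every constant of the analysis surfaces here with its standard
#' default: 500 bp windows, 2000 bp suppression span, the 99th HOT
#' percentile, the 85th-percentile control ceiling, elastic-net
#' mixing 0.5 with 10-fold CV, pseudocount 1 CPM, 3000 windows per
#' occupancy stratum, 50 profile bins winsorized at the 0.5th/99th
#' percentiles, and 200 bp stranded read extension.
#'
#' @param outdir output directory (created if needed).
#' @param peakDir directory of narrowPeak files (one experiment per
#'   file); required for the calling stage.
#' @param genomeFasta genome FASTA path (enables the feature/model
#'   stage).
#' @param chromSizesPath two-column chrom.sizes path (required).
#' @param cgiBed CpG-island BED path (enables CpG-matched sampling
#'   and the methylation comparison).
#' @param readPairs data.frame with columns \code{id}, \code{ip},
#'   \code{control} (BED paths) and optional \code{kind}
#'   (input/IgG/RNaseH); enables the enrichment stage.
#' @param methylationDir directory of per-cell-type bedGraph tables
#'   (enables the methylation stage).
#' @param param a \linkS4class{HotCallerParam}.
#' @param featureWindow sequence window for featurization (2000 bp).
#' @param alpha,nfolds elastic-net settings.
#' @param epsilon enrichment pseudocount in CPM units.
#' @param strata occupancy strata for window sampling.
#' @param winsor winsorization percentiles for profile matrices.
#' @param extendTo stranded read-extension length in bp.
#' @param seed master seed; every stochastic step derives from it.
#' @return a list of class \code{HotPipelineConfig}.
#' @export
hotPipelineConfig <- function(outdir,
        peakDir = NULL, genomeFasta = NULL, chromSizesPath = NULL,
        cgiBed = NULL, readPairs = NULL, methylationDir = NULL,
        param = HotCallerParam(), featureWindow = 2000,
        alpha = 0.5, nfolds = 10, epsilon = 1,
        strata = data.frame(lo = c(0, 75, 99), hi = c(75, 99, 100),
                            n = 3000),
        winsor = c(0.5, 99), extendTo = 200, seed = 1) {
    cfg <- list(outdir = outdir, peakDir = peakDir,
                genomeFasta = genomeFasta,
                chromSizesPath = chromSizesPath, cgiBed = cgiBed,
                readPairs = readPairs, methylationDir = methylationDir,
                param = param, featureWindow = featureWindow,
                alpha = alpha, nfolds = nfolds, epsilon = epsilon,
                strata = strata, winsor = winsor, extendTo = extendTo,
                seed = as.integer(seed))
    class(cfg) <- "HotPipelineConfig"
    cfg
}

#' Generate a complete synthetic input bundle
#'
#' Writes a seeded synthetic data set in exactly the formats the
#' pipeline consumes - genome FASTA, chrom.sizes, a directory of
#' narrowPeak pseudo-experiments whose summits concentrate at planted
#' loci, CpG-island BED (planted HOT loci plus decoy CpG islands
#' without summit enrichment), IP/control read BEDs with a planted
#' log2 fold change over the HOT loci, and per-cell-type methylation
#' tables with planted stable hypomethylation at HOT loci versus
#' variable methylation at decoy islands - together with the ground
#' truth, so a full run is verifiable without downloads.
#'
#' @param outdir directory to write the bundle into.
#' @param chromLengths named chromosome lengths (default five 1 Mb
#'   chromosomes).
#' @param nHotLoci planted HOT loci (default 30).
#' @param nDecoyCgi decoy CpG-island loci without peak enrichment
#'   (default 60).
#' @param nExperiments,pHot,jitterSd,backgroundPerMb,peakWidth see
#'   \code{\link{simPeakExperiments}}.
#' @param log2fc,ipLibrarySize,controlLibrarySize,readLength see
#'   \code{\link{simReads}}.
#' @param nCellTypes,cpgPerRegion,noiseSd see
#'   \code{\link{simMethylation}}.
#' @param methylationPlan data.frame of planted methylation
#'   median/IQR per region set (\code{hot}, \code{decoy_cgi},
#'   \code{background}); the default plants a stable-hypomethylated
#'   HOT set (median 0.05, IQR 0.05) against variable decoy islands
#'   (median 0.05, IQR 0.18) - a 3.6-fold dispersion ratio.
#' @param seed master seed.
#' @return invisibly, a list with the written \code{paths}, the
#'   \code{truth} objects and the generator parameters.
#' @export
simulateBundle <- function(outdir,
        chromLengths = setNames(rep(1e6, 5), paste0("chr", 1:5)),
        nHotLoci = 30, nDecoyCgi = 60,
        nExperiments = 100, pHot = 0.6, jitterSd = 50,
        backgroundPerMb = 10, peakWidth = 200,
        log2fc = 2, ipLibrarySize = 1e6, controlLibrarySize = 1e6,
        readLength = 36,
        nCellTypes = 10, cpgPerRegion = 10, noiseSd = 0.02,
        methylationPlan = data.frame(
            set = c("hot", "decoy_cgi", "background"),
            median = c(0.05, 0.05, 0.80),
            iqr = c(0.05, 0.18, 0.10)),
        seed = 1) {
    if (nExperiments < 1L)
        stop("nExperiments must be >= 1")
    if (nHotLoci < 1L)
        stop("nHotLoci must be >= 1")
    if (pHot < 0 || pHot > 1)
        stop("pHot must lie in [0, 1]")
    chromLengths <- setNames(as.integer(chromLengths),
                             names(chromLengths))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
    dir.create(file.path(outdir, "methylation"), showWarnings = FALSE)

    g <- simGenome(chromLengths, nLoci = nHotLoci + nDecoyCgi,
                   seed = seed)
    isHot <- .withSeed(seed + 1L, {
        sample(c(rep(TRUE, nHotLoci),
                 rep(FALSE, length(g$loci) - nHotLoci)))
    })
    hotLoci <- g$loci[isHot]
    decoyCgi <- g$loci[!isHot]

    peaks <- simPeakExperiments(
        list(chromSizes = chromLengths, loci = hotLoci),
        nExperiments = nExperiments, pHot = pHot, jitterSd = jitterSd,
        backgroundPerMb = backgroundPerMb, peakWidth = peakWidth,
        seed = seed + 2L)
    reads <- simReads(hotLoci, chromLengths, log2fc = log2fc,
                      ipLibrarySize = ipLibrarySize,
                      controlLibrarySize = controlLibrarySize,
                      readLength = readLength, seed = seed + 3L)
    background <- .withSeed(seed + 4L, {
        .placeLoci(chromLengths, nHotLoci + nDecoyCgi, 2000L)
    })
    background <- background[
        !IRanges::overlapsAny(background, g$loci, ignore.strand = TRUE)]
    meth <- simMethylation(
        list(hot = hotLoci, decoy_cgi = decoyCgi,
             background = background),
        planted = methylationPlan, nCellTypes = nCellTypes,
        cpgPerRegion = cpgPerRegion, noiseSd = noiseSd,
        seed = seed + 5L)

    paths <- list(
        genomeFasta = file.path(outdir, "genome.fa"),
        chromSizes = file.path(outdir, "chrom.sizes"),
        peakDir = file.path(outdir, "peaks"),
        cgiBed = file.path(outdir, "cgi.bed"),
        ipBed = file.path(outdir, "ip.bed"),
        controlBed = file.path(outdir, "control.bed"),
        methylationDir = file.path(outdir, "methylation"),
        truthLoci = file.path(outdir, "truth_hot_loci.bed"),
        truthJson = file.path(outdir, "truth.json"))
    Biostrings::writeXStringSet(g$genome, paths$genomeFasta)
    writeChromSizes(chromLengths, paths$chromSizes)
    for (id in names(peaks))
        writeNarrowPeak(peaks[[id]],
            file.path(paths$peakDir, paste0(id, ".narrowPeak")))
    writeBed(g$loci, paths$cgiBed)
    writeBed(reads$ip, paths$ipBed)
    writeBed(reads$control, paths$controlBed)
    for (ct in names(meth$cells))
        writeMethylationBedGraph(meth$cells[[ct]],
            file.path(paths$methylationDir, paste0(ct, ".bedGraph")))
    writeBed(hotLoci, paths$truthLoci)
    jsonlite::write_json(list(
        seed = seed, chromLengths = as.list(chromLengths),
        nHotLoci = nHotLoci, nDecoyCgi = nDecoyCgi,
        nExperiments = nExperiments, pHot = pHot,
        jitterSd = jitterSd, backgroundPerMb = backgroundPerMb,
        log2fc = log2fc, nCellTypes = nCellTypes,
        methylationPlan = methylationPlan),
        paths$truthJson, auto_unbox = TRUE, digits = NA)
    invisible(list(paths = paths,
                   truth = list(hotLoci = hotLoci, decoyCgi = decoyCgi,
                                background = background,
                                reads = reads$truth,
                                methylation = meth$planted),
                   genome = g))
}

#' Run the full HOT-region pipeline
#'
#' Executes call -> features/model -> enrichment -> methylation in
#' order, skipping any stage whose inputs are absent from the
#' configuration, and writes a manifest listing every output file
#' with its MD5 checksum. Reruns with the same configuration and seed
#' produce identical checksums.
#'
#' @param config a \code{\link{hotPipelineConfig}}.
#' @return invisibly, a list with \code{regions} (the
#'   \linkS4class{OccupancyRegions}), \code{model} (fit or
#'   \code{NULL}), \code{manifest} (data.frame file/md5) and
#'   \code{skipped} (character vector of skipped stages).
#' @export
runHotPipeline <- function(config) {
    stopifnot(inherits(config, "HotPipelineConfig"))
    outdir <- config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(outdir, "pipeline.log")
    cat(sprintf("[%s] pipeline start (seed %d)\n",
                format(Sys.time()), config$seed),
        file = logPath)
    outputs <- character()
    skipped <- character()
    note <- function(fmt, ...) {
        line <- sprintf(fmt, ...)
        cat(sprintf("[%s] %s\n", format(Sys.time()), line),
            file = logPath, append = TRUE)
        message(line)
    }
    stage <- function(name, fun) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(fun(), error = function(e) {
            note("stage %s FAILED: %s", name, conditionMessage(e))
            .writeManifest(outputs, outdir)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE)
        })
        note("stage %s done in %.1f s", name,
             proc.time()[["elapsed"]] - t0)
        res
    }

    if (is.null(config$peakDir) || is.null(config$chromSizesPath))
        stop("peakDir and chromSizesPath are required for the calling stage")
    regions <- stage("call", function() {
        chromSizes <- readChromSizes(config$chromSizesPath)
        files <- sort(list.files(config$peakDir,
            pattern = "\\.(narrowPeak|bed)$", full.names = TRUE))
        if (!length(files))
            stop("no narrowPeak files in ", config$peakDir)
        peakSets <- lapply(files, readNarrowPeak)
        names(peakSets) <- sub("\\.(narrowPeak|bed)$", "",
                               basename(files))
        summits <- poolSummits(peakSets)
        dens <- summitDensity(summits, chromSizes, config$param)
        maxima <- localMaxima(dens, config$param@suppressionSpan)
        occ <- callHotRegions(maxima, config$param)
        outputs <<- c(outputs,
            writeRegionsBed(occ, file.path(outdir, "regions.bed")),
            writeRegionsTsv(occ, file.path(outdir, "regions.tsv")))
        occ
    })

    model <- NULL
    if (!is.null(config$genomeFasta)) {
        model <- stage("model", function() {
            genome <- Biostrings::readDNAStringSet(config$genomeFasta)
            names(genome) <- sub("\\s.*$", "", names(genome))
            hot <- regions[regionLabel(regions) == "HOT"]
            nHot <- length(hot)
            if (nHot < config$nfolds)
                stop(sprintf("only %d HOT regions: too few to train", nHot))
            pool <- regions[percentileRank(regions) <
                            config$param@controlCeiling]
            controls <- if (!is.null(config$cgiBed)) {
                cgi <- readBed(config$cgiBed)
                cpgMatchedSampling(hot, pool, cgi,
                                   seed = config$seed + 10L)
            } else {
                sampleControls(regions, nHot,
                               config$param@controlCeiling,
                               seed = config$seed + 10L)
            }
            fm <- buildFeatureMatrix(
                c(regionRanges(hot), regionRanges(controls)),
                genome, window = config$featureWindow)
            labels <- rep(c("HOT", "CONTROL"),
                          c(nHot, length(controls)))
            fit <- trainElasticNet(standardizeFeatureMatrix(fm),
                labels, alpha = config$alpha,
                nfolds = config$nfolds, seed = config$seed + 11L)
            imp <- variableImportance(fit)
            impPath <- file.path(outdir, "importance.tsv")
            write.table(data.frame(feature = names(imp),
                                   importance = imp),
                        impPath, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            outputs <<- c(outputs,
                writeModelJson(fit, file.path(outdir, "model.json")),
                impPath)
            fit
        })
    } else skipped <- c(skipped, "model")

    if (!is.null(config$readPairs) && nrow(config$readPairs)) {
        stage("enrich", function() {
            chromSizes <- readChromSizes(config$chromSizesPath)
            for (i in seq_len(nrow(config$readPairs))) {
                id <- config$readPairs$id[i]
                kind <- if ("kind" %in% names(config$readPairs))
                    config$readPairs$kind[i] else "input"
                ip <- readBed(config$readPairs$ip[i])
                ctrl <- readBed(config$readPairs$control[i])
                enr <- regionLog2Enrichment(ip, ctrl, regions,
                    epsilon = config$epsilon, controlKind = kind)
                enrPath <- file.path(outdir,
                    sprintf("enrichment_%s.tsv", id))
                write.table(enr, enrPath, sep = "\t", quote = FALSE,
                            row.names = FALSE)
                summ <- stratumSummary(enr, percentileRank(regions))
                summPath <- file.path(outdir,
                    sprintf("enrichment_%s_strata.tsv", id))
                write.table(summ, summPath, sep = "\t",
                            quote = FALSE, row.names = FALSE)
                windows <- stratifiedWindowSample(regions,
                    strata = config$strata, seed = config$seed + 20L)
                windows <- suppressWarnings(GenomicRanges::resize(
                    windows, config$featureWindow, fix = "center"))
                track <- perBpLog2Track(
                    coverageCpm(ip, chromSizes),
                    coverageCpm(ctrl, chromSizes),
                    epsilon = config$epsilon)
                pm <- profileMatrix(track, windows,
                                    winsor = config$winsor)
                pmPath <- file.path(outdir,
                    sprintf("profile_%s.tsv", id))
                write.table(round(pm, 6), pmPath, sep = "\t",
                            quote = FALSE, row.names = FALSE)
                outputs <<- c(outputs, enrPath, summPath, pmPath)
            }
            NULL
        })
    } else skipped <- c(skipped, "enrich")

    if (!is.null(config$methylationDir) &&
        dir.exists(config$methylationDir) &&
        !is.null(config$cgiBed)) {
        stage("methyl", function() {
            files <- sort(list.files(config$methylationDir,
                pattern = "\\.(bedGraph|bedgraph|tsv)$",
                full.names = TRUE))
            if (!length(files))
                stop("no methylation tables in ",
                     config$methylationDir)
            calls <- lapply(files, readMethylationBedGraph)
            names(calls) <- sub("\\.[^.]*$", "", basename(files))
            hot <- hotRegions(regions)
            cgi <- readBed(config$cgiBed)
            sets <- list(hot = hot,
                         nonhot_cgi = nonHotCgi(cgi, hot))
            tab <- methylationSummaryTable(sets, calls)
            tabPath <- file.path(outdir, "methylation_summary.tsv")
            write.table(tab, tabPath, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            cmp <- hotVsNonhotCgi(tab[tab$set == "hot", ],
                                  tab[tab$set == "nonhot_cgi", ])
            cmpPath <- file.path(outdir, "methylation_comparison.tsv")
            write.table(cmp$table, cmpPath, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            ratioPath <- file.path(outdir, "methylation_iqr_ratio.txt")
            writeLines(format(cmp$iqr_ratio, digits = 15), ratioPath)
            outputs <<- c(outputs, tabPath, cmpPath, ratioPath)
            NULL
        })
    } else skipped <- c(skipped, "methyl")

    if (length(skipped))
        note("skipped stages: %s", paste(skipped, collapse = ", "))
    manifest <- .writeManifest(outputs, outdir)
    note("pipeline complete: %d output files", nrow(manifest))
    invisible(list(regions = regions, model = model,
                   manifest = manifest, skipped = skipped))
}

.writeManifest <- function(outputs, outdir) {
    manifest <- data.frame(
        file = basename(outputs),
        md5 = unname(tools::md5sum(outputs)))
    write.table(manifest, file.path(outdir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest
}
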