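# Shared fixtures, generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixtureOnce <- function(name, builder) {
    if (is.null(.fixtureCache[[name]]))
        .fixtureCache[[name]] <- builder()
    .fixtureCache[[name]]
}

# The default-scale synthetic bundle (5 x 1 Mb chromosomes, 100
# pseudo-experiments) together with its called regions: used by the
# recovery tests.
defaultBundle <- function() {
    fixtureOnce("defaultBundle", function() {
        dir <- file.path(tempdir(), "hot-bundle-default")
        bundle <- simulateBundle(dir, seed = 101)
        chromSizes <- readChromSizes(bundle$paths$chromSizes)
        files <- sort(list.files(bundle$paths$peakDir,
                                 full.names = TRUE))
        peakSets <- lapply(files, readNarrowPeak)
        names(peakSets) <- sub("\\.narrowPeak$", "", basename(files))
        param <- HotCallerParam(suppressionSpan = 1000)
        dens <- summitDensity(poolSummits(peakSets), chromSizes, param)
        regions <- callHotRegions(localMaxima(dens, 1000), param)
        list(bundle = bundle, chromSizes = chromSizes,
             param = param, regions = regions)
    })
}

# Reduced-scale bundle and configuration used by the orchestration
# tests (two 1 Mb chromosomes, 40 pseudo-experiments, 200k-read
# libraries, 4 cell types): same code paths as the default scale.
smallBundle <- function(dir, seed = 11) {
    simulateBundle(dir,
        chromLengths = c(chrI = 1e6, chrII = 1e6),
        nHotLoci = 12, nDecoyCgi = 24,
        nExperiments = 40, backgroundPerMb = 25, ipLibrarySize = 2e5,
        controlLibrarySize = 2e5, nCellTypes = 4, seed = seed)
}

smallConfig <- function(bundle, outdir, seed = 5,
                        methylationDir = bundle$paths$methylationDir) {
    hotPipelineConfig(outdir = outdir,
        peakDir = bundle$paths$peakDir,
        genomeFasta = bundle$paths$genomeFasta,
        chromSizesPath = bundle$paths$chromSizes,
        cgiBed = bundle$paths$cgiBed,
        readPairs = data.frame(id = "sim",
            ip = bundle$paths$ipBed,
            control = bundle$paths$controlBed),
        methylationDir = methylationDir,
        param = HotCallerParam(suppressionSpan = 1000),
        nfolds = 5,
        strata = data.frame(lo = c(0, 75, 99), hi = c(75, 99, 100),
                            n = 300),
        seed = seed)
}

# Small genome with planted CpG-rich loci plus labelled feature
# matrix of planted versus background windows, for model tests.
plantedFeatureSet <- function(seed = 301, nLoci = 40,
                              chromLengths = c(chrA = 1e6, chrB = 1e6)) {
    g <- simGenome(chromLengths, nLoci = nLoci, seed = seed)
    starts <- round(seq(5000, min(chromLengths) - 5000,
                        length.out = nLoci))
    bg <- GRanges(rep(names(chromLengths)[1], nLoci),
                  IRanges(starts, width = 2000))
    bg <- suppressWarnings(
        c(bg, GRanges(rep(names(chromLengths)[2], nLoci),
                      IRanges(starts, width = 2000))))
    bg <- bg[!IRanges::overlapsAny(bg, g$loci, maxgap = 2000)]
    bg <- bg[seq_len(min(nLoci, length(bg)))]
    fm <- buildFeatureMatrix(
        suppressWarnings(c(GenomicRanges::granges(g$loci), bg)),
        g$genome)
    labels <- rep(c("HOT", "CONTROL"), c(length(g$loci), length(bg)))
    list(genome = g, features = standardizeFeatureMatrix(fm),
         labels = labels)
}
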