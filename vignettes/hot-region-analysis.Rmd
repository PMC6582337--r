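---
title: "Calling and characterizing high-occupancy target (HOT) regions"
author: "hotRegions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing high-occupancy target (HOT) regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(hotRegions))
suppressMessages(library(GenomicRanges))
```

## The problem

High-occupancy target (HOT) regions are genomic windows where an
unusually large number of ChIP-seq experiments — often dozens to
hundreds of different transcription factors — report peaks. They sit
at CpG-island promoters of housekeeping genes, lack canonical motifs
for most of the factors reported to bind them, and attract artifactual
enrichment in knockout ChIP-seq, DRIP-seq (R-loops) and G4 ChIP-seq
experiments. `hotRegions` implements the full analysis around this
phenomenon as a tested pipeline: region calling from peak-summit
density, sequence featurization and discriminative modelling,
IP-versus-control enrichment quantification, and cross-cell-type
methylation dispersion — together with a seeded synthetic-data
generator so that every stage has a parameter-recovery test that runs
in minutes with no downloads.

## Calling HOT regions from summit density

Given many narrowPeak experiments, each peak is reduced to its summit
(the `peak` offset column when present, the interval midpoint
otherwise). Summits are pooled across experiments and counted in
sliding windows of `windowSize = 500` bp. Local maxima of this density
are retained under non-maximum suppression: a kept window must have a
count greater than or equal to every window whose start lies within
half the `suppressionSpan` of its own, and no two kept windows may lie
within that distance. The retained maxima are ranked by their summit
count — the *TF occupancy* — and converted to percentiles; regions
above the `hotPercentile` (default 99) are HOT, those above
`mildPercentile` (default 75) but not HOT are MILD, the rest COLD.
The percentile bins [0,75), [75,99) and [99,100] are the control
strata used throughout the downstream comparisons.

Choices the window arithmetic rests on, in one place:

* **Window step.** The density definition fixes the window width at
  500 bp but not the step. We default to `step = 50` bp (10x
  oversampling), which approximates a continuous density at tractable
  cost; it is configurable, and the density oracle tests cover several
  steps.
* **Suppression span.** "A span of 2000 bp" can be read as a total
  width or a radius. We implement it as a *total* width: a kept
  maximum dominates everything within ± span/2 of its window start.
  Both readings are available by halving or doubling the configured
  value. 2000 bp suits dense human-scale peak collections; 1000 bp
  suits smaller collections, and the synthetic study conditions use
  1000 bp because its genome and experiment count are closer to the
  modENCODE scale.
* **Ties.** Equal-count windows within one span keep the leftmost;
  this makes suppression deterministic and idempotent (re-running it
  on its own output is a no-op, which is tested).
* **Percentiles.** Mean ranks (ties averaged) with Hazen scaling,
  `100 * (r - 0.5) / n`, and a *strict* threshold. With all
  occupancies equal nothing is HOT; with occupancies 1..200 exactly
  the top two exceed the 99th percentile. Plain `100 * r / n` scaling
  would label ambiguous boundary regions HOT and fails simple
  worked examples.
* **Coordinates.** All files (narrowPeak, BED, bedGraph, chrom.sizes)
  are 0-based half-open on disk, the convention of the formats
  themselves; in memory everything is a 1-based closed `GRanges`.
  Conversion happens only in the readers and writers, which are
  round-trip tested.
* **Occupancy = summit count.** The density score at a retained
  window is the number of pooled summits in it, which for point
  summits is what "number of overlapping peak experiments" measures
  at the density maximum.

## Sequence features and the discriminator

Each region is featurized on a 2000 bp window centered on its
midpoint, clipped at chromosome ends, with 339 features: all 2-, 3-
and 4-mer frequencies (16 + 64 + 256), `cpg_freq`, `cpg_oe` and
`gc_skew`.

* **k-mers.** A length-k window containing `N` is skipped entirely;
  counts are divided by the number of valid windows, so each k-mer
  block sums to 1 whenever any valid window exists. This avoids
  biasing GC-linked features at assembly gaps. Features are computed
  on the reference strand only; no reverse-complement collapsing.
* **`cpg_freq`.** Literally (C + G) / L with L the *nominal* window
  length (2000): despite its name this is the GC content of the
  window. The name follows the feature set the discriminators were
  built on, and the documentation says so explicitly.
* **`cpg_oe`.** The observed/expected CpG ratio in Gardiner–Garden
  form, N(CG) · L / (N(C) · N(G)), with counts over the actual
  (possibly clipped) window and L its length; defined as 0 when C or
  G is absent. A frequency-based reading of the same formula
  multiplied by the region width is dimensionally inconsistent, which
  is why the count form is used.
* **`gc_skew`.** (G − C)/(G + C), 0 when the window has no G or C.
* **Standardization.** Columns are centered and scaled to unit
  *population* (divide-by-n) variance; zero-variance columns are left
  at 0 and recorded on the object rather than producing NaNs.

The discriminator is a penalized logistic regression with elastic-net
mixing `alpha` (default 0.5 — the mixing parameter is a free choice
here, and 0.5 weights the ridge and lasso penalties evenly; it is
exposed in the configuration). Controls are sampled uniformly from
regions below the 85th occupancy percentile, matching the number of
HOT regions; for genomes with CpG islands the sampling can be
CpG-matched so that the island-overlap fraction of controls equals
that of the HOT set to within one region, removing the trivial
discriminator. Folds are class-stratified and seeded; `lambda` is
chosen at the minimum of the cross-validated deviance (the plain
CV-minimum rather than the 1-SE rule, so the reported coefficients
correspond to the best-predicting model; configurable). Accuracy is
the mean across folds of the out-of-fold rank-based (Mann–Whitney)
AUC, which is exactly the probability a random HOT region outscores a
random control and is insensitive to the link scale; it is
cross-checked in the tests against an independent ROC implementation.
Variable importance is |coefficient| scaled so the largest is 100;
cross-model averages treat a feature absent from a model as 0, and
top-k extraction breaks ties lexicographically so reports are
deterministic. The PCA view uses the top-10 averaged features on the
standardized submatrix, subsampling the larger class to the smaller
for display balance.

With only tens of HOT regions, individual elastic-net coefficients
are unstable in the usual way for correlated predictors even when the
cross-validated AUC is high; the averaged importance across
replicate models is the stable quantity, and that is what the
top-10 ranking is based on.

## Enrichment over occupancy strata

For an IP/control pair, per-region enrichment is
`log2((ip_cpm + eps) / (control_cpm + eps))`, where a read overlaps a
region by any intersection (≥ 1 bp) and CPM is count / library size x
1e6. The pseudocount `eps` defaults to 1 CPM — one read in a
million-read library — keeping zero-control regions finite while
preserving monotonicity in the IP count; with hundreds of expected
reads per region its bias on a log2 ratio of 2 is under 0.01. When no
input or mock control exists, an RNaseH-treated IP serves as the
control and is recorded as such (`controlKind`).

Profile heatmaps use a per-bp `log2((ip+eps)/(control+eps))` track
over CPM-scaled coverages. Windows sampled per occupancy stratum
(default 3000 each from percentiles [0,75), [75,99), [99,100]; a
smaller stratum is taken whole and the shortfall recorded) are split
into 50 bins, bin values are per-bp means, and the finished matrix is
winsorized at its own 0.5th and 99th percentiles — the natural
reading of clipping "below 0.5 and above 0.99 percentile" of the
value distribution. Binning is bit-exact against a brute-force
average in the tests; the winsorization limits are exactly the type-7
quantiles of the pre-clip matrix. Single-end control reads (IgG-style
libraries) can be extended to 200 bp in a stranded fashion before
coverage, clipped at chromosome bounds.

## Methylation dispersion

Per-region methylation in one cell type is the unweighted mean of the
per-CpG methylated fractions inside the region (half-open interval; a
CpG at the end coordinate is excluded). Coverage weighting is not
applied because the inputs are already per-CpG fractions. Regions
with no covered CpG are missing and excluded downstream. For each
cell type, a region set is summarized by the median and IQR of region
means, using linear-interpolation (type-7) quantiles so that the
numbers are reproducible across implementations. The headline
comparison takes HOT regions versus CpG islands with zero HOT overlap
(1 bp of overlap excludes an island) and reports the ratio
`median(IQR over cell types, non-HOT CGI) / median(IQR, HOT)` —
how many times more variable methylation is at non-HOT islands. A
zero denominator flags the ratio infinite rather than erroring.

## What the synthetic data emulates

The generator produces data with known truth in exactly the formats
the pipeline consumes, so no code path is synthetic-only:

* **Genome.** Background sequence is i.i.d. at GC 0.41 with CpGs
  retained at probability 0.25 (otherwise the G is resampled), giving
  the CpG depletion (O/E near 0.25–0.3) of bulk vertebrate sequence.
  Planted 2 kb loci are i.i.d. at GC 0.60 without depletion, putting
  their realized CpG O/E near 1 — the CpG-island signature. Decoy
  CpG-island loci share the sequence composition but receive no peak
  enrichment, so island-ness alone cannot explain a HOT call.
* **Peak experiments.** 100 pseudo-experiments; each places a summit
  at each planted locus with probability 0.6 (binomially ~60 summits
  per locus), jittered by a normal with SD 50 bp clamped to the
  locus, over a Poisson background of 10 summits/Mb per experiment.
  These rates make planted loci roughly the top 1% of retained
  maxima, matching the percentile threshold being tested.
* **Reads.** Control reads are uniform; IP reads allocate multinomial
  mass `2^log2fc * (w + L - 1) / G` to each planted region (with
  starts uniform over the positions whose reads intersect the
  region) and the rest uniformly *outside* the expanded regions, so
  the expected CPM ratio equals the planted fold change exactly
  rather than approximately.
* **Methylation.** Per-region, per-cell-type means are Beta-drawn
  with shape parameters fitted numerically (Nelder–Mead on the
  log-shapes) so the Beta median and IQR match the planted values;
  per-CpG values add Gaussian noise (SD 0.02) clipped to [0, 1]. The
  default plan — HOT median 0.05/IQR 0.05, decoy islands median
  0.05/IQR 0.18 — plants the stable-hypomethylation contrast with a
  3.6-fold dispersion ratio.

What it does **not** emulate: mappability, GC bias, read-level error,
replicate structure, peak-caller idiosyncrasies, or the long-range
correlation structure of real chromatin. Passing recovery tests
therefore demonstrates that the estimators are correct and calibrated
under their own model, not that real ENCODE-scale data would yield
any particular region count.

## Study conditions and problem sizes

The synthetic study conditions are fixed at: a 5 Mb genome (five 1 Mb
chromosomes), 30 planted HOT loci, 60 decoy islands, 100 peak
experiments, million-read IP/control libraries with planted log2 fold
change 2, and 10 methylation cell types. The recovery suite checks:
≥ 95% of planted loci called HOT within 500 bp with ≤ 1% of
background regions labelled HOT; discriminator cross-validated AUC
≥ 0.9 with permutation null at 0.5; planted fold change recovered
within ± 0.1 (mean over 20 seeds at ≥ 500 expected reads/region); and
the methylation dispersion ratio within ± 20% at 500 regions x 10
cell types. Orchestration tests run a reduced bundle (two 1 Mb
chromosomes, 40 experiments, 200k-read libraries, 4 cell types) that
exercises the same code paths. Density, feature and binning oracles
are bit-exact brute-force comparisons.

## A worked run

```{r example, eval = FALSE}
library(hotRegions)

bundle <- simulateBundle("bundle", seed = 1)
cfg <- hotPipelineConfig(
    outdir = "results",
    peakDir = bundle$paths$peakDir,
    genomeFasta = bundle$paths$genomeFasta,
    chromSizesPath = bundle$paths$chromSizes,
    cgiBed = bundle$paths$cgiBed,
    readPairs = data.frame(id = "sim",
                           ip = bundle$paths$ipBed,
                           control = bundle$paths$controlBed),
    methylationDir = bundle$paths$methylationDir,
    param = HotCallerParam(suppressionSpan = 1000),
    seed = 1)
res <- runHotPipeline(cfg)
res$regions
res$model
```

## Known limitations

* The caller assumes point summits; broad-source peaks without a
  summit column fall back to midpoints, which blurs density for very
  wide peaks.
* Percentiles are computed over retained maxima only; a different
  suppression span changes the denominator and hence the absolute
  HOT count, which is why the span is a named, recorded parameter.
* The elastic-net coefficients themselves should not be
  over-interpreted at small region counts (see above); use the
  averaged importance.
* `cpg_freq` is GC content (see the feature section); users wanting
  CpG *dinucleotide* frequency should use the `kmer.CG` column or
  `cpg_oe`.
* The enrichment module takes aligned-read intervals as BED;
  alignment, duplicate handling and peak calling are out of scope.
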