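# Central S4 containers: coverage histograms, the CMT parameter set,
# IUPAC motifs and simulation configurations.

#' Per-chromosome coverage histogram
#'
#' A dense, nucleotide-resolution pileup of extended fragments over one
#' chromosome. Bin `i` (1-based) holds the number of fragments covering
#' genomic position `origin + i - 1`. The histogram spans the data extent
#' (minimum fragment start to maximum fragment end); positions outside the
#' extent have height zero by convention (see [heightAt()]).
#'
#' @slot chrom chromosome name.
#' @slot origin 1-based genomic coordinate of the first bin.
#' @slot counts integer vector of non-negative per-nucleotide fragment counts.
#'
#' @seealso [buildHistogram()], [heightAt()]
#' @export
setClass("CoverageHistogram",
    representation(chrom = "character", origin = "integer", counts = "integer"))

setValidity("CoverageHistogram", function(object) {
    msg <- character()
    if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
        msg <- c(msg, "'chrom' must be a single non-empty string")
    if (length(object@origin) != 1L || is.na(object@origin) || object@origin < 1L)
        msg <- c(msg, "'origin' must be a single positive integer (1-based)")
    if (anyNA(object@counts) || any(object@counts < 0L))
        msg <- c(msg, "'counts' must be non-negative and free of NA")
    if (length(msg)) msg else TRUE
})

#' Construct a CoverageHistogram
#'
#' @param chrom chromosome name.
#' @param origin 1-based genomic coordinate of the first bin.
#' @param counts integer vector of per-nucleotide coverage.
#' @return A [CoverageHistogram-class] object.
#' @examples
#' h <- CoverageHistogram("chr1", 11L, c(1L, 1L, 1L))
#' heightAt(h, 10:14)
#' @export
CoverageHistogram <- function(chrom, origin = 1L, counts = integer()) {
    new("CoverageHistogram", chrom = as.character(chrom),
        origin = as.integer(origin), counts = as.integer(counts))
}

#' @describeIn CoverageHistogram-class number of bins.
#' @param x a `CoverageHistogram`.
#' @export
setMethod("length", "CoverageHistogram", function(x) length(x@counts))

#' @describeIn CoverageHistogram-class chromosome name.
setMethod("chrom", "CoverageHistogram", function(x) x@chrom)

#' @describeIn CoverageHistogram-class genomic coordinate of the first bin.
setMethod("origin", "CoverageHistogram", function(x) x@origin)

#' @describeIn CoverageHistogram-class per-bin fragment counts.
#' @param object a `CoverageHistogram`.
#' @importFrom BiocGenerics counts
#' @export counts
#' @exportMethod counts
setMethod("counts", "CoverageHistogram",
    function(object) object@counts)

setMethod("show", "CoverageHistogram", function(object) {
    n <- length(object@counts)
    cat("CoverageHistogram on", object@chrom, "\n")
    if (n == 0L) {
        cat("  (empty)\n")
    } else {
        cat(sprintf("  extent: [%d, %d]  (%d bp)\n", object@origin,
            object@origin + n - 1L, n))
        cat(sprintf("  coverage: max %d, mean %.3f\n", max(object@counts),
            mean(object@counts)))
    }
    invisible(NULL)
})

#' CMT parameter set
#'
#' The user-tunable parameters of the constrained multi-level thresholding
#' peak caller: average fragment length, minimum and maximum target region
#' size, the border-shrinking cut-off, the minimum supported-read height used
#' for gap skipping, and the k-fold enrichment threshold.
#'
#' @slot fragmentLength average sonication fragment length (bp); reads are
#'   extended to this length in their strand direction.
#' @slot minRegion minimum target region size (bp).
#' @slot maxRegion maximum target region size (bp); also the scan window.
#' @slot cutoff border-shrinking height threshold (default 1: keep the
#'   contiguous part of a region supported by at least one fragment).
#' @slot minReads minimum acceptable height for a region (gap-skip
#'   threshold).
#' @slot kFold minimum fold change between experiment and control squared
#'   densities (default 2).
#'
#' @seealso [cmtParams()], [callPeaks()]
#' @export
setClass("CMTParams",
    representation(fragmentLength = "numeric", minRegion = "numeric",
        maxRegion = "numeric", cutoff = "numeric", minReads = "numeric",
        kFold = "numeric"))

setValidity("CMTParams", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && !is.na(x)
    if (!one(object@fragmentLength) || object@fragmentLength < 1)
        msg <- c(msg, "'fragmentLength' must be a single value >= 1")
    if (!one(object@minRegion) || !one(object@maxRegion) ||
        object@minRegion <= 0 || object@minRegion > object@maxRegion)
        msg <- c(msg, "need 0 < minRegion <= maxRegion")
    if (!one(object@cutoff) || object@cutoff < 0)
        msg <- c(msg, "'cutoff' must be >= 0")
    if (!one(object@minReads) || object@minReads < 0)
        msg <- c(msg, "'minReads' must be >= 0")
    if (!one(object@kFold) || object@kFold <= 0)
        msg <- c(msg, "'kFold' must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a CMT parameter set
#'
#' Defaults follow the method's published defaults where it states them
#' (`cutoff = 1`, `kFold = 2`); fragment length and the region size range are
#' experiment-specific and should be set to the sonication fragment length
#' and the expected footprint range of the targeted feature (around 10 bp
#' for transcription-factor footprints up to tens of kbp for histone-mark
#' domains).
#'
#' @param fragmentLength average fragment length in bp.
#' @param minRegion,maxRegion minimum/maximum target region size in bp.
#' @param cutoff border-shrinking height threshold.
#' @param minReads minimum supported height for a candidate region.
#' @param kFold minimum experiment/control squared-density fold change.
#' @return A [CMTParams-class] object.
#' @examples
#' cmtParams(fragmentLength = 200, minRegion = 100, maxRegion = 1000,
#'     minReads = 10)
#' @export
cmtParams <- function(fragmentLength = 200, minRegion = 100,
                      maxRegion = 1000, cutoff = 1, minReads = 5,
                      kFold = 2) {
    new("CMTParams", fragmentLength = as.numeric(fragmentLength),
        minRegion = as.numeric(minRegion), maxRegion = as.numeric(maxRegion),
        cutoff = as.numeric(cutoff), minReads = as.numeric(minReads),
        kFold = as.numeric(kFold))
}

setMethod("show", "CMTParams", function(object) {
    cat("CMTParams\n")
    cat(sprintf("  fragmentLength: %g bp\n", object@fragmentLength))
    cat(sprintf("  region size:    [%g, %g] bp\n", object@minRegion,
        object@maxRegion))
    cat(sprintf("  cutoff: %g   minReads: %g   kFold: %g\n", object@cutoff,
        object@minReads, object@kFold))
    invisible(NULL)
})

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
    R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
    B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' IUPAC DNA binding motif
#'
#' A degenerate DNA pattern over the IUPAC alphabet (e.g. `GANGGGT`, where
#' `N` matches any base) used for motif enrichment scoring.
#'
#' @slot pattern IUPAC DNA string.
#' @slot name label for reports.
#' @seealso [motif()], [countMotif()], [enrichmentScore()]
#' @export
setClass("Motif", representation(pattern = "character", name = "character"))

setValidity("Motif", function(object) {
    msg <- character()
    if (length(object@pattern) != 1L || !nzchar(object@pattern))
        msg <- c(msg, "'pattern' must be a single non-empty string")
    else {
        bad <- setdiff(strsplit(object@pattern, "")[[1L]], names(.IUPAC))
        if (length(bad))
            msg <- c(msg, paste0("invalid IUPAC character(s): ",
                paste(unique(bad), collapse = ", ")))
    }
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct a Motif
#'
#' @param pattern IUPAC DNA string (case-insensitive).
#' @param name label; defaults to the pattern itself.
#' @return A [Motif-class] object.
#' @examples
#' motif("GANGGGT", "KR")
#' @export
motif <- function(pattern, name = pattern) {
    new("Motif", pattern = toupper(as.character(pattern)),
        name = as.character(name))
}

setMethod("show", "Motif", function(object) {
    cat(sprintf("Motif %s: %s\n", object@name, object@pattern))
    invisible(NULL)
})

#' Synthetic ChIP-Seq simulation configuration
#'
#' Describes a synthetic experiment: a chromosome of given length carrying
#' uniformly scattered background reads plus planted enriched regions of
#' configurable width and fold enrichment, with a matched background-only
#' control sample. All randomness is driven by `seed`.
#'
#' @slot chrom chromosome name used in all outputs.
#' @slot chromLength chromosome length (bp).
#' @slot nBackgroundReads number of background reads in the experiment
#'   sample.
#' @slot readLength sequenced read length (bp).
#' @slot fragmentLength sonication fragment length (bp); peak-read placement
#'   and downstream extension both use it.
#' @slot peaks data.frame with columns `centre`, `width`, `fold`; one row per
#'   planted enriched region.
#' @slot controlDepthRatio control background depth relative to the
#'   experiment background.
#' @slot seed integer RNG seed.
#' @seealso [simulationConfig()], [simulateReads()]
#' @export
setClass("SimulationConfig",
    representation(chrom = "character", chromLength = "numeric",
        nBackgroundReads = "numeric", readLength = "numeric",
        fragmentLength = "numeric", peaks = "data.frame",
        controlDepthRatio = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@chromLength < 1)
        msg <- c(msg, "'chromLength' must be positive")
    if (object@readLength < 1 || object@readLength > object@chromLength)
        msg <- c(msg, "'readLength' must be in [1, chromLength]")
    if (object@fragmentLength < object@readLength)
        msg <- c(msg, "'fragmentLength' must be >= readLength")
    if (object@nBackgroundReads < 0)
        msg <- c(msg, "'nBackgroundReads' must be >= 0")
    if (object@controlDepthRatio <= 0)
        msg <- c(msg, "'controlDepthRatio' must be > 0")
    pk <- object@peaks
    if (nrow(pk)) {
        if (!all(c("centre", "width", "fold") %in% names(pk)))
            msg <- c(msg, "'peaks' needs columns centre, width, fold")
        else {
            if (any(pk$width < 1))
                msg <- c(msg, "peak widths must be >= 1")
            if (any(pk$fold < 1))
                msg <- c(msg, "peak fold enrichment must be >= 1")
            if (any(pk$width > object@chromLength))
                msg <- c(msg, "a planted peak is wider than the chromosome")
            lo <- pk$centre - pk$width / 2
            hi <- pk$centre + pk$width / 2
            if (any(lo < 1) || any(hi > object@chromLength))
                msg <- c(msg, "planted peaks must lie within the chromosome")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' The defaults describe the package's reference synthetic experiment: a 1-Mbp
#' chromosome, 20,000 background reads of 36 bp extended to 200-bp fragments
#' (expected background coverage 4x), and a single planted 300-bp peak of
#' 10-fold enrichment at the chromosome midpoint, with an equally deep
#' control.
#'
#' @param chrom chromosome name.
#' @param chromLength chromosome length (bp).
#' @param nBackgroundReads background read count of the experiment sample.
#' @param readLength read length (bp).
#' @param fragmentLength fragment length (bp).
#' @param peaks data.frame(centre, width, fold) of planted regions; a zero-row
#'   data.frame plants none.
#' @param controlDepthRatio control depth relative to the experiment
#'   background.
#' @param seed integer RNG seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(seed = 1)
#' @export
simulationConfig <- function(chrom = "chrSim", chromLength = 1e6,
                             nBackgroundReads = 20000, readLength = 36,
                             fragmentLength = 200,
                             peaks = data.frame(centre = 5e5, width = 300,
                                 fold = 10),
                             controlDepthRatio = 1, seed = 1L) {
    new("SimulationConfig", chrom = as.character(chrom),
        chromLength = as.numeric(chromLength),
        nBackgroundReads = as.numeric(nBackgroundReads),
        readLength = as.numeric(readLength),
        fragmentLength = as.numeric(fragmentLength),
        peaks = as.data.frame(peaks),
        controlDepthRatio = as.numeric(controlDepthRatio),
        seed = as.numeric(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  %s: %g bp, %g background reads (%g bp -> %g bp fragments)\n",
        object@chrom, object@chromLength, object@nBackgroundReads,
        object@readLength, object@fragmentLength))
    cat(sprintf("  planted peaks: %d   control depth ratio: %g   seed: %g\n",
        nrow(object@peaks), object@controlDepthRatio, object@seed))
    invisible(NULL)
})
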