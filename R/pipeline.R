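# End-to-end pipeline: extend reads -> pileup -> constrained segmentation ->
# shrink -> k-fold enrichment filter -> ranking; plus the evaluation report.

.asReads <- function(x, what) {
    if (is.character(x) && length(x) == 1L)
        return(readBed(x))
    if (is(x, "GRanges"))
        return(x)
    stop("'", what, "' must be a BED file path or a GRanges of reads")
}

#' Call peaks with constrained multi-level thresholding
#'
#' Runs the full pipeline on an experiment and a control sample: reads are
#' extended to fragments and piled into per-chromosome histograms; each
#' experiment histogram is segmented into candidate regions by constrained
#' between-class-variance thresholding with gap skipping; candidates are
#' shrunk to their supported footprint, filtered by size and by the k-fold
#' squared-density criterion against the control, and ranked by fold
#' enrichment. A control is required: the enrichment filter is defined
#' against it.
#'
#' @param experiment,control BED file paths or stranded read `GRanges`.
#' @param params a [CMTParams-class].
#' @param scaleControl scale control heights by the library-size ratio
#'   before the k-fold test (see [isEnriched()])?
#' @param chromSizes optional named chromosome lengths for right-clipping
#'   extended fragments.
#' @param method squared-density definition, see [squaredDensity()].
#' @return A list:
#'   \describe{
#'     \item{peaks}{ranked passed regions (`GRanges` with `summit`,
#'       `height`, `expDensity`, `ctrlDensity`, `foldEnrichment`).}
#'     \item{candidates}{all shrunk candidates with their `passed` flag.}
#'     \item{summary}{per-chromosome data.frame: candidate count, passed
#'       count, mean passed-peak length.}
#'     \item{scaleFactor}{experiment/control depth ratio used.}
#'   }
#' @examples
#' sim <- simulateReads(simulationConfig(chromLength = 5e4,
#'     nBackgroundReads = 1000, peaks = data.frame(centre = 25000,
#'     width = 300, fold = 10), seed = 11))
#' res <- callPeaks(sim$experiment, sim$control,
#'     cmtParams(fragmentLength = 200, minRegion = 100, maxRegion = 1000,
#'         cutoff = 8, minReads = 17))
#' res$peaks
#' @export
callPeaks <- function(experiment, control, params,
                      scaleControl = TRUE, chromSizes = NULL,
                      method = c("mean-of-squares", "squared-mean")) {
    method <- match.arg(method)
    stopifnot(is(params, "CMTParams"))
    if (missing(control) || is.null(control))
        stop("a control sample is required: the enrichment filter compares ",
            "experiment and control squared densities")
    expReads <- .asReads(experiment, "experiment")
    ctrlReads <- .asReads(control, "control")
    expFrags <- extendReads(expReads, params@fragmentLength, chromSizes)
    ctrlFrags <- extendReads(ctrlReads, params@fragmentLength, chromSizes)
    expChroms <- unique(as.character(GenomicRanges::seqnames(expFrags)))
    ctrlChroms <- unique(as.character(GenomicRanges::seqnames(ctrlFrags)))
    if (length(expChroms) && length(ctrlChroms) &&
        !length(intersect(expChroms, ctrlChroms)))
        stop("experiment and control share no chromosome")
    scaleFactor <- if (scaleControl && length(ctrlFrags))
        length(expFrags) / length(ctrlFrags) else 1

    allCand <- list()
    sumRows <- list()
    for (ch in expChroms) {
        expHist <- buildHistogram(expFrags, ch)
        ctrlHist <- buildHistogram(ctrlFrags, ch)
        cand <- scanChromosome(expHist, params)
        if (length(cand)) {
            shrunk <- do.call(c, lapply(seq_along(cand), function(i)
                shrinkRegion(expHist, cand[i], params@cutoff)))
            cand <- .enrichRegions(expHist, ctrlHist, shrunk, params,
                scaleFactor, method)
        }
        nPassed <- sum(cand$passed)
        sumRows[[ch]] <- data.frame(chrom = ch,
            candidates = length(cand), passed = nPassed,
            meanLength = if (nPassed)
                mean(GenomicRanges::width(cand[cand$passed])) else NA_real_)
        allCand[[ch]] <- cand
    }
    candidates <- if (length(allCand))
        do.call(c, unname(allCand)) else GenomicRanges::GRanges()
    list(peaks = rankRegions(candidates), candidates = candidates,
        summary = if (length(sumRows)) do.call(rbind, unname(sumRows)) else
            data.frame(chrom = character(), candidates = integer(),
                passed = integer(), meanLength = numeric()),
        scaleFactor = scaleFactor)
}

#' Evaluate one or more peak sets
#'
#' Computes, for each peak set, the motif enrichment score against
#' length-matched random intervals (when a genome and motifs are given),
#' all pairwise directional summit-overlap percentages (for two or more
#' sets), and the genomic-feature assignment table (when annotations are
#' given).
#'
#' @param peakSets named list of peak `GRanges`.
#' @param genome named `DNAStringSet` or character vector of chromosome
#'   sequences, or `NULL` to skip enrichment scoring.
#' @param motifs motifs for [enrichmentScore()], or `NULL`.
#' @param annotations feature-labelled `GRanges` for [assignFeatures()], or
#'   `NULL` to omit the feature table.
#' @param seed seed for the random interval draws.
#' @return A list with data.frames `enrichment`, `overlap` and `features`
#'   (each `NULL` when its inputs were not supplied).
#' @export
evaluatePeaks <- function(peakSets, genome = NULL, motifs = NULL,
                          annotations = NULL, seed = 1L) {
    stopifnot(is.list(peakSets), length(peakSets) >= 1L)
    if (is.null(names(peakSets)))
        names(peakSets) <- paste0("set", seq_along(peakSets))
    enrichment <- NULL
    if (!is.null(genome) && !is.null(motifs)) {
        enrichment <- do.call(rbind, lapply(names(peakSets), function(nm) {
            es <- enrichmentScore(peakSets[[nm]], genome, motifs, seed)
            data.frame(set = nm, score = es$score,
                peakCount = es$peakCount, randomCount = es$randomCount)
        }))
    }
    overlap <- NULL
    if (length(peakSets) >= 2L) {
        rows <- list()
        nms <- names(peakSets)
        for (i in seq_along(nms)) for (j in seq_along(nms)) {
            if (i == j) next
            ov <- summitOverlap(peakSets[[nms[i]]], peakSets[[nms[j]]])
            rows[[length(rows) + 1L]] <- data.frame(a = nms[i], b = nms[j],
                aInB = ov$aInB, pctADetectedByB = ov$pctADetectedByB)
        }
        overlap <- do.call(rbind, rows)
    }
    features <- NULL
    if (!is.null(annotations)) {
        features <- do.call(rbind, lapply(names(peakSets), function(nm) {
            cbind(set = nm, assignFeatures(peakSets[[nm]], annotations))
        }))
    }
    list(enrichment = enrichment, overlap = overlap, features = features)
}

#' FDR as a function of the number of top-ranked peaks
#'
#' Thresholds two ranked peak sets (original orientation and
#' experiment/control-swapped) at a grid of top-N values and reports
#' [swapFdr()] at each, tracing the FDR-versus-rank behaviour.
#'
#' @param originalPeaks,swappedPeaks ranked peak `GRanges` (or counts).
#' @param grid integer vector of top-N thresholds; defaults to a
#'   log-spaced grid up to the original peak count.
#' @return data.frame with columns `topN`, `nOriginal`, `nSwapped`, `fdr`.
#' @export
fdrCurve <- function(originalPeaks, swappedPeaks, grid = NULL) {
    nO <- if (is(originalPeaks, "GRanges")) length(originalPeaks) else
        as.integer(originalPeaks)
    nS <- if (is(swappedPeaks, "GRanges")) length(swappedPeaks) else
        as.integer(swappedPeaks)
    if (nO == 0L)
        stop("no original peaks; FDR undefined")
    if (is.null(grid))
        grid <- unique(round(10^seq(0, log10(nO), length.out = 20L)))
    grid <- sort(unique(pmin(grid, nO)))
    data.frame(topN = grid, nOriginal = grid,
        nSwapped = pmin(nS, grid),
        fdr = vapply(grid, function(g) swapFdr(g, min(nS, g)), numeric(1L)))
}
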