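# Region refinement and enrichment selection: shrink candidates to their
# supported footprint, then keep regions whose size is within the target
# range and whose squared coverage density exceeds the control's k-fold.

#' Shrink a candidate region to its supported footprint
#'
#' Starting from the region's highest point (its summit), the start and end
#' borders are walked outward until the coverage first drops strictly below
#' the cut-off level, removing empty flanks: the result is the maximal
#' contiguous sub-interval containing the summit in which every bin has
#' height `>= cutoff`. Signal blocks inside the original candidate that are
#' disconnected from the summit (separated by a sub-cutoff bin) are dropped.
#' The default cut-off of 1 isolates the continuous part of the region
#' supported by at least one fragment.
#'
#' @param hist the [CoverageHistogram-class] the region was called on.
#' @param region a single-range `GRanges` with a `summit` metadata column.
#' @param cutoff height threshold (>= 0).
#' @return The shrunk region (same `summit` and `height`).
#' @export
shrinkRegion <- function(hist, region, cutoff = 1) {
    stopifnot(is(hist, "CoverageHistogram"), length(region) == 1L)
    summit <- region$summit
    if (is.null(summit))
        stop("region must carry a 'summit' metadata column")
    s <- GenomicRanges::start(region)
    e <- GenomicRanges::end(region)
    if (summit < s || summit > e)
        stop("summit lies outside the region")
    h <- .heightsRange(hist, s, e)
    si <- summit - s + 1L
    if (h[si] < cutoff)
        stop("summit height (", h[si], ") is below the cut-off (", cutoff,
            "); candidate should have been removed by the minReads filter")
    below <- h < cutoff
    left <- si
    while (left > 1L && !below[left - 1L]) left <- left - 1L
    right <- si
    while (right < length(h) && !below[right + 1L]) right <- right + 1L
    out <- region
    GenomicRanges::ranges(out) <- IRanges::IRanges(start = s + left - 1L,
        end = s + right - 1L)
    out
}

#' Mean squared coverage density over an interval
#'
#' Returns the mean of squared per-nucleotide heights over the closed
#' interval `[start, end]`; positions outside the histogram extent
#' contribute height 0. `method = "squared-mean"` gives the square of the
#' mean height instead, for sensitivity analysis of the density definition.
#'
#' @param hist a [CoverageHistogram-class].
#' @param start,end 1-based closed interval bounds, `start <= end`.
#' @param method `"mean-of-squares"` (default) or `"squared-mean"`.
#' @return Non-negative density (reads^2).
#' @examples
#' h <- CoverageHistogram("chr1", 1L, c(2L, 2L))
#' squaredDensity(h, 1, 2)  # (4 + 4) / 2 = 4
#' @export
squaredDensity <- function(hist, start, end,
                           method = c("mean-of-squares", "squared-mean")) {
    method <- match.arg(method)
    if (length(start) != 1L || length(end) != 1L || start > end)
        stop("need a non-empty interval with start <= end")
    h <- as.numeric(.heightsRange(hist, start, end))
    if (method == "mean-of-squares") mean(h^2) else mean(h)^2
}

#' Test a region for enrichment over the control
#'
#' A shrunk candidate is enriched when (i) its size lies within the
#' user-defined range `[minRegion, maxRegion]` and (ii) its squared coverage
#' density in the experiment is at least `kFold` times that of the matching
#' control interval. Control heights are multiplied by the library-size
#' ratio `scaleFactor` (experiment/control total fragment mass) before
#' squaring, so unequal sequencing depths do not bias the test; set
#' `scaleControl = FALSE` to compare raw heights. When the scaled control
#' density is zero but the experiment's is positive the region passes (a
#' sparse control must not veto strong signal); the reported fold enrichment
#' then uses a floor of `1 / width(region)` in the denominator to stay
#' finite.
#'
#' @param expHist,ctrlHist experiment and control
#'   [CoverageHistogram-class] objects for the region's chromosome.
#' @param region a single shrunk candidate (`GRanges` with `summit`,
#'   `height`).
#' @param params a [CMTParams-class].
#' @param scaleFactor experiment/control depth ratio; default is the ratio
#'   of total histogram mass. Ignored when `scaleControl = FALSE`.
#' @param scaleControl scale control heights for library size before the
#'   k-fold test?
#' @param method squared-density definition, see [squaredDensity()].
#' @return A list with elements `region` (the input region with
#'   `expDensity`, `ctrlDensity`, `foldEnrichment` and `passed` metadata
#'   columns added), `expDensity`, `ctrlDensity` (scaled) and `passed`.
#' @export
isEnriched <- function(expHist, ctrlHist, region, params,
                       scaleFactor = NULL, scaleControl = TRUE,
                       method = c("mean-of-squares", "squared-mean")) {
    method <- match.arg(method)
    stopifnot(length(region) == 1L)
    f <- .controlScale(expHist, ctrlHist, scaleFactor, scaleControl)
    out <- .enrichRegions(expHist, ctrlHist, region, params, f, method)
    list(region = out, expDensity = out$expDensity,
        ctrlDensity = out$ctrlDensity, passed = out$passed)
}

.controlScale <- function(expHist, ctrlHist, scaleFactor, scaleControl) {
    if (!scaleControl)
        return(1)
    if (!is.null(scaleFactor))
        return(scaleFactor)
    me <- sum(as.numeric(expHist@counts))
    mc <- sum(as.numeric(ctrlHist@counts))
    if (mc > 0) me / mc else 1
}

# vectorized enrichment over a candidate GRanges; f = control height scale
.enrichRegions <- function(expHist, ctrlHist, regions, params, f,
                           method = "mean-of-squares") {
    nr <- length(regions)
    expD <- ctrlD <- numeric(nr)
    for (i in seq_len(nr)) {
        s <- GenomicRanges::start(regions)[i]
        e <- GenomicRanges::end(regions)[i]
        expD[i] <- squaredDensity(expHist, s, e, method)
        ctrlD[i] <- squaredDensity(ctrlHist, s, e, method)
    }
    ctrlD <- f^2 * ctrlD             # scaling heights by f scales h^2 by f^2
    wd <- GenomicRanges::width(regions)
    sizeOK <- wd >= params@minRegion & wd <= params@maxRegion
    passed <- sizeOK & expD > 0 & expD >= params@kFold * ctrlD
    regions$expDensity <- expD
    regions$ctrlDensity <- ctrlD
    regions$foldEnrichment <- expD / pmax(ctrlD, 1 / wd)
    regions$passed <- passed
    regions
}

#' Rank enriched regions by fold enrichment
#'
#' Keeps the regions that passed the enrichment filter and orders them by
#' fold enrichment, descending; ties are broken by (chrom, start) ascending
#' for determinism.
#'
#' @param results a `GRanges` with `passed` and `foldEnrichment` metadata
#'   columns (from [isEnriched()] / [callPeaks()]), or a list of
#'   [isEnriched()] results.
#' @return The passed regions as a ranked `GRanges`.
#' @export
rankRegions <- function(results) {
    if (is.list(results) && !is(results, "GRanges"))
        results <- do.call(c, lapply(results, `[[`, "region"))
    if (length(results) == 0L)
        return(GenomicRanges::GRanges())
    keep <- results[results$passed]
    if (length(keep) == 0L)
        return(keep)
    o <- order(-keep$foldEnrichment,
        as.character(GenomicRanges::seqnames(keep)),
        GenomicRanges::start(keep))
    keep[o]
}
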