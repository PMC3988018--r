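# Pileup construction: dense per-nucleotide coverage over the data extent.

#' Build a per-chromosome coverage histogram from fragments
#'
#' Piles extended fragments into a dense nucleotide-resolution histogram
#' spanning the data extent (minimum fragment start to maximum fragment end)
#' of one chromosome. `counts[i]` is the number of fragments covering genomic
#' position `origin(h) + i - 1`.
#'
#' @param fragments a [GenomicRanges::GRanges] of fragments; all on `chrom`.
#' @param chrom chromosome to build; defaults to the single chromosome
#'   present in `fragments`.
#' @return A [CoverageHistogram-class]; empty fragments give an empty
#'   histogram.
#' @examples
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 3), c(4, 6)))
#' counts(buildHistogram(fr))
#' @export
buildHistogram <- function(fragments, chrom = NULL) {
    if (is.null(chrom)) {
        lv <- unique(as.character(GenomicRanges::seqnames(fragments)))
        if (length(lv) > 1L)
            stop("fragments span multiple chromosomes; supply 'chrom'")
        chrom <- if (length(lv)) lv else "chrUnknown"
    }
    fragments <- fragments[as.character(
        GenomicRanges::seqnames(fragments)) == chrom]
    if (length(fragments) == 0L)
        return(CoverageHistogram(chrom, 1L, integer()))
    org <- min(GenomicRanges::start(fragments))
    ir <- IRanges::IRanges(
        start = GenomicRanges::start(fragments) - org + 1L,
        end = GenomicRanges::end(fragments) - org + 1L)
    cov <- IRanges::coverage(ir)
    CoverageHistogram(chrom, org, as.integer(cov))
}

#' Build histograms for every chromosome in a fragment set
#'
#' @param fragments a `GRanges` of fragments over any number of chromosomes.
#' @return Named list of [CoverageHistogram-class] objects.
#' @export
buildHistograms <- function(fragments) {
    chroms <- unique(as.character(GenomicRanges::seqnames(fragments)))
    stats::setNames(lapply(chroms, function(ch)
        buildHistogram(fragments, ch)), chroms)
}

#' @rdname heightAt
#' @export
setMethod("heightAt", "CoverageHistogram", function(x, positions) {
    idx <- as.integer(positions) - x@origin + 1L
    out <- integer(length(idx))
    ok <- idx >= 1L & idx <= length(x@counts)
    out[ok] <- x@counts[idx[ok]]
    out
})

# heights over the closed interval [from, to], zero-padded outside extent
.heightsRange <- function(hist, from, to) {
    heightAt(hist, seq.int(from, to))
}
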