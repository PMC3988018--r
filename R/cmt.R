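# The constrained multi-level thresholding engine.
#
# Each peak is treated as a one-dimensional cluster separated from its
# neighbours by valleys. Within a window bounded by the user's minimum and
# maximum region sizes, the division point between the current region and
# the next is the position maximizing the between-class (Otsu) variance
# computed along the genomic axis: bin index is the value, normalized
# coverage the weight. Valleys -- low-mass bins between two concentrations
# of coverage -- maximize the criterion.

#' Between-class variance of a positional split
#'
#' For a window of per-bin coverage counts, splits the bins at index `t`
#' (class 1 = bins `1..t`, class 2 = bins `t+1..n`) and returns the Otsu
#' between-class variance computed with bin index as the value axis and
#' normalized coverage `p_i = counts_i / sum(counts)` as the weight:
#' \deqn{\sigma_B^2(t) = \omega_1 (\mu_1 - \mu_T)^2 +
#'       \omega_2 (\mu_2 - \mu_T)^2}
#' which equals \eqn{\omega_1 \omega_2 (\mu_1 - \mu_2)^2} when both classes
#' carry mass, and 0 when either class is empty.
#'
#' @param counts numeric vector (>= 2 bins) of non-negative coverage with a
#'   positive total.
#' @param t split index, `1 <= t < length(counts)`; class 1 ends at bin `t`.
#' @return Non-negative between-class variance (bin-index units squared).
#' @examples
#' x <- numeric(21); x[10] <- 5; x[20] <- 5
#' betweenClassVariance(x, 14)  # 0.5 * 0.5 * (20 - 10)^2 = 25
#' @export
betweenClassVariance <- function(counts, t) {
    n <- length(counts)
    if (n < 2L)
        stop("window must have >= 2 bins")
    total <- sum(counts)
    if (total <= 0)
        stop("window has zero total coverage; gap-skip before splitting")
    if (length(t) != 1L || is.na(t) || t < 1L || t >= n)
        stop("'t' must satisfy 1 <= t < length(counts)")
    p <- counts / total
    idx <- seq_len(n)
    w1 <- sum(p[1:t])
    w2 <- 1 - w1
    if (w1 <= 0 || w2 <= 0)
        return(0)
    muT <- sum(p * idx)
    mu1 <- sum(p[1:t] * idx[1:t]) / w1
    mu2 <- sum(p[(t + 1):n] * idx[(t + 1):n]) / w2
    w1 * (mu1 - muT)^2 + w2 * (mu2 - muT)^2
}

# Vectorized sigma_B^2 over all splits t = 1..n-1 of a window, via running
# sums (each split costs O(1) after two cumulative sums). Returns numeric(n-1).
.sigmaBSweep <- function(counts) {
    n <- length(counts)
    total <- sum(counts)
    if (n < 2L)
        return(numeric(0L))
    if (total <= 0)
        return(numeric(n - 1L))
    p <- counts / total
    idx <- seq_len(n)
    w1 <- cumsum(p)[-n]
    m1 <- cumsum(p * idx)[-n]          # class-1 first moment (unnormalized)
    muT <- sum(p * idx)
    den <- w1 * (1 - w1)
    sig <- numeric(n - 1L)
    pos <- den > 0
    # identity: w1 w2 (mu1 - mu2)^2 = (muT w1 - m1)^2 / (w1 w2)
    sig[pos] <- (muT * w1[pos] - m1[pos])^2 / den[pos]
    sig
}

# Centre of the maximizing plateau of a sigma sweep restricted to the
# admissible split positions. `admissible` is an integer vector of t values.
# Zero-coverage valleys make sigma exactly constant across them; the plateau
# centre (middle element of the first maximal run) is a symmetric,
# reproducible tie-break.
.plateauArgmax <- function(sig, admissible) {
    s <- sig[admissible]
    mx <- max(s)
    tol <- if (mx > 0) mx * 1e-12 else 0
    hit <- s >= mx - tol
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)[1L]
    admissible[(starts[k] + ends[k]) %/% 2L]
}

# Admissible split positions within a window: division points between
# neighbouring peaks lie in valleys, i.e. at bins whose height is below the
# minimum supported height. When the whole constrained range is supported
# (a domain broader than maxRegion) every position in the range is
# admissible, so broad signal is chopped into maxRegion-bounded pieces.
.admissibleSplits <- function(w, minR, minReads) {
    rng <- minR:(length(w) - 1L)
    valley <- rng[w[rng] < minReads]
    if (length(valley)) valley else rng
}

#' Find the constrained division point for the current window
#'
#' Considers the window `[windowStart, windowStart + maxRegion - 1]` of the
#' histogram (shrunk at the chromosome's right edge) and returns the genomic
#' position at which the next region begins: the split maximizing the
#' between-class variance, constrained so the emitted region length lies in
#' `[minRegion, maxRegion)`. Since a division point separates two
#' neighbouring peaks, admissible splits are restricted to valley bins
#' (height below `minReads`) within the constrained range; when the whole
#' range is supported -- a domain broader than `maxRegion` -- every position
#' in the range is admissible, so broad signal is divided into
#' `maxRegion`-bounded pieces. Ties are broken at the centre of the
#' maximizing plateau.
#'
#' @param hist a [CoverageHistogram-class].
#' @param windowStart genomic position of the first bin of the window.
#' @param params a [CMTParams-class]; `minRegion`/`maxRegion` bound the
#'   region emitted to its left, `minReads` defines signal.
#' @return Genomic position of the division point (start of the next
#'   region), so the current region is `[windowStart, division - 1]`; or
#'   `NA` when the window holds no bin reaching `minReads` (a gap, to be
#'   skipped by the caller).
#' @seealso [scanChromosome()], [gapSkip()]
#' @export
findDivisionPoint <- function(hist, windowStart, params) {
    stopifnot(is(hist, "CoverageHistogram"), is(params, "CMTParams"))
    n <- length(hist@counts)
    i0 <- as.integer(windowStart) - hist@origin + 1L
    if (i0 < 1L || i0 > n)
        stop("'windowStart' outside histogram extent")
    i1 <- min(i0 + as.integer(params@maxRegion) - 1L, n)
    w <- hist@counts[i0:i1]
    if (max(w) < params@minReads)
        return(NA_integer_)
    len <- length(w)
    minR <- as.integer(params@minRegion)
    if (len - 1L < minR)          # window too short to admit any split
        return(NA_integer_)
    sig <- .sigmaBSweep(w)
    t <- .plateauArgmax(sig, .admissibleSplits(w, minR, params@minReads))
    as.integer(windowStart) + t
}

#' Skip coverage gaps
#'
#' Returns the first genomic position at or after `pos` whose coverage
#' reaches the minimum acceptable height (`minReads`), so that scanning can
#' jump over the large unsupported stretches typical of sparse alignments.
#' A position already inside signal is returned unchanged.
#'
#' @param hist a [CoverageHistogram-class].
#' @param pos genomic position to start from (clamped to the extent's left
#'   edge).
#' @param params a [CMTParams-class] supplying `minReads`.
#' @return Genomic position, or `NA` (end-of-chromosome sentinel) if no
#'   remaining bin reaches `minReads`.
#' @export
gapSkip <- function(hist, pos, params) {
    stopifnot(is(hist, "CoverageHistogram"), is(params, "CMTParams"))
    n <- length(hist@counts)
    if (n == 0L)
        return(NA_integer_)
    i <- max(1L, as.integer(pos) - hist@origin + 1L)
    if (i > n)
        return(NA_integer_)
    rel <- which(hist@counts[i:n] >= params@minReads)
    if (!length(rel))
        return(NA_integer_)
    hist@origin + (i + rel[1L] - 1L) - 1L
}

#' Segment a chromosome into candidate regions
#'
#' Scans the histogram left to right: gaps below `minReads` are skipped; at
#' each supported position a window of `maxRegion` bins is opened and the
#' constrained division point placed by [findDivisionPoint()]; the region
#' between the current position and the division point is emitted and the
#' scan resumes at the division point. The result is the model's two
#' boundary vectors (starts and ends) as a sorted, non-overlapping `GRanges`
#' of candidates, each carrying its summit position and height. Trailing
#' signal at the chromosome end too short to admit a constrained split is
#' emitted as a final candidate and left to the downstream size filter.
#'
#' @param hist a [CoverageHistogram-class].
#' @param params a [CMTParams-class].
#' @return A `GRanges` of candidate regions with metadata columns `summit`
#'   and `height`; `S4Vectors::metadata()` of the result records
#'   `nEvaluations`, the number of between-class-variance evaluations
#'   performed (used to verify the scan's linear-time behaviour).
#' @export
scanChromosome <- function(hist, params) {
    stopifnot(is(hist, "CoverageHistogram"), is(params, "CMTParams"))
    cts <- hist@counts
    n <- length(cts)
    nEval <- 0
    starts <- integer(0L)
    ends <- integer(0L)
    if (n > 0L) {
        supported <- which(cts >= params@minReads)
        minR <- as.integer(params@minRegion)
        maxR <- as.integer(params@maxRegion)
        si <- 1L                     # pointer into `supported`
        while (si <= length(supported)) {
            i0 <- supported[si]
            i1 <- min(i0 + maxR - 1L, n)
            len <- i1 - i0 + 1L
            if (len - 1L < minR) {   # trailing signal at the right edge
                starts <- c(starts, i0)
                ends <- c(ends, i1)
                break
            }
            w <- cts[i0:i1]
            sig <- .sigmaBSweep(w)
            adm <- .admissibleSplits(w, minR, params@minReads)
            nEval <- nEval + length(adm)
            t <- .plateauArgmax(sig, adm)
            starts <- c(starts, i0)
            ends <- c(ends, i0 + t - 1L)
            # resume at the division point: next supported bin >= i0 + t
            si <- si + findInterval(i0 + t - 1L, supported[si:length(supported)])
        }
    }
    if (length(starts)) {
        summitIdx <- mapply(function(s, e) s + which.max(cts[s:e]) - 1L,
            starts, ends)
        gr <- GenomicRanges::GRanges(hist@chrom,
            IRanges::IRanges(start = hist@origin + starts - 1L,
                end = hist@origin + ends - 1L))
        gr$summit <- hist@origin + as.integer(summitIdx) - 1L
        gr$height <- as.integer(cts[summitIdx])
    } else {
        gr <- GenomicRanges::GRanges()
    }
    S4Vectors::metadata(gr)$nEvaluations <- nEval
    gr
}
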