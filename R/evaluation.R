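# Evaluation machinery: swap-based FDR, IUPAC motif enrichment against
# length-matched random intervals, summit-based overlap between peak sets,
# and genomic-feature assignment.

#' Swap-based false discovery rate
#'
#' The experiment and control samples are exchanged and peaks re-called with
#' identical parameters; every peak surviving the swap is treated as a false
#' discovery. The FDR is `100 * nSwapped / nOriginal` percent: e.g. 100
#' peaks originally and 30 after the swap give 30%.
#'
#' @param nOriginal peak count of the original orientation (> 0).
#' @param nSwapped peak count after swapping experiment and control (>= 0).
#' @return FDR in percent.
#' @examples
#' swapFdr(100, 30)  # 30
#' @export
swapFdr <- function(nOriginal, nSwapped) {
    if (length(nOriginal) != 1L || is.na(nOriginal) || nOriginal <= 0)
        stop("'nOriginal' must be a single positive count; the FDR is ",
            "undefined for zero original peaks")
    if (length(nSwapped) != 1L || is.na(nSwapped) || nSwapped < 0)
        stop("'nSwapped' must be a single non-negative count")
    100 * nSwapped / nOriginal
}

# regex character class for one IUPAC code; sequence N never matches since
# classes list concrete bases only
.iupacClass <- function(code) {
    bases <- .IUPAC[[code]]
    if (nchar(bases) == 1L) bases else paste0("[", bases, "]")
}

.motifRegex <- function(pattern) {
    codes <- strsplit(pattern, "")[[1L]]
    paste0(vapply(codes, .iupacClass, character(1L)), collapse = "")
}

.revcompIupac <- function(pattern) {
    comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", pattern)
    paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

#' Count motif occurrences in a DNA sequence
#'
#' Counts all (possibly overlapping) match positions of an IUPAC-degenerate
#' pattern. By default both strands are scanned: the forward pattern and its
#' reverse complement are matched against the given sequence, since binding
#' sites occur strand-agnostically. `N` in the pattern matches any base; `N`
#' in the sequence matches nothing.
#'
#' @param seq a DNA string (character or [Biostrings::DNAString]) over
#'   A/C/G/T/N.
#' @param m a [Motif-class] (or IUPAC string, coerced).
#' @param bothStrands scan the reverse complement too (default `TRUE`)?
#' @return Non-negative integer occurrence count.
#' @examples
#' countMotif("GATGGGT", motif("GANGGGT"))  # N matches T
#' @export
countMotif <- function(seq, m, bothStrands = TRUE) {
    if (!is(m, "Motif"))
        m <- motif(m)
    validObject(m)
    seq <- toupper(as.character(seq))
    bad <- setdiff(unique(strsplit(seq, "")[[1L]]), c("A", "C", "G", "T", "N"))
    if (length(bad))
        stop("sequence contains non-ACGTN character(s): ",
            paste(bad, collapse = ", "))
    pats <- m@pattern
    if (bothStrands) {
        rc <- .revcompIupac(m@pattern)
        pats <- c(pats, rc)
    }
    total <- 0L
    for (p in pats) {
        hits <- gregexpr(paste0("(?=", .motifRegex(p), ")"), seq,
            perl = TRUE)[[1L]]
        total <- total + sum(hits > 0L)
    }
    total
}

#' Motif enrichment score of a peak set
#'
#' For each chromosome, the same number of random intervals with the same
#' lengths as the called peaks are drawn with uniform random start positions
#' (fully contained in the chromosome). The enrichment score is the total
#' motif occurrence count inside the peaks divided by the count inside the
#' random intervals, summed over all motifs. A score of 1 indicates no
#' enrichment over random placement.
#'
#' @param peaks a `GRanges` of called peaks.
#' @param genome a named [Biostrings::DNAStringSet] (or named character
#'   vector) holding every chromosome the peaks use.
#' @param motifs a [Motif-class], IUPAC string, or list of either.
#' @param seed integer seed for the random interval draw.
#' @param bothStrands passed to [countMotif()].
#' @return A list: `score`, `peakCount`, `randomCount`, `smoothed` (TRUE
#'   when the +1 denominator smoothing was applied because the random
#'   intervals held no occurrence).
#' @export
enrichmentScore <- function(peaks, genome, motifs, seed = 1L,
                            bothStrands = TRUE) {
    if (is(motifs, "Motif") || is.character(motifs) && length(motifs) == 1L)
        motifs <- list(motifs)
    motifs <- lapply(motifs, function(m) if (is(m, "Motif")) m else motif(m))
    seqs <- if (is(genome, "DNAStringSet"))
        stats::setNames(as.character(genome), names(genome)) else
        genome
    chroms <- unique(as.character(GenomicRanges::seqnames(peaks)))
    missing <- setdiff(chroms, names(seqs))
    if (length(missing))
        stop("chromosome(s) absent from the genome: ",
            paste(missing, collapse = ", "))
    set.seed(as.integer(seed))
    peakCount <- randomCount <- 0L
    for (ch in chroms) {
        sel <- peaks[as.character(GenomicRanges::seqnames(peaks)) == ch]
        chromSeq <- seqs[[ch]]
        chromLen <- nchar(chromSeq)
        wd <- GenomicRanges::width(sel)
        if (any(wd > chromLen))
            stop("peak wider than chromosome ", ch)
        randStart <- floor(runif(length(sel), min = 1,
            max = chromLen - wd + 1 + 1))
        randStart <- pmin(randStart, chromLen - wd + 1)
        for (i in seq_along(sel)) {
            pseq <- substr(chromSeq, GenomicRanges::start(sel)[i],
                GenomicRanges::end(sel)[i])
            rseq <- substr(chromSeq, randStart[i], randStart[i] + wd[i] - 1L)
            for (m in motifs) {
                peakCount <- peakCount + countMotif(pseq, m, bothStrands)
                randomCount <- randomCount + countMotif(rseq, m, bothStrands)
            }
        }
    }
    smoothed <- randomCount == 0L
    denom <- randomCount + as.integer(smoothed)
    if (smoothed)
        warning("no motif occurrence in the random intervals; ",
            "applying +1 smoothing to the denominator")
    list(score = peakCount / denom, peakCount = peakCount,
        randomCount = randomCount, smoothed = smoothed)
}

#' Summit-based overlap between two peak sets
#'
#' A peak is considered detected by another method when its summit lies
#' inside a region called by that method. The counts are directional: a
#' sharp caller can recover most of a broad caller's peaks without the
#' converse holding.
#'
#' @param a,b `GRanges` peak sets; a missing `summit` metadata column
#'   defaults to the interval midpoint.
#' @return A list: `aInB` (peaks of `a` whose summit falls in a region of
#'   `b`), `bInA`, `aOnly`, `bOnly`, and `pctADetectedByB` / `pctBDetectedByA`
#'   (percentages of one set's peaks recovered by the other).
#' @examples
#' p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
#' summitOverlap(p, p)$pctADetectedByB  # 100
#' @export
summitOverlap <- function(a, b) {
    summitsOf <- function(x) {
        if (length(x) == 0L)
            return(GenomicRanges::GRanges())
        s <- x$summit
        if (is.null(s))
            s <- (GenomicRanges::start(x) + GenomicRanges::end(x)) %/% 2L
        GenomicRanges::GRanges(GenomicRanges::seqnames(x),
            IRanges::IRanges(s, s))
    }
    aInB <- if (length(a) && length(b))
        sum(IRanges::overlapsAny(summitsOf(a), b)) else 0L
    bInA <- if (length(a) && length(b))
        sum(IRanges::overlapsAny(summitsOf(b), a)) else 0L
    list(aInB = aInB, bInA = bInA,
        aOnly = length(a) - aInB, bOnly = length(b) - bInA,
        pctADetectedByB = if (length(a)) 100 * aInB / length(a) else NA_real_,
        pctBDetectedByA = if (length(b)) 100 * bInA / length(b) else NA_real_)
}

#' Assign genomic features to peaks
#'
#' A peak receives every feature label (gene, exon, intron, promoter, ...)
#' whose annotated interval it overlaps by at least one bp; a peak inside a
#' gene's exon therefore counts as both gene and exon, so the per-label
#' percentages can sum to more than 100. Peaks overlapping no annotation are
#' labelled `inter-genetic`.
#'
#' @param peaks a `GRanges` of peaks.
#' @param annotations a `GRanges` with a `feature` metadata column of
#'   labels.
#' @return A data.frame with columns `feature`, `regions` (peak count) and
#'   `pct` (percentage of peaks), one row per label plus `inter-genetic`.
#' @export
assignFeatures <- function(peaks, annotations) {
    if (is.null(annotations$feature))
        stop("'annotations' must carry a 'feature' metadata column")
    labels <- sort(unique(as.character(annotations$feature)))
    n <- length(peaks)
    cnt <- integer(length(labels))
    anyHit <- logical(n)
    for (i in seq_along(labels)) {
        ann <- annotations[as.character(annotations$feature) == labels[i]]
        hit <- IRanges::overlapsAny(peaks, ann, minoverlap = 1L)
        cnt[i] <- sum(hit)
        anyHit <- anyHit | hit
    }
    out <- data.frame(feature = c(labels, "inter-genetic"),
        regions = c(cnt, sum(!anyHit)),
        stringsAsFactors = FALSE)
    out$pct <- if (n > 0) 100 * out$regions / n else NA_real_
    out
}

#' Read motifs from a text file
#'
#' One motif per line: an IUPAC pattern optionally followed by a label,
#' whitespace-separated. Lines starting with `#` are ignored.
#'
#' @param path motif file path.
#' @return A list of [Motif-class] objects.
#' @export
readMotifs <- function(path) {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lapply(lines, function(ln) {
        f <- strsplit(ln, "[ \t]+")[[1L]]
        motif(f[1L], if (length(f) > 1L) f[2L] else f[1L])
    })
}
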