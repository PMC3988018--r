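# Seeded synthetic ChIP-Seq data with known ground truth: uniform background
# reads plus planted enriched regions, a matched background-only control,
# and i.i.d. genomes with planted motif instances.

#' Simulate a ChIP-Seq experiment with planted peaks
#'
#' Background reads are scattered uniformly over the chromosome with random
#' strands. Each planted peak receives additional reads whose fragment
#' midpoints are uniform over the peak interval, in expectation raising the
#' peak's coverage to `fold` times the background coverage
#' (`nBackgroundReads * fragmentLength / chromLength`); read counts per peak
#' are Poisson-sampled. Peak reads are placed strand-aware: a plus-strand
#' read starts half a fragment left of its midpoint, a minus-strand read
#' ends half a fragment right of it, so that after extension the pileup has
#' the characteristic shape of real ChIP fragments
#' (`strandAware = FALSE` places the read interval directly at the
#' midpoint). The control holds background-only reads, scaled by
#' `controlDepthRatio`. Everything is reproducible from `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @param strandAware place peak reads by strand-offset 5' positions
#'   (default) or centred on their midpoint?
#' @return A list: `experiment` and `control` (stranded read `GRanges` with
#'   a `name` column), `truth` (planted regions as `GRanges` with `fold`),
#'   and `labels` (per-experiment-read origin factor: `background` or
#'   `peak<i>`).
#' @examples
#' sim <- simulateReads(simulationConfig(chromLength = 1e4,
#'     nBackgroundReads = 200, peaks = data.frame(centre = 5000,
#'     width = 300, fold = 10), seed = 42))
#' table(sim$labels)
#' @export
simulateReads <- function(config, strandAware = TRUE) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(as.integer(config@seed))
    L <- config@chromLength
    rl <- config@readLength
    fl <- config@fragmentLength
    ch <- config@chrom

    drawBackground <- function(n) {
        if (n == 0L)
            return(GenomicRanges::GRanges())
        starts <- floor(runif(n, min = 1, max = L - rl + 2))
        strands <- sample(c("+", "-"), n, replace = TRUE)
        GenomicRanges::GRanges(ch, IRanges::IRanges(starts, width = rl),
            strand = strands)
    }

    nBg <- as.integer(round(config@nBackgroundReads))
    expBg <- drawBackground(nBg)
    bgCov <- nBg * fl / L

    pk <- config@peaks
    peakReads <- GenomicRanges::GRanges()
    labels <- rep("background", nBg)
    for (i in seq_len(nrow(pk))) {
        lambda <- (pk$fold[i] - 1) * bgCov * pk$width[i] / fl
        nPeak <- rpois(1L, lambda)
        if (nPeak == 0L) next
        lo <- pk$centre[i] - pk$width[i] / 2
        mids <- runif(nPeak, min = lo, max = lo + pk$width[i])
        strands <- sample(c("+", "-"), nPeak, replace = TRUE)
        if (strandAware) {
            starts <- ifelse(strands == "+", round(mids - fl / 2),
                round(mids + fl / 2) - rl + 1)
        } else {
            starts <- round(mids - rl / 2)
        }
        starts <- pmin(pmax(starts, 1), L - rl + 1)
        peakReads <- c(peakReads, GenomicRanges::GRanges(ch,
            IRanges::IRanges(starts, width = rl), strand = strands))
        labels <- c(labels, rep(paste0("peak", i), nPeak))
    }

    experiment <- c(expBg, peakReads)
    if (length(experiment))
        experiment$name <- paste0("exp_", seq_along(experiment))
    control <- drawBackground(as.integer(round(
        config@nBackgroundReads * config@controlDepthRatio)))
    if (length(control))
        control$name <- paste0("ctrl_", seq_along(control))

    truth <- if (nrow(pk))
        GenomicRanges::GRanges(ch, IRanges::IRanges(
            start = round(pk$centre - pk$width / 2),
            width = round(pk$width)), fold = pk$fold)
    else GenomicRanges::GRanges()

    list(experiment = experiment, control = control, truth = truth,
        labels = factor(labels))
}

#' Simulate a genome sequence with planted motif instances
#'
#' Bases are drawn i.i.d. at the requested GC fraction; motif instances are
#' then overwritten at the stated 1-based positions, with degenerate IUPAC
#' codes instantiated uniformly from their matching bases. Planted instances
#' must not overlap.
#'
#' @param length sequence length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param planted list of `list(motif = <Motif or IUPAC string>,
#'   positions = <integer vector>)` entries; empty list plants nothing.
#' @param seed integer RNG seed.
#' @param name sequence (chromosome) name.
#' @return A named [Biostrings::DNAStringSet] of length 1.
#' @examples
#' g <- simulateGenome(1000, 0.5, list(list(motif = "TGCATG",
#'     positions = 101)), seed = 3)
#' countMotif(as.character(g[[1]]), motif("TGCATG")) >= 1
#' @export
simulateGenome <- function(length, gc = 0.5, planted = list(), seed = 1L,
                           name = "chrSim") {
    seqLen <- as.integer(length)
    length <- base::length             # unshadow base::length
    stopifnot(seqLen >= 1, gc >= 0, gc <= 1)
    set.seed(as.integer(seed))
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(p), seqLen, replace = TRUE, prob = p)
    occupied <- IRanges::IRanges()
    for (entry in planted) {
        m <- entry$motif
        if (!is(m, "Motif")) m <- motif(m)
        w <- nchar(m@pattern)
        codes <- strsplit(m@pattern, "")[[1L]]
        for (pos in entry$positions) {
            if (pos < 1 || pos + w - 1 > seqLen)
                stop("planted motif at position ", pos,
                    " exceeds the sequence bounds")
            iv <- IRanges::IRanges(pos, pos + w - 1L)
            if (length(occupied) && any(IRanges::overlapsAny(iv, occupied)))
                stop("planted motifs overlap at position ", pos)
            occupied <- c(occupied, iv)
            inst <- vapply(codes, function(cd) {
                opts <- strsplit(.IUPAC[[cd]], "")[[1L]]
                if (length(opts) == 1L) opts else sample(opts, 1L)
            }, character(1L))
            bases[pos:(pos + w - 1L)] <- inst
        }
    }
    out <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(out) <- name
    out
}
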