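# BED input/output and strand-aware fragment extension.
#
# Internally all intervals are 1-based closed (GRanges convention); BED files
# are 0-based half-open, converted at these boundaries only.

#' Read aligned reads from a BED file
#'
#' Parses a BED6 file of aligned read positions (chrom, start, end, name,
#' score, strand). Strand is required: the caller extends each read to a
#' fragment in its strand direction, which is undefined without it.
#'
#' @param path path to a BED file with at least 6 columns.
#' @return A [GenomicRanges::GRanges] of reads, in file order, with strand.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t136\tr1\t0\t+", bed)
#' readBed(bed)
#' @export
readBed <- function(path) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        return(GenomicRanges::GRanges())
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 6L)) {
        bad <- which(nf < 6L)[1L]
        if (nf[bad] >= 3L)
            stop("BED line ", bad, " has only ", nf[bad], " fields; ",
                "a strand column (field 6) is required to extend reads ",
                "to fragments")
        stop("malformed BED line ", bad, ": expected >= 6 fields, got ",
            nf[bad])
    }
    chromv <- vapply(fields, `[`, character(1L), 1L)
    startv <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1L), 2L)))
    endv <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1L), 3L)))
    strandv <- vapply(fields, `[`, character(1L), 6L)
    if (anyNA(startv) || anyNA(endv)) {
        bad <- which(is.na(startv) | is.na(endv))[1L]
        stop("malformed BED line ", bad, ": non-numeric coordinates")
    }
    if (any(startv < 0)) {
        bad <- which(startv < 0)[1L]
        stop("malformed BED line ", bad, ": negative start coordinate")
    }
    if (any(startv >= endv)) {
        bad <- which(startv >= endv)[1L]
        stop("malformed BED line ", bad, ": start (", startv[bad],
            ") must be < end (", endv[bad], ")")
    }
    okStrand <- strandv %in% c("+", "-")
    if (!all(okStrand)) {
        bad <- which(!okStrand)[1L]
        stop("BED line ", bad, ": strand must be '+' or '-' (got '",
            strandv[bad], "'); strand is required to extend reads to ",
            "fragments")
    }
    GenomicRanges::GRanges(chromv,
        IRanges::IRanges(start = startv + 1, end = endv),
        strand = strandv,
        name = vapply(fields, `[`, character(1L), 4L))
}

#' Extend reads to fragments in their strand direction
#'
#' Each read is extended to the sonication fragment length: a plus-strand
#' read keeps its 5' start and grows rightward; a minus-strand read keeps its
#' 3' coordinate (its 5' end on the minus strand) and grows leftward.
#' Fragments running past the chromosome origin are clipped at position 1;
#' right-side clipping is applied only when chromosome lengths are supplied,
#' since a BED file alone does not carry them.
#'
#' @param reads a stranded [GenomicRanges::GRanges] of reads.
#' @param fragmentLength target fragment length in bp (>= 1).
#' @param chromSizes optional named vector of chromosome lengths for
#'   right-side clipping.
#' @return A `GRanges` of fragments (strand dropped).
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 136), strand = "+")
#' extendReads(r, 200)
#' @export
extendReads <- function(reads, fragmentLength, chromSizes = NULL) {
    if (length(fragmentLength) != 1L || is.na(fragmentLength) ||
        fragmentLength < 1)
        stop("'fragmentLength' must be a single value >= 1")
    if (length(reads) == 0L)
        return(GenomicRanges::granges(reads))
    if (any(GenomicRanges::strand(reads) == "*"))
        stop("reads must be stranded ('+' or '-') for fragment extension")
    frags <- GenomicRanges::resize(reads, width = round(fragmentLength),
        fix = "start", ignore.strand = FALSE)
    # clip at the chromosome origin (minus-strand reads near position 1)
    over <- GenomicRanges::start(frags) < 1L
    if (any(over))
        GenomicRanges::start(frags)[over] <- 1L
    if (!is.null(chromSizes)) {
        sz <- chromSizes[as.character(GenomicRanges::seqnames(frags))]
        over <- !is.na(sz) & GenomicRanges::end(frags) > sz
        if (any(over))
            GenomicRanges::end(frags)[over] <- sz[over]
    }
    frags <- GenomicRanges::granges(frags)
    GenomicRanges::strand(frags) <- "*"
    frags
}

#' Read a two-column chromosome-sizes file
#'
#' @param path whitespace-separated file with chromosome name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("chrom-sizes file must have two columns: name, length")
    stats::setNames(as.numeric(tab[[2L]]), tab[[1L]])
}

.fmtScore <- function(x) {
    # plain decimal notation, trailing zeros trimmed
    out <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
    sub("0+$", "", sub("\\.$", "", out))
    out <- sub("(\\.\\d*?)0+$", "\\1", out)
    sub("\\.$", "", out)
}

#' Write called peaks to a BED6+1 file
#'
#' One line per region: chrom, start, end, name `CMT_peak_<i>`, score (fold
#' enrichment), strand `.`, and a seventh column with the summit offset from
#' the region start. Coordinates are written 0-based half-open per the BED
#' standard. The file round-trips through [readPeaksBed()].
#'
#' @param regions a [GenomicRanges::GRanges] of peaks sorted by
#'   (chrom, start), with metadata columns `summit`, `height` and
#'   `foldEnrichment` as produced by [callPeaks()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writePeaksBed <- function(regions, path) {
    if (length(regions)) {
        o <- order(as.character(GenomicRanges::seqnames(regions)),
            GenomicRanges::start(regions))
        if (!identical(o, seq_along(regions)))
            stop("'regions' must be sorted by (chrom, start)")
    }
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(regions) == 0L)
        return(invisible(path))
    mc <- S4Vectors::mcols(regions)
    fe <- if ("foldEnrichment" %in% names(mc)) mc$foldEnrichment else
        rep(0, length(regions))
    summit <- if ("summit" %in% names(mc)) mc$summit else
        GenomicRanges::start(regions)
    lines <- paste(as.character(GenomicRanges::seqnames(regions)),
        GenomicRanges::start(regions) - 1L,
        GenomicRanges::end(regions),
        paste0("CMT_peak_", seq_along(regions)),
        .fmtScore(fe), ".",
        summit - GenomicRanges::start(regions),
        sep = "\t")
    writeLines(lines, con)
    invisible(path)
}

#' Read a peak BED file written by writePeaksBed
#'
#' @param path path to a BED6+1 peak file.
#' @return A `GRanges` with `summit`, `foldEnrichment` and `name` metadata
#'   columns.
#' @export
readPeaksBed <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        return(GenomicRanges::GRanges())
    fields <- strsplit(lines, "\t")
    if (any(lengths(fields) < 7L))
        stop("peak BED must have 7 columns (BED6 + summit offset)")
    startv <- as.numeric(vapply(fields, `[`, character(1L), 2L)) + 1
    gr <- GenomicRanges::GRanges(vapply(fields, `[`, character(1L), 1L),
        IRanges::IRanges(start = startv,
            end = as.numeric(vapply(fields, `[`, character(1L), 3L))))
    gr$name <- vapply(fields, `[`, character(1L), 4L)
    gr$foldEnrichment <- as.numeric(vapply(fields, `[`, character(1L), 5L))
    gr$summit <- startv + as.numeric(vapply(fields, `[`, character(1L), 7L))
    gr
}

#' Write reads to a BED6 file
#'
#' Serializes a stranded read set (e.g. from [simulateReads()]) as BED6,
#' 0-based half-open, score 0.
#'
#' @param reads stranded `GRanges`; an optional `name` metadata column is
#'   used for field 4, otherwise `read_<i>`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeReadsBed <- function(reads, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(reads) == 0L)
        return(invisible(path))
    nm <- if (!is.null(reads$name)) reads$name else
        paste0("read_", seq_along(reads))
    lines <- paste(as.character(GenomicRanges::seqnames(reads)),
        GenomicRanges::start(reads) - 1L,
        GenomicRanges::end(reads),
        nm, 0L, as.character(GenomicRanges::strand(reads)),
        sep = "\t")
    writeLines(lines, con)
    invisible(path)
}
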