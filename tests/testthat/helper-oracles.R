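# Independent first-principles oracles used to check the implementation.
# These deliberately avoid the package's running-sum / vectorized code
# paths: everything is recomputed by direct summation or per-position
# counting.

# per-position pileup counter: counts fragments covering each position of
# [origin, origin + len - 1] by looping over fragments
oraclePileup <- function(starts, ends, origin, len) {
    out <- integer(len)
    for (k in seq_along(starts)) {
        lo <- max(starts[k], origin)
        hi <- min(ends[k], origin + len - 1L)
        if (lo <= hi) {
            i <- (lo - origin + 1L):(hi - origin + 1L)
            out[i] <- out[i] + 1L
        }
    }
    out
}

# closed-form between-class variance omega1*omega2*(mu1-mu2)^2, classes
# recomputed by direct summation
oracleSigma <- function(w, t) {
    p <- w / sum(w)
    n <- length(w)
    idx <- seq_len(n)
    w1 <- sum(p[seq_len(t)])
    w2 <- sum(p[(t + 1L):n])
    if (w1 <= 0 || w2 <= 0)
        return(0)
    mu1 <- sum(p[seq_len(t)] * idx[seq_len(t)]) / w1
    mu2 <- sum(p[(t + 1L):n] * idx[(t + 1L):n]) / w2
    w1 * w2 * (mu1 - mu2)^2
}

# exhaustive division-point sweep: evaluates oracleSigma at every admissible
# split (valley bins below minReads within the constrained range, falling
# back to the whole range) and applies the shared plateau-centre tie rule
oracleDivision <- function(w, minR, minReads) {
    rng <- minR:(length(w) - 1L)
    adm <- rng[w[rng] < minReads]
    if (!length(adm))
        adm <- rng
    s <- vapply(adm, function(t) oracleSigma(w, t), numeric(1L))
    mx <- max(s)
    tol <- if (mx > 0) mx * 1e-12 else 0
    hit <- s >= mx - tol
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)[1L]
    adm[(starts[k] + ends[k]) %/% 2L]
}

# position-by-position IUPAC matcher over both strands
.oracleIupac <- c(A = "A", C = "C", G = "G", T = "T",
    R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
    B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.oracleRevcomp <- function(pattern) {
    comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", pattern)
    paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

oracleCountMotif <- function(seq, pattern, bothStrands = TRUE) {
    scan1 <- function(seq, pat) {
        s <- strsplit(seq, "")[[1L]]
        pt <- strsplit(pat, "")[[1L]]
        n <- length(s)
        m <- length(pt)
        if (n < m)
            return(0L)
        cnt <- 0L
        for (i in seq_len(n - m + 1L)) {
            ok <- TRUE
            for (j in seq_len(m)) {
                allowed <- strsplit(.oracleIupac[[pt[j]]], "")[[1L]]
                if (!(s[i + j - 1L] %in% allowed)) {
                    ok <- FALSE
                    break
                }
            }
            if (ok)
                cnt <- cnt + 1L
        }
        cnt
    }
    total <- scan1(seq, pattern)
    if (bothStrands)
        total <- total + scan1(seq, .oracleRevcomp(pattern))
    total
}

# convenience builders
mkReads <- function(chrom, starts, ends, strands) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
        strand = strands)
}

mkHist <- function(counts, chrom = "chr1", origin = 1L) {
    CoverageHistogram(chrom, origin, as.integer(counts))
}

mkRegion <- function(chrom, start, end, summit = NULL, height = NULL,
                     fe = NULL) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    gr$summit <- if (is.null(summit)) (start + end) %/% 2L else summit
    if (!is.null(height)) gr$height <- height
    if (!is.null(fe)) gr$foldEnrichment <- fe
    gr
}
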