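# Border shrinking, squared densities and the k-fold enrichment filter.

test_that("shrinkRegion keeps the contiguous supported footprint around the summit", {
    h <- mkHist(c(0, 0, 1, 3, 5, 3, 1, 0))
    r <- mkRegion("chr1", 1, 8, summit = 5, height = 5L)
    s <- shrinkRegion(h, r, cutoff = 1)
    expect_equal(GenomicRanges::start(s), 3L)
    expect_equal(GenomicRanges::end(s), 7L)
    expect_equal(s$summit, 5)

    # all bins at/above the cutoff: identity
    h2 <- mkHist(c(2, 3, 4, 3, 2))
    r2 <- mkRegion("chr1", 1, 5, summit = 3)
    s2 <- shrinkRegion(h2, r2, cutoff = 1)
    expect_equal(GenomicRanges::ranges(s2), GenomicRanges::ranges(r2))

    # disconnected block left of an internal zero is dropped
    h3 <- mkHist(c(2, 0, 3, 5))
    r3 <- mkRegion("chr1", 1, 4, summit = 4)
    s3 <- shrinkRegion(h3, r3, cutoff = 1)
    expect_equal(GenomicRanges::start(s3), 3L)
    expect_equal(GenomicRanges::end(s3), 4L)

    expect_error(shrinkRegion(h3, mkRegion("chr1", 1, 4, summit = 2),
        cutoff = 1), "below the cut-off")
})

test_that("shrinking is idempotent, never expands, and keeps the summit", {
    set.seed(501)
    for (rep in 1:20) {
        w <- rpois(200, 2)
        h <- mkHist(w)
        lo <- sample(1:100, 1L)
        hi <- lo + sample(20:99, 1L)
        seg <- w[lo:hi]
        if (max(seg) < 1) next
        summit <- lo + which.max(seg) - 1L
        r <- mkRegion("chr1", lo, hi, summit = summit)
        s1 <- shrinkRegion(h, r, cutoff = 1)
        s2 <- shrinkRegion(h, s1, cutoff = 1)
        expect_equal(GenomicRanges::ranges(s2), GenomicRanges::ranges(s1))
        expect_gte(GenomicRanges::start(s1), lo)
        expect_lte(GenomicRanges::end(s1), hi)
        expect_true(GenomicRanges::start(s1) <= summit &&
            summit <= GenomicRanges::end(s1))
        # every bin kept is at/above the cutoff
        expect_true(all(heightAt(h,
            GenomicRanges::start(s1):GenomicRanges::end(s1)) >= 1))
    }
})

test_that("squaredDensity computes the mean of squared heights", {
    expect_equal(squaredDensity(mkHist(c(2, 2)), 1, 2), 4)
    expect_equal(squaredDensity(mkHist(numeric(10)), 2, 8), 0)
    expect_equal(squaredDensity(mkHist(3), 1, 1), 9)
    # positions outside the extent contribute zero height
    expect_equal(squaredDensity(mkHist(c(4, 4), origin = 10), 8, 13),
        (0 + 0 + 16 + 16 + 0 + 0) / 6)
    # alternative definition for sensitivity analysis
    expect_equal(squaredDensity(mkHist(c(1, 3)), 1, 2,
        method = "squared-mean"), 4)
    expect_error(squaredDensity(mkHist(c(1, 2)), 5, 4), "start <= end")
})

test_that("isEnriched applies the size and k-fold squared-density rules", {
    p <- cmtParams(minRegion = 2, maxRegion = 100, kFold = 2)
    r <- mkRegion("chr1", 1, 2, summit = 1, height = 2L)

    # exp [2,2] vs ctrl [1,1]: densities 4 vs 1, 4 >= 2*1 -> passed
    res <- isEnriched(mkHist(c(2, 2)), mkHist(c(1, 1)), r, p,
        scaleControl = FALSE)
    expect_true(res$passed)
    expect_equal(res$expDensity, 4)
    expect_equal(res$ctrlDensity, 1)

    # experiment identical to control: D >= 2D fails for D > 0
    res2 <- isEnriched(mkHist(c(2, 2)), mkHist(c(2, 2)), r, p,
        scaleControl = FALSE)
    expect_false(res2$passed)

    # zero control must not veto experimental signal, fold stays finite
    res3 <- isEnriched(mkHist(c(2, 2)), mkHist(numeric(2)), r, p,
        scaleControl = FALSE)
    expect_true(res3$passed)
    expect_true(is.finite(res3$region$foldEnrichment))

    # size filter: a 2-bp region fails when minRegion = 10
    p10 <- cmtParams(minRegion = 10, maxRegion = 100, kFold = 2)
    expect_false(isEnriched(mkHist(c(9, 9)), mkHist(c(1, 1)), r, p10,
        scaleControl = FALSE)$passed)
})

test_that("library-size scaling of the control behaves as depth correction", {
    # control at half depth: scaling by 2 restores equality -> not enriched
    r <- mkRegion("chr1", 1, 4, summit = 1)
    p <- cmtParams(minRegion = 2, maxRegion = 100, kFold = 2)
    expHist <- mkHist(c(4, 4, 4, 4))
    ctrlHist <- mkHist(c(2, 2, 2, 2))
    expect_false(isEnriched(expHist, ctrlHist, r, p, scaleFactor = 2)$passed)
    # without scaling the raw 2-fold density ratio is 4 -> passes
    expect_true(isEnriched(expHist, ctrlHist, r, p,
        scaleControl = FALSE)$passed)
})

test_that("the passed set shrinks as k grows and is scale invariant", {
    set.seed(502)
    w <- rpois(500, 1)
    w[101:150] <- w[101:150] + rpois(50, 6)
    w[301:340] <- w[301:340] + rpois(40, 2)
    expHist <- mkHist(w)
    ctrlHist <- mkHist(rpois(500, 1))
    regions <- c(mkRegion("chr1", 101, 150, summit = 120),
        mkRegion("chr1", 301, 340, summit = 310),
        mkRegion("chr1", 401, 430, summit = 405))
    passedAt <- function(k, scale = 1) {
        p <- cmtParams(minRegion = 10, maxRegion = 200, kFold = k)
        eh <- mkHist(counts(expHist) * scale)
        ch <- mkHist(counts(ctrlHist) * scale)
        which(vapply(seq_along(regions), function(i)
            isEnriched(eh, ch, regions[i], p, scaleControl = FALSE)$passed,
            logical(1L)))
    }
    ks <- c(1, 2, 4, 8, 16)
    sets <- lapply(ks, passedAt)
    for (i in seq_len(length(ks) - 1L))
        expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
    # joint positive scaling does not change the decision
    for (k in ks)
        expect_equal(passedAt(k, scale = 3), passedAt(k))
})

test_that("rankRegions orders passed regions by fold enrichment", {
    gr <- c(mkRegion("chr1", 1, 10, fe = 1.2), mkRegion("chr1", 21, 30,
        fe = 9.0), mkRegion("chr1", 41, 50, fe = 3.3))
    gr$passed <- TRUE
    expect_equal(rankRegions(gr)$foldEnrichment, c(9.0, 3.3, 1.2))

    gr$passed <- FALSE
    expect_equal(length(rankRegions(gr)), 0L)

    # equal fold enrichment: (chrom, start) ascending
    tie <- GenomicRanges::GRanges(c("chr2", "chr1", "chr1"),
        IRanges::IRanges(c(5, 50, 5), c(10, 60, 10)))
    tie$foldEnrichment <- c(2, 2, 2)
    tie$passed <- TRUE
    ranked <- rankRegions(tie)
    expect_equal(as.character(GenomicRanges::seqnames(ranked)),
        c("chr1", "chr1", "chr2"))
    expect_equal(GenomicRanges::start(ranked)[1:2], c(5L, 50L))
})
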