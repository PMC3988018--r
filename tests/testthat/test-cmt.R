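# The constrained thresholding engine: between-class variance, division
# points, gap skipping and chromosome scanning.

test_that("betweenClassVariance matches the two-class closed form", {
    # all mass in one bin: one class is always empty
    x <- numeric(10); x[4] <- 7
    for (t in c(1, 3, 5, 9)) expect_equal(betweenClassVariance(x, t), 0)

    # equal spikes at indices 10 and 20: omega1*omega2*(mu1-mu2)^2 = 25
    y <- numeric(21); y[10] <- 5; y[20] <- 5
    expect_equal(betweenClassVariance(y, 14), 0.5 * 0.5 * (20 - 10)^2)

    # [4,0,0,4]: constant 2.25 across the whole valley plateau
    for (t in 1:3)
        expect_equal(betweenClassVariance(c(4, 0, 0, 4), t), 2.25)

    expect_error(betweenClassVariance(numeric(5), 2), "zero total")
    expect_error(betweenClassVariance(c(1, 2), 2), "t")
})

test_that("running-sum sweep equals direct recomputation at every split", {
    set.seed(101)
    for (rep in 1:25) {
        n <- sample(20:300, 1L)
        w <- rpois(n, sample(c(0.5, 2, 10), 1L))
        if (sum(w) == 0) w[sample(n, 1L)] <- 3
        sweep <- cmtseq:::.sigmaBSweep(w)
        for (t in unique(round(seq(1, n - 1, length.out = 15)))) {
            direct <- betweenClassVariance(w, t)
            expect_equal(sweep[t], direct, tolerance = 1e-9)
            expect_equal(direct, oracleSigma(w, t), tolerance = 1e-9)
        }
    }
})

test_that("class masses and means decompose the total mean", {
    set.seed(102)
    for (rep in 1:10) {
        n <- sample(30:200, 1L)
        w <- rpois(n, 4)
        if (sum(w) == 0) next
        p <- w / sum(w)
        idx <- seq_len(n)
        muT <- sum(p * idx)
        for (t in seq_len(n - 1L)) {
            w1 <- sum(p[1:t]); w2 <- 1 - w1
            if (w1 <= 0 || w2 <= 0) next
            mu1 <- sum(p[1:t] * idx[1:t]) / w1
            mu2 <- sum(p[(t + 1):n] * idx[(t + 1):n]) / w2
            expect_equal(w1 * mu1 + w2 * mu2, muT, tolerance = 1e-9)
        }
    }
})

test_that("findDivisionPoint places the boundary at the valley centre", {
    # two equal triangular peaks with a zero valley between them
    tri <- c(1:10, 9:1)
    w <- c(tri, numeric(62), tri)          # centres 100 bp apart
    h <- mkHist(c(w, numeric(120)))        # window longer than the signal
    p <- cmtParams(minRegion = 10, maxRegion = 200, minReads = 1)
    d <- findDivisionPoint(h, 1, p)
    valley <- which(w == 0)                # zero bins between the peaks
    mid <- valley[(1 + length(valley)) %/% 2]
    expect_true(d %in% valley)             # boundary inside the valley ...
    expect_lte(abs(d - mid), 1)            # ... at its centre
    expect_equal(d, 1 + oracleDivision(counts(h)[1:200], 10, 1))

    # constraint binding: valley at offset 5, but minRegion = 50
    w2 <- c(3, 3, 3, 3, 0, 0, rep(3, 194))
    h2 <- mkHist(w2)
    p2 <- cmtParams(minRegion = 50, maxRegion = 200, minReads = 1)
    d2 <- findDivisionPoint(h2, 1, p2)
    expect_gte(d2, 1 + 50)
    expect_equal(d2, 1 + oracleDivision(w2, 50, 1))

    # a window with no bin reaching minReads signals a gap
    expect_true(is.na(findDivisionPoint(mkHist(rep(1, 100)), 1,
        cmtParams(minRegion = 10, maxRegion = 100, minReads = 5))))
})

test_that("findDivisionPoint equals the exhaustive sweep oracle on random windows", {
    for (seed in 1:30) {
        set.seed(200 + seed)
        n <- sample(60:800, 1L)
        lam <- sample(c(1, 3, 8), 1L)
        w <- rpois(n, lam)
        # plant a couple of enriched stretches so windows look peak-like
        for (k in 1:2) {
            at <- sample(n - 20, 1L)
            w[at:(at + 19)] <- w[at:(at + 19)] + rpois(20, 5 * lam)
        }
        minR <- sample(5:30, 1L)
        minReads <- sample(c(1, lam + 1, 3 * lam), 1L)
        if (max(w) < minReads) next
        h <- mkHist(w)
        p <- cmtParams(minRegion = minR, maxRegion = n, minReads = minReads)
        expect_equal(findDivisionPoint(h, 1, p),
            1 + oracleDivision(w, minR, minReads),
            info = paste("seed", seed))
    }
})

test_that("gapSkip finds the first supported position", {
    p <- cmtParams(minRegion = 50, maxRegion = 500, minReads = 5)
    # all-zero histogram: end sentinel
    expect_true(is.na(gapSkip(mkHist(numeric(1000)), 1, p)))
    # signal far downstream: linear-scan oracle
    w <- numeric(5000); w[3001:3100] <- 9
    h <- mkHist(w)
    g <- gapSkip(h, 1, p)
    expect_equal(g, which(w >= 5)[1])
    expect_lte(g, 3001)
    # idempotence inside signal
    expect_equal(gapSkip(h, 3050, p), 3050)
    # skipping from beyond the signal finds nothing
    expect_true(is.na(gapSkip(h, 3101, p)))
})

test_that("scanChromosome segments blocks into the expected candidates", {
    p <- cmtParams(minRegion = 50, maxRegion = 1000, minReads = 5)
    # flat zero -> nothing
    expect_equal(length(scanChromosome(mkHist(numeric(2000)), p)), 0L)
    expect_equal(length(scanChromosome(mkHist(integer()), p)), 0L)

    # one block of coverage 10 spanning 200 bp -> exactly one candidate
    w <- numeric(2000); w[101:300] <- 10
    cand <- scanChromosome(mkHist(w), p)
    expect_equal(length(cand), 1L)
    expect_lte(GenomicRanges::start(cand), 101)
    expect_gte(GenomicRanges::end(cand), 300)
    expect_equal(cand$height, 10L)

    # two well-separated blocks -> two candidates, boundary in the gap
    w2 <- w; w2[1201:1400] <- 10
    cand2 <- scanChromosome(mkHist(w2), p)
    expect_equal(length(cand2), 2L)
    expect_gte(GenomicRanges::start(cand2)[2], 301)
    expect_lte(GenomicRanges::end(cand2)[1], 1200)
    expect_lte(GenomicRanges::end(cand2)[1], GenomicRanges::start(cand2)[2])
})

test_that("every supported bin lies inside some candidate region", {
    for (seed in 1:10) {
        set.seed(300 + seed)
        w <- rpois(4000, 0.5)
        for (k in 1:4) {
            at <- sample(3800, 1L)
            w[at:(at + 60)] <- w[at:(at + 60)] + rpois(61, 8)
        }
        p <- cmtParams(minRegion = 30, maxRegion = 600, minReads = 6)
        cand <- scanChromosome(mkHist(w), p)
        supported <- which(w >= 6)
        if (length(cand)) {
            covered <- unlist(mapply(seq,
                GenomicRanges::start(cand), GenomicRanges::end(cand),
                SIMPLIFY = FALSE))
            expect_true(all(supported %in% covered))
            # candidates are sorted and non-overlapping
            expect_true(all(diff(GenomicRanges::start(cand)) > 0))
            expect_true(all(GenomicRanges::end(cand)[-length(cand)] <
                GenomicRanges::start(cand)[-1]))
        } else {
            expect_equal(length(supported), 0L)
        }
    }
})

test_that("evaluation count grows linearly with chromosome length", {
    # deterministic periodic signal at fixed density
    unit <- c(rep(10, 100), numeric(400))
    p <- cmtParams(minRegion = 50, maxRegion = 400, minReads = 5)
    n1 <- S4Vectors::metadata(scanChromosome(mkHist(rep(unit, 20)), p))$nEvaluations
    n2 <- S4Vectors::metadata(scanChromosome(mkHist(rep(unit, 40)), p))$nEvaluations
    expect_lte(n2, 2 * n1)
    expect_gt(n2, n1)
})
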