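test_that("SE bins are genome-grid bins intersecting the span", {
    # BED span [12000, 26000) at 5 kb: bins 2..5
    se <- gr("chr1", 12001, 26000)
    b <- seBins(se, 5000)
    expect_equal(S4Vectors::mcols(b)$bin, 2:5)
    expect_equal(BiocGenerics::start(b), c(10001, 15001, 20001, 25001))
    expect_equal(BiocGenerics::end(b), c(15000, 20000, 25000, 30000))

    inside <- gr("chr1", 7001, 9000)   # fully inside bin 1
    expect_equal(S4Vectors::mcols(seBins(inside, 5000))$bin, 1)

    set.seed(14)
    for (rep in 1:20) {
        s0 <- sample.int(1e6, 1)
        w <- sample.int(60000, 1)
        region <- gr("chr1", s0 + 1, s0 + w)
        b <- seBins(region, 5000)
        expect_equal(length(b), floor((s0 + w - 1) / 5000) -
                                floor(s0 / 5000) + 1)
        expect_true(all(overlapAny(b, region)))
        # bins tile the span: the union covers the region
        expect_true(BiocGenerics::start(b)[1] <= s0 + 1)
        expect_true(BiocGenerics::end(b)[length(b)] >= s0 + w)
    }
})

test_that("the H-score is the maximum population z-score, zero when degenerate", {
    hz <- hScore(c(2, 2, 2, 14))
    expect_equal(hz$H, sqrt(3))
    expect_equal(hz$z, c(-1, -1, -1, 3) / sqrt(3))

    expect_equal(hScore(c(5, 5, 5, 5))$H, 0)
    expect_equal(hScore(0)$H, 0)         # single bin
    expect_equal(hScore(7)$H, 0)
    expect_error(hScore(numeric(0)), "non-empty")

    # invariance under positive affine transforms
    set.seed(15)
    f <- rpois(12, 6)
    base <- hScore(f)
    tr <- hScore(3.7 * f + 11)
    expect_equal(tr$z, base$z)
    expect_equal(tr$H, base$H)

    # extremal bound sqrt(n - 1), attained by one-outlier vectors
    for (rep in 1:50) {
        f <- rpois(sample(2:30, 1), 8)
        expect_lte(hScore(f)$H, sqrt(length(f) - 1) + 1e-12)
    }
    for (n in 2:10) {
        oneHot <- c(rep(0, n - 1), 5)
        expect_equal(hScore(oneHot)$H, sqrt(n - 1))
    }
})

test_that("raising one bin's frequency never lowers its z-score", {
    set.seed(16)
    for (rep in 1:20) {
        f <- rpois(8, 5)
        i <- sample(8, 1)
        z1 <- hScore(f)$z[i]
        f2 <- f
        f2[i] <- f2[i] + sample(1:10, 1)
        z2 <- hScore(f2)$z[i]
        expect_gte(z2, z1 - 1e-12)
    }
})

test_that("hierarchy calls threshold strictly and label hub enhancers by overlap", {
    res <- 5000
    # two SEs: one with a dominant bin, one flat
    peaksA <- gr("chr1", c(10101, 16001, 23001, 27001),
                 c(11100, 17500, 24500, 28500),
                 score = c(30, 40, 35, 20))
    peaksB <- gr("chr1", c(200101, 206001), c(201600, 207500),
                 score = c(30, 30))
    sset <- rankSE(stitchEnhancers(c(peaksA, peaksB), gap = 12500))
    S4Vectors::mcols(sset@regions)$isSuper <- c(TRUE, TRUE)
    # dominant frequency in bin 3 (BED [15000,20000)) of SE A
    track <- new("BinFrequencyTrack", resolution = res,
                 counts = data.frame(chrom = "chr1", bin = c(2, 3, 4),
                                     count = c(1L, 12L, 1L)))
    calls <- hierarchyCalls(sset, track, threshold = 1.5)
    expect_equal(isHierarchical(calls), c(TRUE, FALSE))
    hub <- hubEnhancers(calls)
    expect_length(hub, 1)
    expect_equal(BiocGenerics::start(hub), 16001)   # overlaps bin 3
    nh <- nonhubEnhancers(calls)
    expect_length(nh, 3)
    # labels exist only within hierarchical SEs
    expect_true(all(is.na(calls@labels[5:6])))

    # a 2-bin SE can reach at most H = 1: never hierarchical at 1.5
    two <- gr("chr1", 500001, 507000, score = 10)
    s2 <- rankSE(stitchEnhancers(two))
    S4Vectors::mcols(s2@regions)$isSuper <- TRUE
    t2 <- new("BinFrequencyTrack", resolution = res,
              counts = data.frame(chrom = "chr1", bin = c(100, 101),
                                  count = c(0L, 50L)))
    c2 <- hierarchyCalls(s2, t2, threshold = 1.5)
    expect_equal(hScores(c2), 1)
    expect_false(isHierarchical(c2))

    # threshold sweeps move calls in the expected direction
    c125 <- hierarchyCalls(sset, track, threshold = 1.25)
    c175 <- hierarchyCalls(sset, track, threshold = 1.75)
    expect_gte(sum(isHierarchical(c125)), sum(isHierarchical(calls)))
    expect_lte(sum(isHierarchical(c175)), sum(isHierarchical(calls)))
})

test_that("hub labels equal a brute-force overlap of constituents with hub bins", {
    set.seed(17)
    res <- 5000
    for (rep in 1:5) {
        nSE <- 20
        peaks <- list()
        for (i in seq_len(nSE)) {
            base <- (i - 1) * 100000
            k <- sample(3:6, 1)
            starts <- base + sort(sample(seq(0, 35000, by = 1500), k))
            peaks[[i]] <- gr("chr1", starts + 1, starts + 1200,
                             score = runif(k, 10, 50))
        }
        sset <- rankSE(stitchEnhancers(do.call(c, peaks), gap = 12500))
        S4Vectors::mcols(sset@regions)$isSuper <- TRUE
        allBins <- seBins(seRegions(sset), res)
        freq <- rpois(length(allBins), 2) +
            ifelse(runif(length(allBins)) < 0.2, 15, 0)
        track <- new("BinFrequencyTrack", resolution = res,
                     counts = data.frame(
                         chrom = "chr1",
                         bin = S4Vectors::mcols(allBins)$bin,
                         count = as.integer(freq)))
        calls <- hierarchyCalls(sset, track, threshold = 1.5)
        flat <- unlist(seConstituents(calls), use.names = FALSE)
        nReg <- length(seRegions(calls))   # blocks may split when stitched
        seIdx <- rep(seq_len(nReg), lengths(seConstituents(calls)))
        for (i in seq_len(nReg)) {
            bins <- seBins(seRegions(calls)[i], res)
            hz <- hScore(binFrequencies(track, "chr1",
                                        S4Vectors::mcols(bins)$bin))
            if (hz$H > 1.5) {
                hubBins <- bins[hz$z > 1.5]
                want <- ifelse(naiveOverlapAny(flat[seIdx == i], hubBins),
                               "hub", "non-hub")
                expect_equal(calls@labels[seIdx == i], want)
                # partition: hub and non-hub cover the constituents
                expect_false(anyNA(calls@labels[seIdx == i]))
            } else {
                expect_true(all(is.na(calls@labels[seIdx == i])))
            }
        }
    }
})

test_that("interaction-subtype filtering drops exactly the matching pairs", {
    res <- 5000
    enh <- gr("chr1", 10001, 12000)         # in bin 2
    ctcf <- gr("chr1", 52001, 52500)        # in bin 10
    prom <- gr("chr1", 101001, 103000)      # in bin 20
    mids <- function(b) b * res + res / 2
    cs <- contactSet(rep("chr1", 3), mids(c(2, 2, 10)),
                     mids(c(10, 20, 20)), c(4, 5, 6), resolution = res)

    expect_identical(filterInteractionsByType(cs, "none"), cs)

    dropEC <- filterInteractionsByType(cs, "enhancer-CTCF",
        enhancers = enh, ctcf = ctcf, promoters = prom)
    expect_equal(contactRecords(dropEC)$rawCount, c(5, 6))

    dropEP <- filterInteractionsByType(cs, "enhancer-promoter",
        enhancers = enh, ctcf = ctcf, promoters = prom)
    expect_equal(contactRecords(dropEP)$rawCount, c(4, 6))

    expect_error(filterInteractionsByType(cs, "enhancer-enhancer-x"),
                 "arg")

    # brute force on a random fixture
    set.seed(18)
    nb <- 60
    b1 <- sample.int(nb, 80, replace = TRUE) - 1
    b2 <- b1 + sample.int(20, 80, replace = TRUE)
    cs <- contactSet(rep("chr1", 80), mids(b1), mids(b2), rep(1, 80),
                     resolution = res)
    r <- contactRecords(cs)
    sets <- list(enhancer = randomIntervals(15, chroms = "chr1",
                                            maxPos = nb * res),
                 CTCF = randomIntervals(15, chroms = "chr1",
                                        maxPos = nb * res),
                 promoter = randomIntervals(15, chroms = "chr1",
                                            maxPos = nb * res))
    binGR <- function(mid) gr("chr1", mid - res / 2 + 1, mid + res / 2)
    for (excl in c("enhancer-CTCF", "enhancer-enhancer",
                   "enhancer-promoter")) {
        lab <- strsplit(excl, "-")[[1]]
        keep <- logical(nrow(r))
        for (k in seq_len(nrow(r))) {
            a1 <- binGR(r$mid1[k])
            a2 <- binGR(r$mid2[k])
            h <- function(a, wh) any(naiveOverlapAny(a, sets[[wh]]))
            drop <- (h(a1, lab[1]) && h(a2, lab[2])) ||
                    (h(a1, lab[2]) && h(a2, lab[1]))
            keep[k] <- !drop
        }
        got <- filterInteractionsByType(cs, excl,
            enhancers = sets$enhancer, ctcf = sets$CTCF,
            promoters = sets$promoter)
        expect_equal(contactRecords(got), r[keep, ],
                     ignore_attr = "row.names")
    }
})
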