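test_that("fold enrichment follows (m/n)/(M/N) and Fisher matches the exact oracle", {
    # direct formula: m=10, n=100, M=1000, N=100000 -> 10.0
    mkLoci <- function(n, hit, offset = 0) {
        # `hit` loci covering variant positions, the rest far away
        s <- c(seq_len(hit) * 1000, 5e7 + offset + seq_len(n - hit) * 1000)
        gr("chr1", s, s + 10)
    }
    v <- gr("chr1", seq_len(1000) * 1000, seq_len(1000) * 1000)
    gl <- mkLoci(100, 10)
    bl <- mkLoci(100000, 1000, offset = 7e7)
    er <- enrichmentScore(gl, v, bl)
    expect_equal(er@score, 10)
    expect_equal(c(er@m, er@n, er@M, er@N), c(10, 100, 1000, 100000))

    # background against itself scores exactly 1
    self <- enrichmentScore(bl, v, bl)
    expect_identical(self@score, 1)
    expect_equal(self@fisherP, 1)

    expect_error(enrichmentScore(GenomicRanges::GRanges(), v, bl),
                 "undefined")

    # Fisher p equals the hypergeometric-sum oracle on random small tables
    set.seed(19)
    for (rep in 1:50) {
        n <- sample(5:80, 1)
        N <- sample(20:120, 1)
        m <- sample(0:n, 1)
        M <- sample(0:N, 1)
        p <- stats::fisher.test(matrix(c(m, n - m, M, N - M), 2,
                                       byrow = TRUE))$p.value
        expect_equal(p, oracleFisherP(m, n, M, N), tolerance = 1e-10)
    }

    # brute-force recount on random interval fixtures
    set.seed(20)
    for (rep in 1:10) {
        grp <- randomIntervals(30)
        bg <- randomIntervals(200)
        vv <- randomIntervals(60, maxWidth = 5)
        m <- sum(naiveOverlapAny(grp, vv))
        M <- sum(naiveOverlapAny(bg, vv))
        if (M == 0) next
        er <- enrichmentScore(grp, vv, bg)
        expect_equal(er@score, (m / 30) / (M / 200))
        expect_equal(er@fisherP, oracleFisherP(m, 30, M, 200),
                     tolerance = 1e-10)
    }

    # per-variant counting mode counts occurrences, not loci
    g2 <- gr("chr1", 1, 100)
    v2 <- gr("chr1", c(10, 20, 30), c(10, 20, 30))
    b2 <- gr("chr1", c(1, 201), c(100, 300))
    erL <- enrichmentScore(g2, v2, b2, countMode = "loci")
    erV <- enrichmentScore(g2, v2, b2, countMode = "variants")
    expect_equal(erL@m, 1)
    expect_equal(erV@m, 3)
})

test_that("CTCF context classes partition the peaks with the exclusion rule", {
    hub <- gr("chr1", c(1000, 5000), c(1500, 5500))
    nonhub <- gr("chr1", 9000, 9500)
    bound <- gr("chr1", c(5200, 20000), c(5800, 20500))
    ctcf <- gr("chr1", c(1100, 5300, 9100, 20100, 30000),
               c(1200, 5400, 9200, 20200, 30100))
    ctx <- ctcfContext(ctcf, hub, nonhub, bound)
    expect_equal(as.character(S4Vectors::mcols(ctx)$context),
                 c("hub", "excluded", "non-hub", "TAD-boundary", "other"))

    # partition property on random fixtures
    set.seed(22)
    pk <- randomIntervals(300)
    h <- randomIntervals(40)
    nh <- randomIntervals(40)
    b <- randomIntervals(40)
    ctx <- S4Vectors::mcols(ctcfContext(pk, h, nh, b))$context
    expect_false(anyNA(ctx))
    onH <- naiveOverlapAny(pk, h)
    onB <- naiveOverlapAny(pk, b)
    onN <- naiveOverlapAny(pk, nh)
    want <- ifelse(onH & onB, "excluded",
            ifelse(onH, "hub",
            ifelse(onB, "TAD-boundary",
            ifelse(onN, "non-hub", "other"))))
    expect_equal(as.character(ctx), want)
})

test_that("consensus score is the percentage of cell types detecting the peak", {
    peak <- gr("chr1", 1000, 2000)
    sets <- lapply(1:55, function(i) {
        if (i <= 11) gr("chr1", 1500, 2500) else gr("chr1", 50000, 51000)
    })
    expect_equal(consensusScore(peak, sets), 20)
    expect_equal(consensusScore(peak, sets[1:11]), 100)

    set.seed(23)
    peaks <- randomIntervals(50)
    sets <- lapply(1:8, function(i) randomIntervals(30))
    got <- consensusScore(peaks, sets)
    naive <- sapply(seq_along(peaks), function(i)
        100 * mean(sapply(sets, function(s)
            any(naiveOverlapAny(peaks[i], s)))))
    expect_equal(got, naive)
})

test_that("motif scanning maximizes log-odds over offsets and strands", {
    pwm <- toyPWM()
    # the consensus sequence attains the PWM's maximum attainable score
    hit <- motifScan("ACGTCA", pwm)
    p <- sweep(pwm + 1e-3, 2, colSums(pwm + 1e-3), "/")
    maxAttainable <- sum(log2(apply(p, 2, max) / 0.25))
    expect_equal(hit$maxScore, maxAttainable)
    expect_equal(hit$bestStart, 1)
    expect_equal(hit$bestStrand, "+")

    # uniform PWM with uniform background scores 0 everywhere
    u <- matrix(1, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
    flat <- motifScan("ACGTACGTAC", u)
    expect_equal(flat$maxScore, 0)
    expect_true(all(abs(flat$scores) < 1e-12))

    # reverse-complement hits score like forward hits
    expect_equal(motifScan("TGACGT", pwm)$maxScore, maxAttainable)
    expect_equal(motifScan("TGACGT", pwm)$bestStrand, "-")

    # brute-force oracle over offsets and strands on random sequences
    set.seed(24)
    for (rep in 1:5) {
        s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                   collapse = "")
        expect_equal(motifScan(s, pwm)$maxScore, oracleMotifScan(s, pwm))
    }

    # ambiguous bases contribute background odds (zero)
    expect_equal(motifScan("NNNNNN", pwm)$maxScore, 0)
    expect_error(motifScan("ACG", pwm), "shorter")

    # FASTA front-end scans every record; short records get NA
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">hit", "TTACGTCATT", ">miss", "GGGGGGGG", ">short",
                 "ACG"), fa)
    tab <- motifScanFasta(fa, pwm)
    expect_equal(tab$name, c("hit", "miss", "short"))
    expect_equal(tab$maxScore[1], maxAttainable)
    expect_equal(tab$bestStart[1], 3)
    expect_lt(tab$maxScore[2], 0)
    expect_true(is.na(tab$maxScore[3]))
})

test_that("signal profiles average per-offset signal around centers", {
    # constant track: flat profile at the constant
    track <- gr("chr1", 1, 100000, score = 3)
    centers <- gr("chr1", c(20001, 50001), c(20001, 50001))
    prof <- siteproProfile(track, centers, flank = 1000, bin = 100)
    expect_equal(nrow(prof), 20)
    expect_true(all(prof$value == 3))
    expect_equal(prof$offset, seq(-1000, 900, by = 100))

    # spike at the center shows up at offset 0
    spike <- gr("chr1", 50001, 50100, score = 10)
    p2 <- siteproProfile(spike, gr("chr1", 50001, 50001),
                         flank = 500, bin = 100)
    expect_equal(which.max(p2$value), which(p2$offset == 0))

    # point features recover the offset histogram exactly (no smoothing)
    centersP <- gr("chr1", c(10001, 30001), c(10001, 30001))
    feat <- gr("chr1", c(10051, 30051, 30052, 9952), c(10051, 30051, 30052, 9952))
    pf <- siteproProfile(feat, centersP, flank = 100, bin = 50,
                         pointFeatures = TRUE)
    expect_equal(pf$offset, c(-100, -50, 0, 50))
    expect_equal(pf$value, c(0, 0.5, 0, 1.5))

    # smoothing is a centered moving average
    ps <- siteproProfile(feat, centersP, flank = 100, bin = 50,
                         smoothing = 150, pointFeatures = TRUE)
    expect_equal(ps$value[2], mean(c(0, 0.5, 0)))

    # brute-force per-center extraction on a random interval track
    set.seed(25)
    ivs <- gr("chr1", seq(1, 99000, by = 1000),
              seq(1, 99000, by = 1000) + sample(100:900, 99, TRUE),
              score = runif(99, 0, 5))
    pos <- sample(5000:90000, 20)
    ctr <- gr("chr1", pos, pos)
    got <- siteproProfile(ivs, ctr, flank = 500, bin = 100)
    cov <- numeric(100000)
    for (i in seq_along(ivs)) {
        idx <- BiocGenerics::start(ivs)[i]:BiocGenerics::end(ivs)[i]
        cov[idx] <- cov[idx] + S4Vectors::mcols(ivs)$score[i]
    }
    naive <- matrix(0, length(ctr), 10)
    for (i in seq_along(ctr)) {
        mid0 <- BiocGenerics::start(ctr)[i] - 1
        vals <- cov[(mid0 - 500 + 1):(mid0 + 500)]
        naive[i, ] <- colMeans(matrix(vals, nrow = 100))
    }
    expect_equal(got$value, colMeans(naive))
})

test_that("enhancer-promoter edges require a connecting pair within one TAD", {
    res <- 5000
    mids <- function(b) b * res + res / 2
    enh <- gr("chr1", c(10001, 210001), c(12000, 212000))
    tssGR <- gr("chr1", c(52001, 252001), c(52001, 252001),
                name = c("GENE1", "GENE2"))
    prom <- promotersFromTSS(tssGR, 2000)
    tads <- gr("chr1", c(1, 200001), c(200000, 400000))
    # pair 1 connects enh1 (bin 2) to prom1 (bin 10), both in TAD 1
    # pair 2 connects enh1 to prom2 across the TAD border: no edge
    cs <- contactSet(rep("chr1", 2), mids(c(2, 2)), mids(c(10, 50)),
                     c(3, 3), resolution = res)
    ep <- mapEnhancersToPromoters(enh, prom, cs, tads)
    expect_equal(nrow(ep$edges), 1)
    expect_equal(ep$edges$enhancerIndex, 1)
    expect_equal(ep$edges$promoterIndex, 1)
    expect_equal(ep$edges$gene, "GENE1")
    expect_equal(ep$targetCounts, c(1, 0))

    # no significant pairs: empty map
    none <- contactSet(character(0), numeric(0), numeric(0), numeric(0),
                       resolution = res)
    expect_equal(nrow(mapEnhancersToPromoters(enh, prom, none,
                                              tads)$edges), 0)

    # brute-force triple-overlap oracle
    set.seed(26)
    nb <- 80
    enh <- randomIntervals(10, chroms = "chr1", maxPos = nb * res)
    promPts <- sample(seq(5000, nb * res - 5000, by = 500), 10)
    prom <- gr("chr1", pmax(promPts - 2000, 1), promPts + 2000)
    b1 <- sample.int(nb - 20, 30, replace = TRUE) - 1
    b2 <- b1 + sample.int(20, 30, replace = TRUE)
    cs <- contactSet(rep("chr1", 30), mids(b1), mids(b2), rep(1, 30),
                     resolution = res)
    edgesTad <- sort(c(0, sample(seq(10, nb - 10, by = 7), 4), nb))
    tads <- gr("chr1", head(edgesTad, -1) * res + 1,
               tail(edgesTad, -1) * res)
    got <- mapEnhancersToPromoters(enh, prom, cs, tads)
    r <- contactRecords(cs)
    binGR <- function(mid) gr("chr1", mid - res / 2 + 1, mid + res / 2)
    want <- character(0)
    for (k in seq_len(nrow(r))) for (e in 1:10) for (p in 1:10) {
        for (ori in 1:2) {
            aE <- binGR(if (ori == 1) r$mid1[k] else r$mid2[k])
            aP <- binGR(if (ori == 1) r$mid2[k] else r$mid1[k])
            if (!any(naiveOverlapAny(aE, enh[e]))) next
            if (!any(naiveOverlapAny(aP, prom[p]))) next
            for (t in seq_along(tads)) {
                if (any(naiveOverlapAny(enh[e], tads[t])) &&
                    any(naiveOverlapAny(prom[p], tads[t])) &&
                    any(naiveOverlapAny(aE, tads[t])) &&
                    any(naiveOverlapAny(aP, tads[t]))) {
                    want <- c(want, paste(e, p))
                    break
                }
            }
        }
    }
    expect_setequal(paste(got$edges$enhancerIndex,
                          got$edges$promoterIndex), unique(want))
})

test_that("expression specificity is fold-change over the cell-type mean", {
    expr <- rbind(flat = c(2, 2, 2, 2), only = c(8, 0, 0, 0),
                  zero = c(0, 0, 0, 0))
    colnames(expr) <- c("K562", "A", "B", "C")
    sp <- expressionSpecificity(expr, "K562")
    expect_equal(unname(sp["flat"]), 1)
    expect_equal(unname(sp["only"]), 4)   # expressed in 1 of 4 cell types
    expect_true(is.na(sp["zero"]))

    set.seed(27)
    m <- matrix(rexp(60), 12, 5, dimnames = list(NULL, letters[1:5]))
    expect_equal(expressionSpecificity(m, "c"), m[, "c"] / rowMeans(m))
    expect_error(expressionSpecificity(-m, "c"), "non-negative")
})

test_that("boundary overlap fraction and trait keyword filter behave", {
    hub <- gr("chr1", c(1000, 5000, 9000), c(1999, 5999, 9999))
    expect_equal(boundaryOverlapFraction(hub, GenomicRanges::GRanges()), 0)
    expect_equal(boundaryOverlapFraction(hub, gr("chr1", 1, 20000)), 100)
    expect_equal(boundaryOverlapFraction(hub, gr("chr1", 5500, 5600)),
                 100 / 3)
    expect_error(boundaryOverlapFraction(GenomicRanges::GRanges(),
                                         gr("chr1", 1, 10)), "undefined")

    traits <- c("Platelet count", "Height", "chronic lymphocytic leukemia",
                "Type 2 diabetes", "Mean corpuscular hemoglobin")
    expect_equal(bloodTraitFilter(traits), c(TRUE, FALSE, TRUE, FALSE, TRUE))
})
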