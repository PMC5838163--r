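suppressPackageStartupMessages(library(GenomicRanges))

# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive (O(n^2) scans, explicit loops) so it stays independent
# of the package's implementation paths.

gr <- function(chrom, start1, end1, ...) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1), ...)
}

# Random interval set on a toy genome (1-based closed coordinates).
randomIntervals <- function(n, chroms = c("chr1", "chr2"), maxPos = 1e5,
                            maxWidth = 500) {
    chrom <- sample(chroms, n, replace = TRUE)
    start1 <- sample.int(maxPos, n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE)
    gr(chrom, start1, start1 + w - 1)
}

# Naive 1-bp-shared overlap between two single intervals.
naivePairOverlap <- function(c1, s1, e1, c2, s2, e2) {
    c1 == c2 && s1 <= e2 && s2 <= e1
}

# Naive any-overlap of each query against a subject set.
naiveOverlapAny <- function(query, subjects) {
    qc <- as.character(GenomeInfoDb::seqnames(query))
    qs <- BiocGenerics::start(query)
    qe <- BiocGenerics::end(query)
    sc <- as.character(GenomeInfoDb::seqnames(subjects))
    ss <- BiocGenerics::start(subjects)
    se <- BiocGenerics::end(subjects)
    out <- logical(length(query))
    for (i in seq_along(query)) {
        hit <- FALSE
        for (j in seq_along(subjects)) {
            if (naivePairOverlap(qc[i], qs[i], qe[i], sc[j], ss[j], se[j])) {
                hit <- TRUE
                break
            }
        }
        out[i] <- hit
    }
    out
}

# Two-pass mean/SD/max oracle for the H-score (population SD).
oracleHScore <- function(f) {
    n <- length(f)
    s <- 0
    for (x in f) s <- s + x
    mu <- s / n
    ss <- 0
    for (x in f) ss <- ss + (x - mu)^2
    sdev <- sqrt(ss / n)
    if (sdev == 0) return(list(z = rep(0, n), H = 0))
    z <- numeric(n)
    for (i in seq_len(n)) z[i] <- (f[i] - mu) / sdev
    list(z = z, H = max(z))
}

# Two-sided Fisher exact p by direct hypergeometric summation for the table
# [[m, n-m], [M, N-M]] (rows: group / background; columns: hit / miss).
oracleFisherP <- function(m, n, M, N) {
    k <- m + M                    # column total of hits
    support <- max(0, k - N):min(n, k)
    dobs <- stats::dhyper(m, k, n + N - k, n)
    d <- stats::dhyper(support, k, n + N - k, n)
    sum(d[d <= dobs * (1 + 1e-7)])
}

# Toy 6-bp PWM (counts) with consensus ACGTCA.
toyPWM <- function() {
    m <- matrix(1, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
    consensus <- c("A", "C", "G", "T", "C", "A")
    for (j in seq_along(consensus)) m[consensus[j], j] <- 20
    m
}

# Naive per-offset, per-strand log-odds scan (character arithmetic only).
oracleMotifScan <- function(seqChar, pwm, background = rep(0.25, 4),
                            pseudocount = 1e-3) {
    bases <- c("A", "C", "G", "T")
    p <- pwm[bases, , drop = FALSE] + pseudocount
    p <- sweep(p, 2, colSums(p), "/")
    w <- ncol(p)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    scoreWindow <- function(win) {
        sc <- 0
        for (j in seq_len(w)) {
            b <- substr(win, j, j)
            if (b %in% bases)
                sc <- sc + log2(p[b, j] / background[match(b, bases)])
        }
        sc
    }
    best <- -Inf
    for (off in seq_len(nchar(seqChar) - w + 1)) {
        win <- substr(seqChar, off, off + w - 1)
        rc <- paste(rev(unname(comp[strsplit(win, "")[[1]]])),
                    collapse = "")
        best <- max(best, scoreWindow(win), scoreWindow(rc))
    }
    best
}

# Small raw symmetric contact matrix with positive entries.
randomSymmetricMatrix <- function(n, maxCount = 50) {
    m <- matrix(stats::rpois(n * n, maxCount / 2) + 1, n, n)
    m <- m + t(m)
    diag(m) <- 0
    m
}

# Shared heavyweight fixture for hierarchy recovery tests: built once per
# test run (lazily) and reused across test files.
recoveryEnv <- new.env()
recoveryFixture <- function() {
    if (is.null(recoveryEnv$sim)) {
        cfg <- simConfig(seed = 7, nChrom = 2, chromLength = 5e6,
                         nSE = 52, nRE = 20, fracHierarchical = 0.5,
                         hubFold = 5)
        sim <- simulateFixture(cfg)
        sset <- callSuperEnhancers(sim$peaks)
        hic <- hicSignificant(sim$contacts, seqinfo = sim$seqinfo)
        calls <- hierarchyCalls(sset, hic$track)
        recoveryEnv$sim <- sim
        recoveryEnv$sset <- sset
        recoveryEnv$hic <- hic
        recoveryEnv$calls <- calls
        recoveryEnv$eval <- evaluateRecovery(sim, calls)
    }
    as.list(recoveryEnv)
}
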