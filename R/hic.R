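#' @include io.R
NULL

#' Significance-caller configuration
#'
#' Defaults follow the standard distance-corrected calling setup at 5 kb
#' resolution: interactions tested between 10 kb and 2 Mb, FDR 0.01, with
#' 100 equal-occupancy distance strata for the expected model.
#'
#' @param L minimum genomic distance tested (bp)
#' @param U maximum genomic distance tested (bp)
#' @param fdr BH-adjusted significance threshold
#' @param nDistanceBins number of equal-occupancy distance strata
#' @param minPairBias low-coverage QC floor: pairs whose relative balancing
#'   weight product (`bias` column written by [normalizeContacts()]) falls
#'   below this value are excluded from testing. Bins near chromosome ends
#'   have structurally truncated rows; iterative correction mistakes the
#'   deficit for bias and inflates their normalized counts, which would
#'   show up as spurious significant pairs.
#' @return a named list
#' @export
significanceConfig <- function(L = 10000, U = 2e6, fdr = 0.01,
                               nDistanceBins = 100, minPairBias = 0.9) {
    if (!(L > 0 && L < U)) stop("need 0 < L < U")
    if (!(fdr > 0 && fdr < 1)) stop("need 0 < fdr < 1")
    if (nDistanceBins < 1) stop("need nDistanceBins >= 1")
    list(L = L, U = U, fdr = fdr, nDistanceBins = nDistanceBins,
         minPairBias = minPairBias)
}

# Tested-pair predicate shared by fitExpected and callSignificant.
testedPairs <- function(records, config) {
    ok <- records$distance >= config$L & records$distance <= config$U
    if (!is.null(records$bias) && !is.null(config$minPairBias))
        ok <- ok & (is.na(records$bias) |
                    records$bias >= config$minPairBias)
    ok
}

#' Iterative correction (ICE) of a raw contact matrix
#'
#' Balances a symmetric non-negative contact matrix by iterative correction:
#' at each step every entry `(i, j)` is divided by `b_i * b_j`, where `b` is
#' the current vector of row sums rescaled to mean 1 over unmasked rows,
#' until the coefficient of variation (CV) of unmasked row sums falls below
#' `tol`. Rows that are entirely zero are masked and their bias is fixed at
#' 1. The accumulated bias vector satisfies the reconstruction contract
#' `raw[i, j] = norm[i, j] * bias[i] * bias[j] * scale` exactly (here
#' `scale = 1`).
#'
#' @param mat square, symmetric, non-negative matrix (raw counts)
#' @param maxIter iteration cap
#' @param tol CV convergence tolerance on unmasked row sums
#' @return list with `matrix` (balanced), `bias`, `scale`, `iterations`,
#'   `cv` (final CV), and `masked` (logical vector of all-zero rows)
#' @export
iceNormalize <- function(mat, maxIter = 300, tol = 1e-8) {
    if (!is.matrix(mat) || nrow(mat) != ncol(mat))
        stop("mat must be a square matrix")
    if (any(mat < 0)) stop("mat must be non-negative")
    if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat))))
        stop("mat must be symmetric")
    n <- nrow(mat)
    masked <- rowSums(mat) == 0
    if (all(masked)) stop("no unmasked rows")
    bias <- rep(1, n)
    cv <- Inf
    iter <- 0L
    while (iter < maxIter) {
        s <- rowSums(mat)
        su <- s[!masked]
        cv <- stats::sd(su) / mean(su)
        if (is.na(cv)) cv <- 0   # single unmasked row
        if (cv < tol) break
        d <- s / mean(su)
        d[masked] <- 1
        mat <- mat / outer(d, d)
        bias <- bias * d
        iter <- iter + 1L
    }
    if (iter == maxIter) {
        s <- rowSums(mat)
        su <- s[!masked]
        cv <- stats::sd(su) / mean(su)
        if (is.na(cv)) cv <- 0
    }
    list(matrix = mat, bias = bias, scale = 1, iterations = iter, cv = cv,
         masked = masked)
}

#' Build a dense contact matrix for one chromosome
#'
#' Bins are anchored to the genome grid: bin `k` covers
#' `[k*resolution, (k+1)*resolution)` (0-based), midpoints at
#' `k*resolution + resolution/2`.
#'
#' @param contacts a [ContactSet]
#' @param chrom chromosome name
#' @param nBins number of bins (e.g. `ceiling(chromLength / resolution)`);
#'   if NULL, inferred from the largest midpoint
#' @return symmetric numeric matrix of raw counts
#' @export
contactMatrix <- function(contacts, chrom, nBins = NULL) {
    r <- contacts@records
    r <- r[r$chrom == chrom, , drop = FALSE]
    res <- contacts@resolution
    i <- (r$mid1 - res / 2) / res + 1
    j <- (r$mid2 - res / 2) / res + 1
    if (is.null(nBins))
        nBins <- if (nrow(r)) max(j) else 0L
    m <- matrix(0, nBins, nBins)
    if (nrow(r)) {
        m[cbind(i, j)] <- r$rawCount
        m[cbind(j, i)] <- r$rawCount
    }
    m
}

#' ICE-normalize the contacts of every chromosome
#'
#' Builds the dense per-chromosome matrix, balances it with [iceNormalize()],
#' and writes the balanced values back into the record table's `normCount`.
#'
#' @param contacts a [ContactSet]
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] fixing the bin count per
#'   chromosome
#' @param maxIter,tol passed to [iceNormalize()]
#' @return the [ContactSet] with `normCount` replaced by balanced counts
#' @export
normalizeContacts <- function(contacts, seqinfo = NULL, maxIter = 300,
                              tol = 1e-8) {
    r <- contacts@records
    res <- contacts@resolution
    r$bias <- NA_real_
    for (chrom in unique(r$chrom)) {
        nBins <- NULL
        if (!is.null(seqinfo)) {
            len <- GenomeInfoDb::seqlengths(seqinfo)[chrom]
            if (!is.na(len)) nBins <- ceiling(len / res)
        }
        m <- contactMatrix(contacts, chrom, nBins)
        ice <- iceNormalize(m, maxIter = maxIter, tol = tol)
        sel <- r$chrom == chrom
        i <- (r$mid1[sel] - res / 2) / res + 1
        j <- (r$mid2[sel] - res / 2) / res + 1
        r$normCount[sel] <- ice$matrix[cbind(i, j)]
        # relative balancing weight of each pair; used as a QC filter by
        # the significance caller (see significanceConfig)
        medb <- stats::median(ice$bias[!ice$masked])
        rel <- ice$bias / medb
        r$bias[sel] <- rel[i] * rel[j]
    }
    methods::new("ContactSet", records = r, resolution = contacts@resolution)
}

# Group tested pairs into ~equal-occupancy strata of consecutive distances.
# All pairs sharing a genomic distance stay in one stratum so the fitted
# step function of distance is well defined.
equalOccupancyBins <- function(distance, nBins) {
    tab <- sort(unique(distance))
    cnt <- tabulate(match(distance, tab), nbins = length(tab))
    n <- length(distance)
    target <- n / nBins
    grp <- integer(length(tab))
    g <- 1L
    acc <- 0
    for (k in seq_along(tab)) {
        if (acc >= target && g < nBins) {
            g <- g + 1L
            acc <- 0
        }
        grp[k] <- g
        acc <- acc + cnt[k]
    }
    grp[match(distance, tab)]
}

# Pool-adjacent-violators: weighted monotone non-increasing fit.
pavaNonIncreasing <- function(y, w) {
    n <- length(y)
    vals <- y
    wts <- w
    sizes <- rep(1L, n)
    m <- 0L
    for (k in seq_len(n)) {
        m <- m + 1L
        vals[m] <- y[k]
        wts[m] <- w[k]
        sizes[m] <- 1L
        while (m > 1L && vals[m - 1L] < vals[m]) {
            tot <- wts[m - 1L] + wts[m]
            vals[m - 1L] <- (vals[m - 1L] * wts[m - 1L] +
                             vals[m] * wts[m]) / tot
            wts[m - 1L] <- tot
            sizes[m - 1L] <- sizes[m - 1L] + sizes[m]
            m <- m - 1L
        }
    }
    rep(vals[seq_len(m)], sizes[seq_len(m)])
}

#' Fit the distance-dependent expected contact probability
#'
#' Partitions tested pairs (distances within `[L, U]`) into equal-occupancy
#' distance strata; within each stratum the expected contact probability is
#' `sum(normCount) / (N_total * nPairs)`, where `N_total` is the (rounded)
#' sum of normalized counts over the whole tested range. The stratum
#' probabilities are made monotone non-increasing in distance by weighted
#' isotonic pooling, yielding a step function of distance.
#'
#' @param contacts a [ContactSet] with balanced `normCount`
#' @param config a [significanceConfig()]
#' @return list with `breaks` (stratum distance ranges), `prob`
#'   (per-stratum probability), `nTotal`, and `fun(distance)` evaluating the
#'   step function
#' @export
fitExpected <- function(contacts, config = significanceConfig()) {
    r <- contacts@records
    r <- r[testedPairs(r, config), , drop = FALSE]
    if (!nrow(r)) stop("no contact pairs within [L, U]")
    nBins <- config$nDistanceBins
    if (nrow(r) < nBins) {
        warning("fewer pairs than distance strata; reducing strata to ",
                nrow(r))
        nBins <- nrow(r)
    }
    grp <- equalOccupancyBins(r$distance, nBins)
    nTotal <- round(sum(r$normCount))
    o <- order(r$distance)
    d <- r$distance[o]
    nc <- r$normCount[o]
    g <- grp[o]                      # non-decreasing along sorted distance
    rl <- rle(g)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    csum <- c(0, cumsum(nc))
    sums <- csum[ends + 1L] - csum[starts]
    npairs <- rl$lengths
    dmin <- d[starts]
    dmax <- d[ends]
    prob <- sums / (nTotal * npairs)
    prob <- pavaNonIncreasing(prob, npairs)
    breaks <- data.frame(dmin = dmin, dmax = dmax, prob = prob,
                         nPairs = npairs)
    fun <- function(distance) {
        idx <- findInterval(distance, breaks$dmin)
        idx[idx < 1L] <- 1L
        breaks$prob[idx]
    }
    list(breaks = breaks, prob = prob, nTotal = nTotal, fun = fun)
}

#' Call statistically significant interactions
#'
#' For each tested pair (distance within `[L, U]`), the p-value is the
#' upper-tail binomial probability of observing at least the (rounded)
#' normalized count in `N_total` trials with the distance-dependent expected
#' probability; q-values are Benjamini-Hochberg over all tested pairs, and
#' pairs with `q <= fdr` are significant.
#'
#' @param contacts a [ContactSet] with balanced `normCount`
#' @param expected result of [fitExpected()] (fitted on the fly when NULL)
#' @param config a [significanceConfig()]
#' @return the [ContactSet] with `p`/`q` filled for tested pairs (NA
#'   elsewhere); retrieve the FDR-passing subset with
#'   [significantContacts()]
#' @export
callSignificant <- function(contacts, expected = NULL,
                            config = significanceConfig()) {
    r <- contacts@records
    tested <- testedPairs(r, config)
    if (is.null(expected)) expected <- fitExpected(contacts, config)
    pexp <- expected$fun(r$distance[tested])
    obs <- pmax(round(r$normCount[tested]), 0)
    if (any(pexp == 0 & obs > 0))
        warning("expected probability 0 with non-zero observed count; p = 0")
    p <- stats::pbinom(obs - 1, size = expected$nTotal, prob = pexp,
                       lower.tail = FALSE)
    r$p <- NA_real_
    r$q <- NA_real_
    r$p[tested] <- p
    r$q[tested] <- stats::p.adjust(p, method = "BH")
    methods::new("ContactSet", records = r, resolution = contacts@resolution)
}

#' Per-bin significant-interaction frequency
#'
#' The interaction frequency of a bin is the number of significant
#' interactions associated with it: every pair increments the bin holding
#' each of its two midpoints by 1. A pair with both midpoints in the same
#' bin would increment it by 2; with `countSameBinTwice = FALSE` such pairs
#' add 1 (self-pairs cannot occur in a [ContactSet], so this only matters
#' for resolutions coarser than the pair grid).
#'
#' @param contacts a [ContactSet] of significant pairs (see
#'   [significantContacts()])
#' @param resolution output bin size in bp (defaults to the contact
#'   resolution)
#' @param countSameBinTwice count both ends of a within-bin pair
#' @return a [BinFrequencyTrack]
#' @export
binFrequency <- function(contacts, resolution = NULL,
                         countSameBinTwice = TRUE) {
    if (is.null(resolution)) resolution <- contacts@resolution
    r <- contacts@records
    b1 <- floor(r$mid1 / resolution)
    b2 <- floor(r$mid2 / resolution)
    chrom <- c(r$chrom, r$chrom)
    bin <- c(b1, b2)
    if (!countSameBinTwice) {
        dupEnd <- c(rep(FALSE, nrow(r)), b1 == b2)
        chrom <- chrom[!dupEnd]
        bin <- bin[!dupEnd]
    }
    if (!length(bin)) {
        return(methods::new("BinFrequencyTrack", resolution = resolution,
            counts = data.frame(chrom = character(0), bin = integer(0),
                                count = integer(0))))
    }
    key <- paste(chrom, bin)
    tab <- table(key)
    parts <- strsplit(names(tab), " ", fixed = TRUE)
    counts <- data.frame(
        chrom = vapply(parts, `[[`, character(1), 1),
        bin = as.integer(vapply(parts, `[[`, character(1), 2)),
        count = as.integer(tab), stringsAsFactors = FALSE)
    counts <- counts[order(counts$chrom, counts$bin), , drop = FALSE]
    rownames(counts) <- NULL
    methods::new("BinFrequencyTrack", resolution = resolution,
                 counts = counts)
}

#' Per-bin frequency from pre-called anchor intervals
#'
#' For pre-called interaction anchors (e.g. ChIA-PET PET clusters), every
#' anchor interval increments each bin it overlaps by 1.
#'
#' @param anchors GRanges of anchor intervals (pass both anchors of each
#'   pair, e.g. `c(first, second)`)
#' @param resolution bin size in bp
#' @return a [BinFrequencyTrack]
#' @export
pairsFrequency <- function(anchors, resolution = 5000) {
    if (!length(anchors)) {
        return(methods::new("BinFrequencyTrack", resolution = resolution,
            counts = data.frame(chrom = character(0), bin = integer(0),
                                count = integer(0))))
    }
    chrom <- as.character(GenomeInfoDb::seqnames(anchors))
    first <- floor((BiocGenerics::start(anchors) - 1) / resolution)
    last <- floor((BiocGenerics::end(anchors) - 1) / resolution)
    n <- last - first + 1
    key <- paste(rep(chrom, n),
                 unlist(Map(seq, first, last), use.names = FALSE))
    tab <- table(key)
    parts <- strsplit(names(tab), " ", fixed = TRUE)
    counts <- data.frame(
        chrom = vapply(parts, `[[`, character(1), 1),
        bin = as.integer(vapply(parts, `[[`, character(1), 2)),
        count = as.integer(tab), stringsAsFactors = FALSE)
    counts <- counts[order(counts$chrom, counts$bin), , drop = FALSE]
    rownames(counts) <- NULL
    methods::new("BinFrequencyTrack", resolution = resolution,
                 counts = counts)
}

#' Normalize, test and count in one call
#'
#' The standard contact workflow: ICE-balance per chromosome, fit the
#' distance-expected model, call significant pairs under BH-FDR, and reduce
#' them to per-bin interaction frequencies.
#'
#' @param contacts a [ContactSet] of raw records
#' @param seqinfo optional [GenomeInfoDb::Seqinfo]
#' @param config a [significanceConfig()]
#' @return list with `contacts` (tested ContactSet), `significant`
#'   (ContactSet), `track` (a [BinFrequencyTrack]) and `expected`
#' @export
hicSignificant <- function(contacts, seqinfo = NULL,
                           config = significanceConfig()) {
    normed <- normalizeContacts(contacts, seqinfo = seqinfo)
    expected <- fitExpected(normed, config)
    called <- callSignificant(normed, expected, config)
    sig <- significantContacts(called, fdr = config$fdr)
    track <- binFrequency(sig)
    list(contacts = called, significant = sig, track = track,
         expected = expected)
}
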