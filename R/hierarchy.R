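#' @include hic.R
NULL

#' Genome-grid bins intersecting a region
#'
#' Returns the bins of the fixed genome grid (bin `k` covers
#' `[k*resolution, (k+1)*resolution)`, 0-based) that intersect the region —
#' the same grid the Hi-C matrix is binned on, so a SE only partially
#' covering a bin still owns the full bin.
#'
#' @param region a GRanges of length 1 (or more; bins are returned per
#'   region, concatenated, with a `region` metadata column)
#' @param resolution bin size in bp (> 0)
#' @return GRanges of grid bins in coordinate order with metadata columns
#'   `region` (index into `region`) and `bin` (0-based bin index)
#' @export
seBins <- function(region, resolution = 5000) {
    if (resolution <= 0) stop("resolution must be > 0")
    outs <- lapply(seq_along(region), function(i) {
        k1 <- floor((BiocGenerics::start(region)[i] - 1) / resolution)
        k2 <- floor((BiocGenerics::end(region)[i] - 1) / resolution)
        k <- seq(k1, k2)
        GenomicRanges::GRanges(
            as.character(GenomeInfoDb::seqnames(region))[i],
            IRanges::IRanges(start = k * resolution + 1,
                             end = (k + 1) * resolution),
            region = i, bin = k)
    })
    if (!length(outs)) return(GenomicRanges::GRanges(region = integer(0),
                                                     bin = integer(0)))
    do.call(c, outs)
}

#' H-score of a bin frequency vector
#'
#' Standardizes the per-bin interaction frequencies of one SE to z-scores
#' using the population standard deviation (divide by `n`) and returns the
#' maximum z as the H-score. A constant vector (including all-zero, or a
#' single bin) has zero standard deviation and is defined to give `z = 0`
#' and `H = 0`. With population standardization the H-score is bounded by
#' `sqrt(n - 1)`, attained by a single-outlier vector.
#'
#' @param frequencies numeric vector of per-bin interaction frequencies
#'   (length >= 1)
#' @param populationSD use the population SD (divide by `n`, default); set
#'   FALSE for the sample SD (divide by `n - 1`)
#' @return list with `z` (vector) and `H` (max z)
#' @examples
#' hScore(c(2, 2, 2, 14))   # H = sqrt(3)
#' @export
hScore <- function(frequencies, populationSD = TRUE) {
    if (!length(frequencies)) stop("frequencies must be non-empty")
    f <- as.numeric(frequencies)
    n <- length(f)
    m <- mean(f)
    s <- if (populationSD) sqrt(sum((f - m)^2) / n) else stats::sd(f)
    if (is.na(s) || s == 0) {
        return(list(z = rep(0, n), H = 0))
    }
    z <- (f - m) / s
    list(z = z, H = max(z))
}

#' Hierarchy calls for a set of super-enhancers
#'
#' For every SE region: divide it into resolution-sized genome-grid bins,
#' look up the significant-interaction frequency of each bin, standardize to
#' z-scores ([hScore()]), call the SE hierarchical when the H-score strictly
#' exceeds the threshold, flag hub bins (`z > threshold`), and label
#' constituent enhancers of hierarchical SEs as "hub" when they overlap at
#' least one hub bin, "non-hub" otherwise. Enhancers of non-hierarchical SEs
#' carry no label (NA).
#'
#' @param sset a [SuperEnhancerSet]; only regions with `isSuper == TRUE` are
#'   analysed unless `onlySuper = FALSE`
#' @param track a [BinFrequencyTrack] of significant-interaction counts
#' @param threshold H-score / z-score threshold (default 1.5; 1.25 and 1.75
#'   are customary sensitivity sweeps)
#' @param resolution bin size in bp (defaults to the track resolution)
#' @param onlySuper restrict to super-enhancer regions
#' @param populationSD passed to [hScore()]
#' @return a [HierarchyCallSet]
#' @export
hierarchyCalls <- function(sset, track, threshold = 1.5, resolution = NULL,
                           onlySuper = TRUE, populationSD = TRUE) {
    if (is.null(resolution)) resolution <- track@resolution
    reg <- sset@regions
    con <- sset@constituents
    if (onlySuper) {
        keep <- !is.na(S4Vectors::mcols(reg)$isSuper) &
            S4Vectors::mcols(reg)$isSuper
        reg <- reg[keep]
        con <- con[keep]
    }
    use <- methods::new("SuperEnhancerSet", regions = reg,
                        constituents = con)
    nSE <- length(reg)
    sumRows <- vector("list", nSE)
    binRows <- vector("list", nSE)
    labels <- rep(NA_character_, sum(lengths(con)))
    offset <- 0L
    for (i in seq_len(nSE)) {
        bins <- seBins(reg[i], resolution)
        freq <- binFrequencies(track,
            as.character(GenomeInfoDb::seqnames(reg))[i],
            S4Vectors::mcols(bins)$bin)
        hz <- hScore(freq, populationSD = populationSD)
        isHier <- hz$H > threshold
        isHub <- hz$z > threshold
        sumRows[[i]] <- data.frame(seIndex = i, nBins = length(bins),
                                   hScore = hz$H, isHierarchical = isHier)
        binRows[[i]] <- data.frame(
            seIndex = i,
            chrom = as.character(GenomeInfoDb::seqnames(bins)),
            start = BiocGenerics::start(bins),
            end = BiocGenerics::end(bins),
            frequency = freq, z = hz$z, isHub = isHier & isHub)
        k <- lengths(con)[i]
        if (isHier) {
            hubBins <- bins[isHub]
            lab <- ifelse(overlapAny(con[[i]], hubBins), "hub", "non-hub")
            labels[offset + seq_len(k)] <- lab
        }
        offset <- offset + k
    }
    methods::new("HierarchyCallSet", se = use,
                 summary = if (nSE) do.call(rbind, sumRows) else
                     data.frame(seIndex = integer(0), nBins = integer(0),
                                hScore = numeric(0),
                                isHierarchical = logical(0)),
                 bins = if (nSE) do.call(rbind, binRows) else
                     data.frame(seIndex = integer(0), chrom = character(0),
                                start = numeric(0), end = numeric(0),
                                frequency = integer(0), z = numeric(0),
                                isHub = logical(0)),
                 labels = labels, threshold = threshold,
                 resolution = resolution)
}

#' Drop significant pairs of a given interaction subtype
#'
#' Classifies each significant pair by what its two anchor bins overlap
#' (enhancer, CTCF peak, promoter; a bin may carry several labels) and drops
#' pairs whose unordered label pair matches the excluded subtype. Used for
#' leave-one-subtype-out reanalysis of hierarchy calls.
#'
#' @param contacts a [ContactSet] of significant pairs
#' @param exclude one of `"enhancer-CTCF"`, `"enhancer-enhancer"`,
#'   `"enhancer-promoter"`, `"none"`
#' @param enhancers,ctcf,promoters GRanges annotation sets
#' @return the filtered [ContactSet]
#' @export
filterInteractionsByType <- function(contacts,
                                     exclude = c("none", "enhancer-CTCF",
                                                 "enhancer-enhancer",
                                                 "enhancer-promoter"),
                                     enhancers = GenomicRanges::GRanges(),
                                     ctcf = GenomicRanges::GRanges(),
                                     promoters = GenomicRanges::GRanges()) {
    exclude <- match.arg(exclude)
    if (exclude == "none") return(contacts)
    r <- contacts@records
    res <- contacts@resolution
    anchorGR <- function(mid) {
        s0 <- mid - res / 2
        GenomicRanges::GRanges(r$chrom,
            IRanges::IRanges(start = s0 + 1, end = s0 + res))
    }
    a1 <- anchorGR(r$mid1)
    a2 <- anchorGR(r$mid2)
    lab <- strsplit(exclude, "-", fixed = TRUE)[[1]]
    annot <- list(enhancer = enhancers, CTCF = ctcf, promoter = promoters)
    hasLab <- function(anchors, what) overlapAny(anchors, annot[[what]])
    drop <- (hasLab(a1, lab[1]) & hasLab(a2, lab[2])) |
            (hasLab(a1, lab[2]) & hasLab(a2, lab[1]))
    methods::new("ContactSet", records = r[!drop, , drop = FALSE],
                 resolution = res)
}

#' Write hierarchy-call outputs
#'
#' Writes `hierarchy_calls.tsv` (one row per SE), `hub_enhancers.bed`,
#' `nonhub_enhancers.bed` and `se_bins.tsv` (per-bin frequency and z).
#'
#' @param calls a [HierarchyCallSet]
#' @param dir output directory
#' @return invisibly, the file paths
#' @export
writeHierarchyCalls <- function(calls, dir) {
    reg <- calls@se@regions
    s <- calls@summary
    bed <- grangesToBed0(reg)
    header <- "# se_id\tchrom\tstart\tend\tn_bins\th_score\tclass"
    lines <- sprintf("SE_%d\t%s\t%s\t%s\t%d\t%s\t%s",
        s$seIndex, bed$chrom, fmtNum(bed$start), fmtNum(bed$end),
        s$nBins, fmtNum(s$hScore, 6),
        ifelse(s$isHierarchical, "hierarchical", "non-hierarchical"))
    p1 <- file.path(dir, "hierarchy_calls.tsv")
    writeLines(c(header, lines), p1)
    p2 <- file.path(dir, "hub_enhancers.bed")
    writeBed(hubEnhancers(calls), p2)
    p3 <- file.path(dir, "nonhub_enhancers.bed")
    writeBed(nonhubEnhancers(calls), p3)
    b <- calls@bins
    header <- "# se_id\tchrom\tstart\tend\tfrequency\tz"
    lines <- sprintf("SE_%d\t%s\t%s\t%s\t%s\t%s", b$seIndex, b$chrom,
                     fmtNum(b$start - 1), fmtNum(b$end),
                     fmtNum(b$frequency), fmtNum(b$z, 6))
    p4 <- file.path(dir, "se_bins.tsv")
    writeLines(c(header, lines), p4)
    invisible(c(p1, p2, p3, p4))
}
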