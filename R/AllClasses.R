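#' @include SEhierarchy-package.R
NULL

#' SuperEnhancerSet: stitched enhancer regions with constituents
#'
#' Container for stitched enhancer regions produced by [stitchEnhancers()].
#' Each region carries its constituent enhancer peaks, the aggregate H3K27ac
#' signal (sum of constituent scores), its signal rank (1 = strongest) and the
#' super-enhancer flag set by [seCutoff()].
#'
#' @slot regions a [GenomicRanges::GRanges] of stitched spans with metadata
#'   columns `totalSignal` (numeric), `rank` (integer, NA until ranked) and
#'   `isSuper` (logical, NA until the cutoff is applied).
#' @slot constituents a [GenomicRanges::GRangesList] parallel to `regions`;
#'   element `i` holds the member enhancer peaks of region `i`, each with a
#'   `score` metadata column.
#'
#' @seealso [stitchEnhancers()], [rankSE()], [seCutoff()]
#' @export
setClass("SuperEnhancerSet",
    representation(regions = "GRanges", constituents = "GRangesList"))

setValidity("SuperEnhancerSet", function(object) {
    reg <- object@regions
    con <- object@constituents
    if (length(reg) != length(con))
        return("regions and constituents must have equal length")
    need <- c("totalSignal", "rank", "isSuper")
    if (!all(need %in% names(S4Vectors::mcols(reg))))
        return(paste("regions must carry metadata columns:",
                     paste(need, collapse = ", ")))
    if (length(reg)) {
        if (any(lengths(con) == 0L))
            return("empty constituent set")
        flat <- unlist(con, use.names = FALSE)
        grp <- rep(seq_along(con), lengths(con))
        if (!all(as.character(GenomeInfoDb::seqnames(flat)) ==
                 as.character(GenomeInfoDb::seqnames(reg))[grp]) ||
            any(BiocGenerics::start(flat) <
                BiocGenerics::start(reg)[grp]) ||
            any(BiocGenerics::end(flat) > BiocGenerics::end(reg)[grp]))
            return("constituents not within their region")
        ord <- order(grp, BiocGenerics::start(flat))
        sameGrp <- diff(grp[ord]) == 0L
        if (any(sameGrp &
                BiocGenerics::start(flat)[ord][-1] <=
                BiocGenerics::end(flat)[ord][-length(ord)]))
            return("constituents overlap within a region")
        score <- S4Vectors::mcols(flat)$score
        if (!is.null(score) && !anyNA(score)) {
            ss <- as.numeric(rowsum(as.numeric(score), grp,
                                    reorder = FALSE))
            ts <- S4Vectors::mcols(reg)$totalSignal
            bad <- is.finite(ts) & abs(ts - ss) > 1e-9 * pmax(1, abs(ss))
            if (any(bad))
                return("totalSignal does not match the sum of scores")
        }
    }
    rk <- S4Vectors::mcols(reg)$rank
    if (!all(is.na(rk)) &&
        !identical(sort(as.integer(rk)), seq_along(reg)))
        return("ranks are not a permutation of 1..N")
    TRUE
})

#' ContactSet: intra-chromosomal contact records
#'
#' Holds one row per intra-chromosomal bin pair: the two bin midpoints (on the
#' genome grid of the stated resolution, so `mid %% resolution ==
#' resolution/2`), the raw and (after balancing) normalized counts, the
#' genomic distance, and, after [callSignificant()], the binomial p-value and
#' its Benjamini-Hochberg adjustment.
#'
#' @slot records a data.frame with columns `chrom`, `mid1`, `mid2`,
#'   `rawCount`, `normCount`, `distance`, `p`, `q` (`p`/`q` are NA for pairs
#'   outside the tested distance range).
#' @slot resolution bin size in bp.
#'
#' @seealso [readContacts()], [callSignificant()], [significantContacts()]
#' @export
setClass("ContactSet",
    representation(records = "data.frame", resolution = "numeric"))

setValidity("ContactSet", function(object) {
    r <- object@records
    res <- object@resolution
    need <- c("chrom", "mid1", "mid2", "rawCount", "normCount",
              "distance", "p", "q")
    if (!all(need %in% names(r)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (length(res) != 1L || res <= 0)
        return("resolution must be a single positive number")
    if (nrow(r)) {
        if (any(r$mid1 >= r$mid2))
            return("mid1 must be < mid2 (off-diagonal, intra-chromosomal)")
        if (any((r$mid1 - res / 2) %% res != 0) ||
            any((r$mid2 - res / 2) %% res != 0))
            return("midpoints not aligned to the resolution grid")
        if (any(r$distance != r$mid2 - r$mid1))
            return("distance must equal mid2 - mid1")
        if (any(r$rawCount < 0) || any(r$normCount < 0))
            return("counts must be non-negative")
        ok <- !is.na(r$p)
        if (any(r$p[ok] < 0 | r$p[ok] > 1))
            return("p-values outside [0, 1]")
        ok <- !is.na(r$p) & !is.na(r$q)
        if (any(r$q[ok] < r$p[ok] - 1e-12))
            return("q must be >= p")
    }
    TRUE
})

#' BinFrequencyTrack: significant-interaction counts per genomic bin
#'
#' Sparse per-bin counts of significant chromatin interactions at a fixed
#' resolution. Bin `k` on a chromosome covers the half-open interval
#' `[k*resolution, (k+1)*resolution)` in 0-based coordinates; bins absent from
#' the table have frequency 0.
#'
#' @slot resolution bin size in bp (default pipeline value: 5000).
#' @slot counts a data.frame with columns `chrom`, `bin` (0-based bin index)
#'   and `count`.
#'
#' @seealso [binFrequency()], [pairsFrequency()], [binFrequencies()]
#' @export
setClass("BinFrequencyTrack",
    representation(resolution = "numeric", counts = "data.frame"))

setValidity("BinFrequencyTrack", function(object) {
    cts <- object@counts
    if (!all(c("chrom", "bin", "count") %in% names(cts)))
        return("counts must have columns chrom, bin, count")
    if (nrow(cts) && (any(cts$count < 0) || any(cts$bin < 0)))
        return("bin indices and counts must be non-negative")
    if (nrow(cts) && anyDuplicated(paste(cts$chrom, cts$bin)))
        return("duplicated (chrom, bin) entries")
    TRUE
})

#' HierarchyCallSet: per-SE H-scores and hub-enhancer labels
#'
#' Result of [hierarchyCalls()]: for every stitched super-enhancer, its 5 kb
#' bins with interaction frequencies and z-scores, the H-score (maximum bin
#' z-score), the hierarchical/non-hierarchical call, and hub/non-hub labels
#' for constituent enhancers of hierarchical SEs.
#'
#' @slot se the [SuperEnhancerSet] the calls refer to (SE regions only).
#' @slot summary data.frame, one row per SE: `seIndex`, `nBins`, `hScore`,
#'   `isHierarchical`.
#' @slot bins data.frame, one row per SE bin: `seIndex`, `chrom`, `start`,
#'   `end` (1-based closed, as in GRanges), `frequency`, `z`, `isHub`.
#' @slot labels a character vector parallel to the unlisted constituents:
#'   "hub" or "non-hub" within hierarchical SEs, NA elsewhere.
#' @slot threshold the H-score / z-score threshold used (default 1.5).
#' @slot resolution bin size in bp.
#'
#' @seealso [hierarchyCalls()], [hubEnhancers()], [isHierarchical()]
#' @export
setClass("HierarchyCallSet",
    representation(se = "SuperEnhancerSet", summary = "data.frame",
                   bins = "data.frame", labels = "character",
                   threshold = "numeric", resolution = "numeric"))

setValidity("HierarchyCallSet", function(object) {
    s <- object@summary
    b <- object@bins
    if (!all(c("seIndex", "nBins", "hScore", "isHierarchical") %in% names(s)))
        return("summary lacks required columns")
    if (!all(c("seIndex", "chrom", "start", "end", "frequency", "z",
               "isHub") %in% names(b)))
        return("bins lacks required columns")
    if (nrow(s) != length(object@se@regions))
        return("summary rows must match number of SEs")
    hs <- s$hScore
    if (any(s$isHierarchical != (hs > object@threshold)))
        return("isHierarchical inconsistent with hScore and threshold")
    TRUE
})

#' EnrichmentResult: variant fold-enrichment for one enhancer group
#'
#' The 2x2 counts behind a fold-enrichment score `(m/n)/(M/N)`: `m` of `n`
#' group loci overlap a variant, against `M` of `N` background loci, with a
#' two-sided Fisher exact p-value.
#'
#' @slot groupName label of the enhancer group.
#' @slot m within-group loci overlapping a variant.
#' @slot n within-group locus count.
#' @slot M background loci overlapping a variant.
#' @slot N background locus count.
#' @slot score fold enrichment `(m/n)/(M/N)`.
#' @slot fisherP two-sided Fisher exact p for the table `[[m, n-m], [M, N-M]]`.
#'
#' @seealso [enrichmentScore()]
#' @export
setClass("EnrichmentResult",
    representation(groupName = "character", m = "numeric", n = "numeric",
                   M = "numeric", N = "numeric", score = "numeric",
                   fisherP = "numeric"))

setValidity("EnrichmentResult", function(object) {
    if (object@m < 0 || object@M < 0) return("need m >= 0 and M >= 0")
    if (object@n <= 0 || object@N <= 0) return("need n > 0 and N > 0")
    if (!is.na(object@fisherP) &&
        (object@fisherP < 0 || object@fisherP > 1))
        return("fisherP outside [0, 1]")
    TRUE
})

#' SimulationConfig: parameters of the synthetic fixture generator
#'
#' See [simConfig()] for field semantics and defaults.
#'
#' @slot params named list of generator parameters (validated by
#'   [simConfig()]).
#' @export
setClass("SimulationConfig", representation(params = "list"))

#' @describeIn SuperEnhancerSet compact display
#' @param object a SuperEnhancerSet
#' @export
setMethod("show", "SuperEnhancerSet", function(object) {
    n <- length(object@regions)
    ns <- S4Vectors::mcols(object@regions)$isSuper
    cat(sprintf("SuperEnhancerSet with %d stitched region(s)\n", n))
    if (n && !all(is.na(ns)))
        cat(sprintf("  super-enhancers: %d; regular: %d\n",
                    sum(ns, na.rm = TRUE), sum(!ns, na.rm = TRUE)))
    cat(sprintf("  constituents: %d peak(s)\n",
                sum(lengths(object@constituents))))
})

#' @describeIn ContactSet compact display
#' @param object a ContactSet
#' @export
setMethod("show", "ContactSet", function(object) {
    r <- object@records
    cat(sprintf("ContactSet: %d intra-chromosomal pair(s) at %d bp resolution\n",
                nrow(r), as.integer(object@resolution)))
    tested <- sum(!is.na(r$p))
    if (tested)
        cat(sprintf("  tested: %d; significant (q <= 0.01): %d\n",
                    tested, sum(r$q <= 0.01, na.rm = TRUE)))
})

#' @describeIn BinFrequencyTrack compact display
#' @param object a BinFrequencyTrack
#' @export
setMethod("show", "BinFrequencyTrack", function(object) {
    cat(sprintf(
        "BinFrequencyTrack: %d non-zero bin(s) at %d bp; total count %d\n",
        nrow(object@counts), as.integer(object@resolution),
        as.integer(sum(object@counts$count))))
})

#' @describeIn HierarchyCallSet compact display
#' @param object a HierarchyCallSet
#' @export
setMethod("show", "HierarchyCallSet", function(object) {
    s <- object@summary
    cat(sprintf("HierarchyCallSet: %d SE(s), threshold %.3g\n",
                nrow(s), object@threshold))
    cat(sprintf("  hierarchical: %d; non-hierarchical: %d\n",
                sum(s$isHierarchical), sum(!s$isHierarchical)))
    lab <- object@labels
    cat(sprintf("  hub enhancers: %d; non-hub: %d\n",
                sum(lab == "hub", na.rm = TRUE),
                sum(lab == "non-hub", na.rm = TRUE)))
})

#' @describeIn EnrichmentResult compact display
#' @param object an EnrichmentResult
#' @export
setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult [%s]: m/n = %d/%d vs M/N = %d/%d; score %.4g; Fisher p %.3g\n",
        object@groupName, as.integer(object@m), as.integer(object@n),
        as.integer(object@M), as.integer(object@N), object@score,
        object@fisherP))
})

#' @describeIn SimulationConfig compact display
#' @param object a SimulationConfig
#' @export
setMethod("show", "SimulationConfig", function(object) {
    p <- object@params
    cat(sprintf(
        "SimulationConfig: %d chrom x %g bp, %d SE / %d RE, lambda = %g, seed %d\n",
        p$nChrom, p$chromLength, p$nSE, p$nRE, p$hubFold, p$seed))
})
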