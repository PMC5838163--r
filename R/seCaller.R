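#' @include intervals.R
NULL

#' Stitch enhancers into candidate super-enhancer regions
#'
#' Merges neighbouring enhancers on the same chromosome whenever the genomic
#' gap between them (end of one to start of the next) is at most `gap`,
#' transitively; each stitched region spans the envelope of its members. The
#' default gap of 12,500 bp is the stitching distance of the ROSE
#' (Rank Ordering of Super-Enhancers) algorithm.
#'
#' @param enhancers GRanges of filtered enhancer peaks with a `score`
#'   metadata column (aggregate signal per peak)
#' @param gap maximum stitching distance in bp (>= 0)
#' @return a [SuperEnhancerSet] with `totalSignal` filled and `rank`/
#'   `isSuper` still NA
#' @seealso [rankSE()], [seCutoff()], [callSuperEnhancers()]
#' @export
stitchEnhancers <- function(enhancers, gap = 12500) {
    if (gap < 0) stop("gap must be >= 0")
    if (!length(enhancers))
        return(methods::new("SuperEnhancerSet",
            regions = GenomicRanges::GRanges(
                totalSignal = numeric(0), rank = integer(0),
                isSuper = logical(0)),
            constituents = GenomicRanges::GRangesList()))
    ord <- order(as.character(GenomeInfoDb::seqnames(enhancers)),
                 BiocGenerics::start(enhancers),
                 BiocGenerics::end(enhancers))
    e <- enhancers[ord]
    chrom <- as.character(GenomeInfoDb::seqnames(e))
    s <- BiocGenerics::start(e)
    en <- BiocGenerics::end(e)
    grp <- integer(length(e))
    grp[1] <- 1L
    curEnd <- en[1]
    for (i in seq_along(e)[-1]) {
        # 0-based gap between intervals = (start-1) - prevEnd
        if (chrom[i] == chrom[i - 1] && (s[i] - 1 - curEnd) <= gap) {
            grp[i] <- grp[i - 1]
            curEnd <- max(curEnd, en[i])
        } else {
            grp[i] <- grp[i - 1] + 1L
            curEnd <- en[i]
        }
    }
    con <- unname(S4Vectors::split(e, grp))   # CompressedGRangesList
    # per-group region stats from the sorted vectors (grp is
    # non-decreasing, enhancers sorted by start within it)
    rl <- rle(grp)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    regChrom <- chrom[starts]
    regStart <- s[starts]
    regEnd <- vapply(seq_along(starts), function(k)
        max(en[starts[k]:ends[k]]), numeric(1))
    score <- S4Vectors::mcols(e)$score
    ts <- as.numeric(rowsum(as.numeric(score), grp, reorder = FALSE))
    reg <- GenomicRanges::GRanges(regChrom,
        IRanges::IRanges(regStart, regEnd),
        totalSignal = ts,
        rank = NA_integer_,
        isSuper = NA)
    methods::new("SuperEnhancerSet", regions = reg,
                 constituents = unname(con))
}

#' Rank stitched regions by aggregate signal
#'
#' Recomputes `totalSignal` as the sum of constituent scores and assigns
#' descending ranks (1 = strongest); ties are broken by (chromosome, start)
#' ascending so ranking is deterministic.
#'
#' @param sset a [SuperEnhancerSet]
#' @return the same set with `rank` filled
#' @export
rankSE <- function(sset) {
    reg <- sset@regions
    con <- sset@constituents
    flat <- unlist(con, use.names = FALSE)
    score <- S4Vectors::mcols(flat)$score
    if (is.null(score) || anyNA(score) || length(score) != length(flat))
        stop("every constituent must carry a score")
    ts <- as.numeric(rowsum(as.numeric(score),
                            rep(seq_along(con), lengths(con)),
                            reorder = FALSE))
    S4Vectors::mcols(reg)$totalSignal <- ts
    ord <- order(-ts, as.character(GenomeInfoDb::seqnames(reg)),
                 BiocGenerics::start(reg))
    rk <- integer(length(ts))
    rk[ord] <- seq_along(ts)
    S4Vectors::mcols(reg)$rank <- rk
    methods::new("SuperEnhancerSet", regions = reg, constituents = con)
}

# Geometric cutoff on the rank-vs-signal curve: rescale both axes to [0, 1]
# with signals sorted ascending and return the signal value at the first
# discrete-difference slope > 1. Returns -Inf when every region should pass
# and +Inf when the curve never steepens past slope 1 (e.g. an exact line).
roseCutoffValue <- function(signals) {
    n <- length(signals)
    y <- sort(signals)
    if (diff(range(y)) == 0) return(Inf)   # flat curve: nothing is super
    x01 <- (seq_len(n) - 1) / (n - 1)
    y01 <- (y - y[1]) / (y[n] - y[1])
    slope <- diff(y01) / diff(x01)
    idx <- which(slope > 1)
    if (!length(idx)) return(Inf)
    y[idx[1]]
}

#' Super-enhancer cutoff on the ranked signal curve
#'
#' ROSE-style geometric cutoff: signals are sorted ascending and both axes
#' rescaled to `[0, 1]`; scanning the discrete first differences, the cutoff
#' is the signal at the first point where the curve's slope exceeds 1.
#' Regions with `totalSignal` strictly greater than the cutoff are flagged
#' super-enhancers; because the flag depends only on signal, the flagged set
#' is always a prefix of the descending ranking. Degenerate curves that never
#' reach slope 1 (e.g. perfectly linear or constant signals) yield no
#' super-enhancers.
#'
#' @param sset a ranked [SuperEnhancerSet] (see [rankSE()])
#' @return the same set with `isSuper` filled
#' @export
seCutoff <- function(sset) {
    reg <- sset@regions
    ts <- S4Vectors::mcols(reg)$totalSignal
    if (length(ts) < 3) {
        warning("fewer than 3 regions; no super-enhancers called")
        S4Vectors::mcols(reg)$isSuper <- rep(FALSE, length(ts))
    } else {
        cut <- roseCutoffValue(ts)
        S4Vectors::mcols(reg)$isSuper <- ts > cut
    }
    methods::new("SuperEnhancerSet", regions = reg,
                 constituents = sset@constituents)
}

#' Call super-enhancers from peaks
#'
#' End-to-end SE calling: filter peaks against blacklist and promoter
#' windows, stitch with the ROSE gap, rank by aggregate H3K27ac signal and
#' apply the geometric cutoff.
#'
#' @param peaks GRanges of H3K27ac peaks with `score`
#' @param blacklist,promoters GRanges of excluded regions (defaults: empty)
#' @param gap stitching distance in bp (default 12,500)
#' @return a [SuperEnhancerSet] with ranks and `isSuper` set
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 2001, 50001), width = 1000),
#'     score = c(5, 7, 100))
#' callSuperEnhancers(gr)
#' @export
callSuperEnhancers <- function(peaks,
                               blacklist = GenomicRanges::GRanges(),
                               promoters = GenomicRanges::GRanges(),
                               gap = 12500) {
    enh <- filterEnhancerCandidates(peaks, blacklist, promoters)
    seCutoff(rankSE(stitchEnhancers(enh, gap = gap)))
}

#' Write a SuperEnhancerSet as BED files
#'
#' Writes `superenhancers.bed` (stitched spans, name `SE_<rank>` or
#' `RE_<rank>`, total signal as score) and `constituents.bed` (member peaks,
#' named `<region name>_<i>`).
#'
#' @param sset a ranked, cutoff [SuperEnhancerSet]
#' @param dir output directory
#' @return invisibly, the two file paths
#' @export
writeSuperEnhancers <- function(sset, dir) {
    reg <- sset@regions
    mc <- S4Vectors::mcols(reg)
    label <- ifelse(is.na(mc$isSuper) | !mc$isSuper, "RE", "SE")
    nm <- sprintf("%s_%d", label, mc$rank)
    bed <- grangesToBed0(reg)
    ord <- order(mc$rank)
    lines <- sprintf("%s\t%s\t%s\t%s\t%s\t.", bed$chrom[ord],
                     fmtNum(bed$start[ord]), fmtNum(bed$end[ord]), nm[ord],
                     fmtNum(mc$totalSignal[ord], 6))
    p1 <- file.path(dir, "superenhancers.bed")
    writeLines(lines, p1)
    conLines <- character(0)
    for (i in order(mc$rank)) {
        g <- sset@constituents[[i]]
        b <- grangesToBed0(g)
        conLines <- c(conLines, sprintf("%s\t%s\t%s\t%s\t%s\t.",
            b$chrom, fmtNum(b$start), fmtNum(b$end),
            sprintf("%s_%d", nm[i], seq_along(g)),
            fmtNum(S4Vectors::mcols(g)$score, 6)))
    }
    p2 <- file.path(dir, "constituents.bed")
    writeLines(conLines, p2)
    invisible(c(p1, p2))
}
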