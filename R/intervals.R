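#' @include io.R
NULL

#' Does each query interval overlap any subject interval?
#'
#' Strand-ignored, same-chromosome overlap of at least 1 bp. Half-open BED
#' intervals that merely touch (e.g. `[0,100)` and `[100,200)`) do not
#' overlap.
#'
#' @param query,subjects GRanges
#' @return logical vector parallel to `query`
#' @export
overlapAny <- function(query, subjects) {
    IRanges::overlapsAny(query, subjects, ignore.strand = TRUE)
}

#' Filter enhancer candidates against blacklist and promoter regions
#'
#' Removes peaks that overlap ENCODE-style blacklisted regions or promoter
#' windows (TSS +/- 2 kb, see [promotersFromTSS()]); the survivors are the
#' enhancers used for super-enhancer calling. Input order is preserved.
#'
#' @param peaks GRanges of H3K27ac peaks
#' @param blacklist GRanges of excluded regions (may be empty)
#' @param promoters GRanges of promoter windows (may be empty)
#' @return the retained subset of `peaks`
#' @export
filterEnhancerCandidates <- function(peaks,
                                     blacklist = GenomicRanges::GRanges(),
                                     promoters = GenomicRanges::GRanges()) {
    drop <- overlapAny(peaks, blacklist) | overlapAny(peaks, promoters)
    peaks[!drop]
}

#' Promoter windows around transcription start sites
#'
#' Expands 1-bp TSS intervals to `[tss - flank, tss + flank)` windows
#' (0-based half-open; 4 kb wide for the default-style `flank = 2000`),
#' clipped at chromosome ends when lengths are known.
#'
#' @param tss GRanges of 1-bp TSS positions
#' @param flank half-width in bp (> 0)
#' @return GRanges of promoter windows, parallel to `tss`
#' @export
promotersFromTSS <- function(tss, flank = 2000) {
    if (length(flank) != 1L || !is.finite(flank) || flank <= 0)
        stop("flank must be a single positive number")
    if (length(tss) && any(BiocGenerics::width(tss) != 1L))
        stop("TSS must be 1-bp intervals")
    pos0 <- BiocGenerics::start(tss) - 1L   # 0-based TSS coordinate
    start0 <- pmax(pos0 - flank, 0)
    end0 <- pos0 + flank
    sl <- GenomeInfoDb::seqlengths(tss)
    if (length(sl) && !all(is.na(sl))) {
        lens <- sl[as.character(GenomeInfoDb::seqnames(tss))]
        end0 <- ifelse(is.na(lens), end0, pmin(end0, lens))
    }
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tss),
        IRanges::IRanges(start = start0 + 1, end = end0),
        seqinfo = GenomeInfoDb::seqinfo(tss))
    S4Vectors::mcols(out) <- S4Vectors::mcols(tss)
    out
}

#' Randomly relocate intervals over a genome
#'
#' Places each interval uniformly at random over all positions where it fits,
#' choosing the chromosome with probability proportional to its number of
#' eligible start positions. Widths are preserved exactly. Optionally rejects
#' placements overlapping an exclusion set (up to `maxTries` draws per
#' interval). Used to build the shuffled regular-enhancer background for
#' fold-enrichment analysis.
#'
#' @param intervals GRanges to relocate
#' @param genome a [GenomeInfoDb::Seqinfo] with chromosome lengths
#' @param seed integer seed; the result is a pure function of
#'   (intervals, genome, seed, excluded)
#' @param excluded optional GRanges the output must not overlap
#' @param maxTries rejection-sampling cap per interval
#' @return GRanges of relocated intervals (same widths, arbitrary positions)
#' @export
shuffleIntervals <- function(intervals, genome, seed, excluded = NULL,
                             maxTries = 1000) {
    lens <- GenomeInfoDb::seqlengths(genome)
    if (!length(lens) || any(is.na(lens)))
        stop("genome must provide chromosome lengths")
    widths <- BiocGenerics::width(intervals)
    if (length(widths) && max(widths) > max(lens))
        stop("an interval is longer than every chromosome")
    withSeed(seed, {
        chromOut <- character(length(intervals))
        startOut <- numeric(length(intervals))
        for (i in seq_along(intervals)) {
            w <- widths[i]
            elig <- pmax(lens - w + 1, 0)   # eligible start positions
            if (sum(elig) == 0)
                stop("interval does not fit on any chromosome")
            placed <- FALSE
            for (try in seq_len(maxTries)) {
                chrom <- sample(names(lens), 1, prob = elig / sum(elig))
                start1 <- sample.int(elig[[chrom]], 1)
                ok <- if (is.null(excluded) || !length(excluded)) {
                    TRUE
                } else {
                    cand <- GenomicRanges::GRanges(chrom,
                        IRanges::IRanges(start1, width = w))
                    # no-common-seqlevels warnings just mean "no overlap"
                    !any(suppressWarnings(overlapAny(cand, excluded)))
                }
                if (ok) {
                    chromOut[i] <- chrom
                    startOut[i] <- start1
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop("could not place interval ", i, " after ", maxTries,
                     " tries against the exclusion set")
        }
        out <- GenomicRanges::GRanges(chromOut,
            IRanges::IRanges(startOut, width = widths), seqinfo = genome)
        S4Vectors::mcols(out) <- S4Vectors::mcols(intervals)
        out
    })
}

#' Derive TAD boundary windows from TAD intervals
#'
#' When only TAD spans are available, boundaries are taken as windows of
#' +/- `resolution/2` around each TAD edge (so one bin wide at the Hi-C
#' resolution), deduplicated.
#'
#' @param tads GRanges of TADs
#' @param resolution Hi-C bin size in bp
#' @return GRanges of boundary windows
#' @export
tadBoundaries <- function(tads, resolution = 5000) {
    half <- resolution / 2
    edge0 <- c(BiocGenerics::start(tads) - 1L, BiocGenerics::end(tads))
    chrom <- rep(as.character(GenomeInfoDb::seqnames(tads)), 2)
    start0 <- pmax(edge0 - half, 0)
    end0 <- edge0 + half
    df <- unique(data.frame(chrom = chrom, start0 = start0, end0 = end0))
    df <- df[order(df$chrom, df$start0), , drop = FALSE]
    bed0ToGRanges(df$chrom, df$start0, df$end0)
}
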