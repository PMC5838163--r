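#' @include intervals.R
NULL

#' Variant fold-enrichment for an enhancer group
#'
#' Fold enrichment relative to a genome background: `(m/n) / (M/N)`, where
#' `m` of the `n` group loci overlap at least one variant and `M` of the `N`
#' background loci do (the background is typically a size-matched shuffle of
#' the regular enhancers, see [shuffleIntervals()]). Significance is the
#' two-sided Fisher exact p-value of the table `[[m, n-m], [M, N-M]]`.
#' With `countMode = "variants"`, `m`/`M` instead count variants overlapping
#' the group/background (one variant may hit several loci).
#'
#' @param group GRanges of group loci (e.g. hub enhancers)
#' @param variants GRanges of variant positions (GWAS SNPs, eQTLs, ...)
#' @param background GRanges of background loci
#' @param groupName label carried into the result
#' @param countMode `"loci"` (default) counts loci with >= 1 variant;
#'   `"variants"` counts variant occurrences
#' @return an [EnrichmentResult]
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), width = 50))
#' v <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 10))
#' b <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 301, 601, 901), width = 50))
#' enrichmentScore(g, v, b)
#' @export
enrichmentScore <- function(group, variants, background,
                            groupName = "group",
                            countMode = c("loci", "variants")) {
    countMode <- match.arg(countMode)
    n <- length(group)
    N <- length(background)
    if (countMode == "loci") {
        m <- sum(overlapAny(group, variants))
        M <- sum(overlapAny(background, variants))
    } else {
        m <- sum(overlapAny(variants, group))
        M <- sum(overlapAny(variants, background))
    }
    if (n == 0 || M == 0)
        stop("undefined enrichment score: need n > 0 and M > 0")
    score <- (m / n) / (M / N)
    tab <- matrix(c(m, n - m, M, N - M), nrow = 2, byrow = TRUE)
    fisherP <- if (all(tab >= 0)) {
        # fisher.test can exceed 1 by a rounding hair; clamp to [0, 1]
        min(max(stats::fisher.test(tab)$p.value, 0), 1)
    } else {
        # in per-variant mode counts are not bounded by locus counts and
        # the 2x2 table can be ill-formed
        NA_real_
    }
    methods::new("EnrichmentResult", groupName = groupName,
                 m = as.numeric(m), n = as.numeric(n), M = as.numeric(M),
                 N = as.numeric(N), score = score, fisherP = fisherP)
}

#' Classify CTCF peaks by regulatory context
#'
#' Partitions CTCF peaks into non-overlapping context classes: `hub`
#' (overlaps hub enhancers but no TAD boundary), `TAD-boundary` (overlaps
#' boundaries but no hub enhancer), `excluded` (overlaps both — removed from
#' downstream comparisons), `non-hub` (overlaps non-hub enhancers and
#' neither of the above), `other` (none of the sets).
#'
#' @param ctcf GRanges of CTCF peaks
#' @param hub,nonhub,boundaries GRanges annotation sets
#' @return `ctcf` with a `context` factor metadata column
#' @export
ctcfContext <- function(ctcf, hub, nonhub, boundaries) {
    onHub <- overlapAny(ctcf, hub)
    onBound <- overlapAny(ctcf, boundaries)
    onNonhub <- overlapAny(ctcf, nonhub)
    context <- rep("other", length(ctcf))
    context[onNonhub] <- "non-hub"
    context[onHub & !onBound] <- "hub"
    context[onBound & !onHub] <- "TAD-boundary"
    context[onHub & onBound] <- "excluded"
    out <- ctcf
    S4Vectors::mcols(out)$context <- factor(context,
        levels = c("hub", "non-hub", "TAD-boundary", "excluded", "other"))
    out
}

#' Cell-type consensus score of peaks
#'
#' Percentage of cell types in which each peak is detected (any overlap with
#' that cell type's peak set).
#'
#' @param peaks GRanges of query peaks
#' @param peaksetsByCellType named list of GRanges, one per cell type
#' @return numeric vector of percentages parallel to `peaks`
#' @export
consensusScore <- function(peaks, peaksetsByCellType) {
    if (!length(peaksetsByCellType)) stop("need at least one cell-type set")
    hits <- vapply(peaksetsByCellType, function(set) overlapAny(peaks, set),
                   logical(length(peaks)))
    if (length(peaks) == 1L) hits <- matrix(hits, nrow = 1)
    100 * rowSums(hits) / length(peaksetsByCellType)
}

# Column-normalize a count/frequency PWM with a pseudocount.
normalizePWM <- function(pwm, pseudocount = 1e-3) {
    if (is.null(rownames(pwm)))
        rownames(pwm) <- c("A", "C", "G", "T")
    pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
    pwm <- pwm + pseudocount
    sweep(pwm, 2, colSums(pwm), "/")
}

#' Maximum PWM motif match in a sequence
#'
#' Scans every offset of the sequence on both strands with a log-odds score
#' `sum(log2(P(base | PWM) / P(base | background)))`; the PWM is
#' column-normalized after adding a pseudocount. Ambiguous bases (anything
#' outside ACGT) contribute 0 (they are scored with the background
#' probability). Returns the maximum score and its location.
#'
#' @param sequence a character scalar or [Biostrings::DNAString]
#' @param pwm 4 x width matrix (rows A, C, G, T; counts or probabilities)
#' @param background base composition (A, C, G, T), default uniform
#' @param pseudocount added per PWM cell before normalization
#' @param bothStrands scan the reverse complement too
#' @return list with `maxScore`, `bestStart` (1-based offset of the best
#'   window), `bestStrand` (`"+"`/`"-"`), and `scores` (per-offset matrix
#'   with rows `+`/`-`)
#' @export
motifScan <- function(sequence, pwm, background = rep(0.25, 4),
                      pseudocount = 1e-3, bothStrands = TRUE) {
    seqChar <- toupper(as.character(sequence))
    bases <- strsplit(seqChar, "")[[1]]
    w <- ncol(pwm)
    if (length(bases) < w)
        stop("sequence shorter than the motif")
    p <- normalizePWM(pwm, pseudocount)
    background <- background / sum(background)
    lo <- log2(sweep(p, 1, background, "/"))   # 4 x w log-odds
    scoreStrand <- function(mat) {
        nOff <- length(bases) - w + 1L
        idx <- match(bases, c("A", "C", "G", "T"))
        out <- numeric(nOff)
        for (j in seq_len(w)) {
            contrib <- mat[, j][idx[seq(j, j + nOff - 1L)]]
            contrib[is.na(contrib)] <- 0   # ambiguous base
            out <- out + contrib
        }
        out
    }
    fwd <- scoreStrand(lo)
    if (bothStrands) {
        # scanning the reverse complement of each window == scanning the
        # forward sequence with the reverse-complemented PWM
        loRC <- lo[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
        rownames(loRC) <- c("A", "C", "G", "T")
        bwd <- scoreStrand(loRC)
        scores <- rbind(`+` = fwd, `-` = bwd)
    } else {
        scores <- rbind(`+` = fwd)
    }
    best <- which(scores == max(scores), arr.ind = TRUE)[1, ]
    list(maxScore = max(scores),
         bestStart = unname(best["col"]),
         bestStrand = rownames(scores)[best["row"]],
         scores = scores)
}

#' Scan every sequence of a FASTA file for a motif
#'
#' Applies [motifScan()] to each record of a FASTA file (e.g. CTCF peak
#' sequences) and reports the maximum motif-matching score per sequence.
#'
#' @param fasta path to a FASTA file of DNA sequences
#' @param pwm,background,pseudocount,bothStrands passed to [motifScan()]
#' @return data.frame with `name`, `maxScore`, `bestStart`, `bestStrand`;
#'   sequences shorter than the motif get NA scores
#' @export
motifScanFasta <- function(fasta, pwm, background = rep(0.25, 4),
                           pseudocount = 1e-3, bothStrands = TRUE) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    out <- data.frame(name = names(seqs), maxScore = NA_real_,
                      bestStart = NA_integer_,
                      bestStrand = NA_character_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(seqs)) {
        if (length(seqs[[i]]) < ncol(pwm)) next
        hit <- motifScan(seqs[[i]], pwm, background = background,
                         pseudocount = pseudocount,
                         bothStrands = bothStrands)
        out$maxScore[i] <- hit$maxScore
        out$bestStart[i] <- hit$bestStart
        out$bestStrand[i] <- hit$bestStrand
    }
    out
}

#' Mean signal profile around anchor positions (sitepro)
#'
#' Averages a genomic signal in offset bins around the midpoints of a set of
#' anchor intervals (strand-ignored), e.g. chromatin-mark density within
#' +/- 5 kb of enhancers or conservation within +/- 200 bp of CTCF motif
#' sites. Interval-valued tracks contribute their per-bp score; with
#' `pointFeatures = TRUE` the profile is the mean per-bin feature count (a
#' frequency profile, e.g. mutation density). An optional moving average of
#' `smoothing` bp is applied to the final profile.
#'
#' @param signal GRanges with a `score` column (track mode) or feature
#'   positions (point mode)
#' @param centers GRanges of anchors; the profile is centered on their
#'   midpoints
#' @param flank half-window in bp
#' @param bin offset bin width in bp (must divide `2*flank`)
#' @param smoothing moving-average window in bp (0 = off)
#' @param pointFeatures treat `signal` as point features and count them
#' @return data.frame with `offset` (bin start relative to the center, bp)
#'   and `value`
#' @export
siteproProfile <- function(signal, centers, flank, bin = 1, smoothing = 0,
                           pointFeatures = FALSE) {
    if (!length(centers)) stop("centers must be non-empty")
    if ((2 * flank) %% bin != 0)
        stop("bin must divide the window 2*flank")
    nb <- as.integer(2 * flank / bin)
    offsets <- -flank + (seq_len(nb) - 1L) * bin
    sigChrom <- as.character(GenomeInfoDb::seqnames(signal))
    available <- unique(sigChrom)
    cChrom <- as.character(GenomeInfoDb::seqnames(centers))
    usable <- cChrom %in% available
    if (pointFeatures) usable <- rep(TRUE, length(centers))
    if (!all(usable))
        message("skipping ", sum(!usable),
                " center(s) on chromosomes absent from the signal")
    centers <- centers[usable]
    cChrom <- cChrom[usable]
    if (!length(centers)) stop("no usable centers")
    mid0 <- floor((BiocGenerics::start(centers) - 1 +
                   BiocGenerics::end(centers)) / 2)   # 0-based midpoint
    acc <- numeric(nb)
    if (pointFeatures) {
        pos0 <- BiocGenerics::start(signal) - 1
        for (i in seq_along(centers)) {
            off <- pos0[sigChrom == cChrom[i]] - mid0[i]
            keep <- off >= -flank & off < flank
            if (any(keep))
                acc <- acc + tabulate(
                    floor((off[keep] + flank) / bin) + 1L, nbins = nb)
        }
        prof <- acc / length(centers)
    } else {
        cov <- GenomicRanges::coverage(signal, weight = "score")
        for (i in seq_along(centers)) {
            rl <- cov[[cChrom[i]]]
            from0 <- mid0[i] - flank
            to0 <- mid0[i] + flank           # [from0, to0) 0-based
            lo <- max(from0, 0)
            hi <- min(to0, length(rl))
            vals <- numeric(2 * flank)       # out-of-range padded with 0
            if (hi > lo)
                vals[(lo - from0 + 1):(hi - from0)] <-
                    as.numeric(rl[(lo + 1):hi])
            binned <- colMeans(matrix(vals, nrow = bin))
            acc <- acc + binned
        }
        prof <- acc / length(centers)
    }
    if (smoothing > 0) {
        k <- max(1L, as.integer(round(smoothing / bin)))
        if (k > 1L) {
            sm <- numeric(nb)
            half <- (k - 1L) %/% 2L
            for (idx in seq_len(nb)) {
                lo <- max(1L, idx - half)
                hi <- min(nb, idx + (k - 1L - half))
                sm[idx] <- mean(prof[lo:hi])
            }
            prof <- sm
        }
    }
    data.frame(offset = offsets, value = prof)
}

#' TAD-constrained enhancer-promoter mapping
#'
#' Connects an enhancer to a gene promoter when a significant chromatin
#' interaction has one anchor bin overlapping the enhancer and the other
#' overlapping the promoter, and enhancer, promoter and both anchor bins all
#' overlap one common TAD.
#'
#' @param enhancers GRanges of enhancers
#' @param promoters GRanges of promoter windows (see [promotersFromTSS()]);
#'   an optional `name` column labels the gene
#' @param contacts a [ContactSet] of significant pairs
#' @param tads GRanges of TADs
#' @return list with `edges` (data.frame `enhancerIndex`, `promoterIndex`,
#'   `gene`), `targetCounts` (per-enhancer out-degree) and the inputs'
#'   lengths
#' @export
mapEnhancersToPromoters <- function(enhancers, promoters, contacts, tads) {
    r <- contacts@records
    res <- contacts@resolution
    edges <- data.frame(enhancerIndex = integer(0),
                        promoterIndex = integer(0))
    if (nrow(r) && length(enhancers) && length(promoters)) {
        anchorGR <- function(mid) {
            s0 <- mid - res / 2
            GenomicRanges::GRanges(r$chrom,
                IRanges::IRanges(start = s0 + 1, end = s0 + res))
        }
        a1 <- anchorGR(r$mid1)
        a2 <- anchorGR(r$mid2)
        memb <- function(gr) {
            # logical matrix: interval x TAD any-overlap
            m <- matrix(FALSE, length(gr), length(tads))
            hits <- GenomicRanges::findOverlaps(gr, tads,
                                                ignore.strand = TRUE)
            m[cbind(S4Vectors::queryHits(hits),
                    S4Vectors::subjectHits(hits))] <- TRUE
            m
        }
        tadE <- memb(enhancers)
        tadP <- memb(promoters)
        tadA1 <- memb(a1)
        tadA2 <- memb(a2)
        collect <- function(anchorE, anchorP, tadAE, tadAP) {
            he <- GenomicRanges::findOverlaps(anchorE, enhancers,
                                              ignore.strand = TRUE)
            hp <- GenomicRanges::findOverlaps(anchorP, promoters,
                                              ignore.strand = TRUE)
            eByPair <- split(S4Vectors::subjectHits(he),
                             S4Vectors::queryHits(he))
            pByPair <- split(S4Vectors::subjectHits(hp),
                             S4Vectors::queryHits(hp))
            common <- intersect(names(eByPair), names(pByPair))
            out <- list()
            for (pr in common) {
                k <- as.integer(pr)
                for (e in eByPair[[pr]]) for (p in pByPair[[pr]]) {
                    ok <- tadE[e, ] & tadP[p, ] & tadAE[k, ] & tadAP[k, ]
                    if (any(ok))
                        out[[length(out) + 1L]] <-
                            c(enhancerIndex = e, promoterIndex = p)
                }
            }
            if (length(out)) as.data.frame(do.call(rbind, out)) else
                data.frame(enhancerIndex = integer(0),
                           promoterIndex = integer(0))
        }
        edges <- rbind(collect(a1, a2, tadA1, tadA2),
                       collect(a2, a1, tadA2, tadA1))
        edges <- unique(edges)
        edges <- edges[order(edges$enhancerIndex, edges$promoterIndex), ,
                       drop = FALSE]
        rownames(edges) <- NULL
    }
    gene <- S4Vectors::mcols(promoters)$name
    edges$gene <- if (!is.null(gene) && nrow(edges)) {
        gene[edges$promoterIndex]
    } else rep(NA_character_, nrow(edges))
    targetCounts <- tabulate(edges$enhancerIndex, nbins = length(enhancers))
    list(edges = edges, targetCounts = targetCounts,
         nEnhancers = length(enhancers), nPromoters = length(promoters))
}

#' Cell-type specificity of expression
#'
#' Fold-change of each gene's expression in the target cell type relative to
#' its mean across all cell types. Genes with zero mean are reported NA.
#'
#' @param expr non-negative gene x cell-type matrix
#' @param cell target cell-type (column name or index)
#' @return named numeric vector per gene
#' @export
expressionSpecificity <- function(expr, cell) {
    if (any(expr < 0)) stop("expression must be non-negative")
    mu <- rowMeans(expr)
    out <- expr[, cell] / mu
    out[mu == 0] <- NA_real_
    out
}

#' Fraction of hub enhancers overlapping TAD boundaries
#'
#' @param hub GRanges of hub enhancers (non-empty)
#' @param boundaries GRanges of TAD boundary windows
#' @return percentage (0-100)
#' @export
boundaryOverlapFraction <- function(hub, boundaries) {
    if (!length(hub)) stop("undefined: no hub enhancers")
    100 * mean(overlapAny(hub, boundaries))
}

#' Keyword filter for blood-associated traits
#'
#' Case-insensitive substring match of a trait column against the standard
#' blood/hematology keyword list used to subset GWAS catalog SNPs.
#'
#' @param traits character vector of trait descriptions
#' @param keywords keyword list (default: packaged blood-trait keywords)
#' @return logical vector
#' @export
bloodTraitFilter <- function(traits, keywords = bloodTraitKeywords()) {
    hit <- rep(FALSE, length(traits))
    lowered <- tolower(traits)
    for (kw in tolower(keywords))
        hit <- hit | grepl(kw, lowered, fixed = TRUE)
    hit
}

#' Packaged blood-trait keyword list
#'
#' @return character vector of trait keywords
#' @export
bloodTraitKeywords <- function() {
    c("Erythrocyte", "F-cell", "HbA2", "Hematocrit", "Hematological",
      "Hematology", "Hemoglobin", "Platelet", "Blood", "Anemia",
      "Sickle cell disease", "Thalassemia", "Leukemia", "Lymphoma",
      "Lymphocyte", "B cell ", "B-cell", "White blood cell")
}
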