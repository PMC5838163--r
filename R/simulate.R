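#' @include hierarchy.R
NULL

#' Configuration of the synthetic fixture generator
#'
#' Builds a validated [SimulationConfig]. The defaults describe the standard
#' desk-scale study condition: a small multi-chromosome genome, SEs spanning
#' eight 5 kb bins with 4-8 constituent peaks, isolated regular enhancers,
#' Poisson contact counts decaying as a power law of distance
#' (`mean = backgroundContactMean * (referenceDistance / distance) ^
#' decayExponent`, i.e. the stated background mean at the 50 kb reference
#' distance, the middle of the planted loop range), and, in hierarchical
#' SEs, one planted hub bin connected to `nHubPartners` partner bins at
#' loop-scale distances whose pair counts are multiplied by `hubFold`.
#' Partner bins are drawn outside SE spans, and their number is kept small
#' relative to the hub bin's total contact mass: a hub that simply scaled
#' all its contacts would be a pure multiplicative bias, which matrix
#' balancing removes by construction, whereas a modest set of discrete
#' loops survives it (see the methods vignette).
#'
#' @param seed integer seed; the fixture is a pure function of the config
#' @param nChrom number of chromosomes
#' @param chromLength chromosome length in bp
#' @param resolution bin size in bp
#' @param nSE,nRE numbers of planted super-enhancer clusters and isolated
#'   regular enhancers
#' @param fracHierarchical fraction of SEs given a planted hub bin
#' @param hubFold interaction-rate multiplier lambda at planted hub loops
#'   (>= 1; 1 = null, no planted structure)
#' @param backgroundContactMean Poisson mean at `referenceDistance`
#' @param referenceDistance distance (bp) at which the background mean is
#'   anchored (default 50 kb)
#' @param decayExponent power-law distance-decay exponent
#' @param nVariants number of variant loci
#' @param hubVariantFold sampling-weight multiplier of hub bins for variants
#' @param seSpanBins SE span in bins
#' @param minConstituents,maxConstituents constituent peaks per SE
#' @param nHubPartners partner anchor bins per planted hub
#' @param partnerDistanceBins integer range (length 2) of partner distances
#'   in bins
#' @param edgeMargin bp kept free of planted elements at each chromosome
#'   end (real enhancer clusters are not sub-telomeric, and bins next to a
#'   chromosome end have structurally truncated contact rows)
#' @return a [SimulationConfig]
#' @export
simConfig <- function(seed = 1, nChrom = 2, chromLength = 2e6,
                      resolution = 5000, nSE = 12, nRE = 60,
                      fracHierarchical = 0.5, hubFold = 5,
                      backgroundContactMean = 10, referenceDistance = 50000,
                      decayExponent = 1,
                      nVariants = 400, hubVariantFold = 5, seSpanBins = 8,
                      minConstituents = 4, maxConstituents = 8,
                      nHubPartners = 12, partnerDistanceBins = c(4, 40),
                      edgeMargin = 250000) {
    if (hubFold < 1) stop("hubFold must be >= 1")
    if (fracHierarchical < 0 || fracHierarchical > 1)
        stop("fracHierarchical must be in [0, 1]")
    if (any(c(nChrom, chromLength, resolution, nSE) <= 0) ||
        any(c(nRE, nVariants) < 0))
        stop("counts and sizes must be positive")
    if (minConstituents < 2 || maxConstituents < minConstituents)
        stop("invalid constituent range")
    params <- list(seed = as.integer(seed), nChrom = nChrom,
                   chromLength = chromLength, resolution = resolution,
                   nSE = nSE, nRE = nRE,
                   fracHierarchical = fracHierarchical, hubFold = hubFold,
                   backgroundContactMean = backgroundContactMean,
                   referenceDistance = referenceDistance,
                   decayExponent = decayExponent, nVariants = nVariants,
                   hubVariantFold = hubVariantFold, seSpanBins = seSpanBins,
                   minConstituents = minConstituents,
                   maxConstituents = maxConstituents,
                   nHubPartners = nHubPartners,
                   partnerDistanceBins = partnerDistanceBins,
                   edgeMargin = edgeMargin)
    methods::new("SimulationConfig", params = params)
}

#' Generate a complete synthetic fixture
#'
#' Produces a desk-scale dataset with known ground truth: a genome table;
#' enhancer peaks organized into planted SE clusters (high-signal peak runs
#' within stitching distance) and isolated regular enhancers; a TSS for the
#' nearest gene of each SE; TADs partitioning each chromosome; CTCF peaks at
#' TAD boundaries and hub bins; raw contact records with power-law distance
#' decay and planted hub loops; and variant loci oversampled at hub bins.
#' Everything is a deterministic function of the config seed.
#'
#' @param config a [SimulationConfig] from [simConfig()]
#' @return list with `seqinfo`, `peaks`, `tss`, `tads`, `ctcf`, `variants`,
#'   `contacts` (a raw [ContactSet]), `truth` (see Details) and `config`.
#'   `truth` holds `se` (data.frame: chrom, start0, end0, isHierarchical,
#'   hubBin), `enhancerLabels` (per peak: hub / non-hub / NA), and
#'   `variantClass` (hub / background per variant).
#' @export
simulateFixture <- function(config) {
    p <- config@params
    withSeed(p$seed, {
        res <- p$resolution
        nbins <- floor(p$chromLength / res)
        chroms <- sprintf("chr%d", seq_len(p$nChrom))
        seqinfo <- GenomeInfoDb::Seqinfo(seqnames = chroms,
            seqlengths = rep(as.integer(p$chromLength), p$nChrom))

        ## ---- element layout -------------------------------------------
        types <- sample(c(rep("SE", p$nSE), rep("RE", p$nRE)))
        peakRows <- list()
        tssRows <- list()
        seRows <- list()
        cursor <- rep(p$edgeMargin, p$nChrom)   # 0-based per-chrom cursor
        chromIdx <- 1L
        spanLen <- p$seSpanBins * res
        for (el in types) {
            need <- if (el == "SE") spanLen + 45000 else 30000
            tries <- 0L
            while (cursor[chromIdx] + need >
                   p$chromLength - p$edgeMargin) {
                chromIdx <- chromIdx %% p$nChrom + 1L
                tries <- tries + 1L
                if (tries > p$nChrom)
                    stop("genome too small for the requested elements")
            }
            chrom <- chroms[chromIdx]
            if (el == "SE") {
                spanStart <- ceiling(cursor[chromIdx] / res) * res
                k <- sample(p$minConstituents:p$maxConstituents, 1)
                w <- sample(800:1600, k, replace = TRUE)
                slots <- round(seq(spanStart + 200,
                                   spanStart + spanLen - 200 - w[k],
                                   length.out = k))
                jitter <- c(0, round(stats::runif(k - 2, -400, 400)), 0)
                starts <- slots + jitter
                score <- exp(stats::rnorm(k, log(20), 0.5))
                isHier <- stats::runif(1) < p$fracHierarchical
                hubConst <- sample(k, 1)
                hubBin <- floor((starts[hubConst] + w[hubConst] / 2) / res)
                peakRows[[length(peakRows) + 1L]] <- data.frame(
                    chrom = chrom, start0 = starts, end0 = starts + w,
                    score = score, element = length(seRows) + 1L,
                    type = "SE")
                seRows[[length(seRows) + 1L]] <- data.frame(
                    chrom = chrom, start0 = spanStart,
                    end0 = spanStart + spanLen, isHierarchical = isHier,
                    hubBin = if (isHier) hubBin else NA_integer_)
                tssPos <- spanStart + spanLen + 15000 +
                    sample.int(5000, 1)
                tssRows[[length(tssRows) + 1L]] <- data.frame(
                    chrom = chrom, pos0 = tssPos,
                    gene = sprintf("GENE%d", length(tssRows) + 1L))
                cursor[chromIdx] <- tssPos + 16000 +
                    round(stats::runif(1, 0, 15000))
            } else {
                w <- sample(600:1500, 1)
                start0 <- cursor[chromIdx]
                peakRows[[length(peakRows) + 1L]] <- data.frame(
                    chrom = chrom, start0 = start0, end0 = start0 + w,
                    score = exp(stats::rnorm(1, log(2), 0.5)),
                    element = NA_integer_, type = "RE")
                cursor[chromIdx] <- start0 + w + 15000 +
                    round(stats::runif(1, 0, 15000))
            }
            chromIdx <- chromIdx %% p$nChrom + 1L
        }
        peakDf <- do.call(rbind, peakRows)
        seDf <- if (length(seRows)) do.call(rbind, seRows) else
            data.frame(chrom = character(0), start0 = numeric(0),
                       end0 = numeric(0), isHierarchical = logical(0),
                       hubBin = integer(0))

        ## ---- truth enhancer labels ------------------------------------
        labels <- rep(NA_character_, nrow(peakDf))
        for (i in seq_len(nrow(seDf))) {
            if (!seDf$isHierarchical[i]) next
            sel <- which(!is.na(peakDf$element) & peakDf$element == i)
            hb <- seDf$hubBin[i]
            hubLo <- hb * res
            hubHi <- (hb + 1) * res
            onHub <- peakDf$start0[sel] < hubHi & peakDf$end0[sel] > hubLo
            labels[sel] <- ifelse(onHub, "hub", "non-hub")
        }

        ## ---- planted hub loops ----------------------------------------
        seBinSpan <- cbind(floor(seDf$start0 / res),
                           ceiling(seDf$end0 / res) - 1)
        hubPairs <- list()   # per chrom: two-column matrices of bin pairs
        for (ch in chroms) hubPairs[[ch]] <- NULL
        drange <- seq(p$partnerDistanceBins[1], p$partnerDistanceBins[2])
        for (i in seq_len(nrow(seDf))) {
            if (!seDf$isHierarchical[i]) next
            ch <- seDf$chrom[i]
            h <- seDf$hubBin[i]
            cand <- h + c(-drange, drange)
            cand <- cand[cand >= 0 & cand < nbins]
            inSE <- rep(FALSE, length(cand))
            onCh <- which(seDf$chrom == ch)
            for (j in onCh)
                inSE <- inSE | (cand >= seBinSpan[j, 1] &
                                cand <= seBinSpan[j, 2])
            cand <- cand[!inSE]
            take <- if (length(cand) > p$nHubPartners) {
                sample(cand, p$nHubPartners)
            } else cand
            if (length(take))
                hubPairs[[ch]] <- rbind(hubPairs[[ch]],
                    cbind(pmin(h, take), pmax(h, take)))
        }

        ## ---- contact records ------------------------------------------
        maxD <- min(nbins - 1, 400)
        refBins <- p$referenceDistance / res
        meanAt <- function(d)
            p$backgroundContactMean * (refBins / d)^p$decayExponent
        recList <- list()
        for (ch in chroms) {
            hp <- hubPairs[[ch]]
            for (d in seq_len(maxD)) {
                i0 <- 0:(nbins - 1 - d)
                mu <- rep(meanAt(d), length(i0))
                if (!is.null(hp)) {
                    sel <- hp[hp[, 2] - hp[, 1] == d, 1]
                    if (length(sel))
                        mu[sel + 1] <- mu[sel + 1] * p$hubFold
                }
                cnt <- stats::rpois(length(i0), mu)
                nz <- cnt > 0
                if (any(nz))
                    recList[[length(recList) + 1L]] <- data.frame(
                        chrom = ch,
                        mid1 = i0[nz] * res + res / 2,
                        mid2 = (i0[nz] + d) * res + res / 2,
                        count = cnt[nz])
            }
        }
        rec <- do.call(rbind, recList)
        contacts <- contactSet(rec$chrom, rec$mid1, rec$mid2, rec$count,
                               resolution = res)

        ## ---- TADs ------------------------------------------------------
        tadRows <- list()
        for (ch in chroms) {
            pos <- 0
            while (pos < nbins) {
                len <- sample(50:100, 1)
                hi <- min(pos + len, nbins)
                tadRows[[length(tadRows) + 1L]] <- data.frame(
                    chrom = ch, start0 = pos * res, end0 = hi * res)
                pos <- hi
            }
        }
        tadDf <- do.call(rbind, tadRows)

        ## ---- CTCF peaks ------------------------------------------------
        ctcfRows <- list()
        for (i in seq_len(nrow(tadDf))) {
            edge <- tadDf$end0[i]
            if (edge >= p$chromLength) next
            ctcfRows[[length(ctcfRows) + 1L]] <- data.frame(
                chrom = tadDf$chrom[i], start0 = edge - 100,
                end0 = edge + 100)
        }
        for (i in seq_len(nrow(seDf))) {
            if (!seDf$isHierarchical[i]) next
            c0 <- seDf$hubBin[i] * res + res / 2 - 150
            ctcfRows[[length(ctcfRows) + 1L]] <- data.frame(
                chrom = seDf$chrom[i], start0 = c0, end0 = c0 + 300)
        }
        for (ch in chroms) {
            s0 <- sort(sample.int(p$chromLength - 400, 20))
            ctcfRows[[length(ctcfRows) + 1L]] <- data.frame(
                chrom = ch, start0 = s0, end0 = s0 + 250)
        }
        ctcfDf <- do.call(rbind, ctcfRows)
        ctcfDf <- ctcfDf[order(ctcfDf$chrom, ctcfDf$start0), , drop = FALSE]

        ## ---- variants --------------------------------------------------
        hubKey <- character(0)
        if (any(seDf$isHierarchical))
            hubKey <- paste(seDf$chrom[seDf$isHierarchical],
                            seDf$hubBin[seDf$isHierarchical])
        allBins <- expand.grid(chrom = chroms, bin = 0:(nbins - 1),
                               stringsAsFactors = FALSE)
        wts <- ifelse(paste(allBins$chrom, allBins$bin) %in% hubKey,
                      p$hubVariantFold, 1)
        vIdx <- sample.int(nrow(allBins), p$nVariants, replace = TRUE,
                           prob = wts)
        vPos0 <- allBins$bin[vIdx] * res +
            sample.int(res, p$nVariants, replace = TRUE) - 1L
        vClass <- ifelse(paste(allBins$chrom[vIdx], allBins$bin[vIdx]) %in%
                         hubKey, "hub", "background")
        vOrd <- order(allBins$chrom[vIdx], vPos0)

        ## ---- assemble GRanges -----------------------------------------
        peaks <- bed0ToGRanges(peakDf$chrom, peakDf$start0, peakDf$end0,
            seqinfo = seqinfo, name = sprintf("E%d", seq_len(nrow(peakDf))),
            score = peakDf$score)
        tssDf <- if (length(tssRows)) do.call(rbind, tssRows) else
            data.frame(chrom = character(0), pos0 = numeric(0),
                       gene = character(0))
        tss <- bed0ToGRanges(tssDf$chrom, tssDf$pos0, tssDf$pos0 + 1,
            seqinfo = seqinfo, name = tssDf$gene)
        tads <- bed0ToGRanges(tadDf$chrom, tadDf$start0, tadDf$end0,
                              seqinfo = seqinfo)
        ctcf <- bed0ToGRanges(ctcfDf$chrom, ctcfDf$start0, ctcfDf$end0,
            seqinfo = seqinfo,
            name = sprintf("CTCF%d", seq_len(nrow(ctcfDf))))
        variants <- bed0ToGRanges(allBins$chrom[vIdx][vOrd], vPos0[vOrd],
            vPos0[vOrd] + 1, seqinfo = seqinfo, name = vClass[vOrd])

        list(seqinfo = seqinfo, peaks = peaks, tss = tss, tads = tads,
             ctcf = ctcf, variants = variants, contacts = contacts,
             truth = list(se = seDf, enhancerLabels = labels,
                          variantClass = vClass[vOrd]),
             config = config)
    })
}

#' Write a fixture bundle to a directory
#'
#' Emits `chrom.sizes`, `peaks.narrowPeak`, `contacts.tsv` (5-column
#' chrom/mid/chrom/mid/count), `tads.bed`, `ctcf.bed`, `variants.bed`,
#' `tss.bed` and `truth.json`. Output is byte-stable for a given fixture.
#'
#' @param sim result of [simulateFixture()]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
writeFixture <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sl <- GenomeInfoDb::seqlengths(sim$seqinfo)
    writeLines(sprintf("%s\t%d", names(sl), sl),
               file.path(dir, "chrom.sizes"))
    pk <- grangesToBed0(sim$peaks)
    mc <- S4Vectors::mcols(sim$peaks)
    writeLines(sprintf("%s\t%s\t%s\t%s\t%d\t.\t%s\t-1\t-1\t-1",
        pk$chrom, fmtNum(pk$start), fmtNum(pk$end), mc$name,
        pmin(1000L, as.integer(round(mc$score * 10))),
        fmtNum(mc$score, 6)), file.path(dir, "peaks.narrowPeak"))
    r <- sim$contacts@records
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s", r$chrom, fmtNum(r$mid1),
                       r$chrom, fmtNum(r$mid2), fmtNum(r$rawCount)),
               file.path(dir, "contacts.tsv"))
    writeBed(sim$tads, file.path(dir, "tads.bed"))
    writeBed(sim$ctcf, file.path(dir, "ctcf.bed"))
    writeBed(sim$variants, file.path(dir, "variants.bed"))
    writeBed(sim$tss, file.path(dir, "tss.bed"))
    truth <- sim$truth
    jsonlite::write_json(
        list(se = truth$se, enhancerLabels = truth$enhancerLabels,
             variantClass = truth$variantClass,
             config = sim$config@params),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
        na = "null", pretty = TRUE)
    invisible(dir)
}

#' The packaged golden-fixture configuration
#'
#' A fixed small configuration (2 chromosomes x 2 Mb, 12 SEs, 60 regular
#' enhancers, seed 20240611) used for end-to-end regression tests; the
#' frozen expected outputs under `inst/extdata/golden/` were produced by
#' [runPipeline()] on exactly this fixture.
#'
#' @return a [SimulationConfig]
#' @export
goldenConfig <- function() {
    simConfig(seed = 20240611, nChrom = 2, chromLength = 2e6, nSE = 12,
              nRE = 60, fracHierarchical = 0.5, hubFold = 5,
              backgroundContactMean = 10, nVariants = 400,
              hubVariantFold = 5)
}

#' Materialize the golden fixture
#'
#' Regenerates the golden fixture deterministically from [goldenConfig()]
#' and writes it to `dir`.
#'
#' @param dir output directory
#' @return the fixture list (see [simulateFixture()]), invisibly extended
#'   with `dir`
#' @export
goldenFixture <- function(dir = tempfile("golden")) {
    sim <- simulateFixture(goldenConfig())
    writeFixture(sim, dir)
    sim$dir <- dir
    invisible(sim)
}

#' Score pipeline hub recovery against fixture truth
#'
#' Matches pipeline SE calls to planted SE spans by overlap and computes
#' hub-bin sensitivity and precision (over truth hub bins of planted
#' hierarchical SEs vs predicted hub bins) and hierarchical/non-hierarchical
#' classification accuracy over the matched SEs.
#'
#' @param sim fixture from [simulateFixture()]
#' @param calls a [HierarchyCallSet] from the pipeline
#' @return list with `sensitivity`, `precision`, `accuracy`, `nMatched`
#' @export
evaluateRecovery <- function(sim, calls) {
    truthSE <- sim$truth$se
    res <- calls@resolution
    truthGR <- bed0ToGRanges(truthSE$chrom, truthSE$start0, truthSE$end0)
    callGR <- calls@se@regions
    hits <- GenomicRanges::findOverlaps(truthGR, callGR,
                                        ignore.strand = TRUE)
    matched <- tapply(S4Vectors::subjectHits(hits),
                      S4Vectors::queryHits(hits), `[`, 1)
    predBins <- calls@bins[calls@bins$isHub, , drop = FALSE]
    predKey <- paste(predBins$chrom, floor((predBins$start - 1) / res))
    truthHier <- truthSE$isHierarchical
    truthKey <- paste(truthSE$chrom, truthSE$hubBin)[truthHier]
    sens <- if (length(truthKey)) mean(truthKey %in% predKey) else NA_real_
    prec <- if (length(predKey)) mean(predKey %in% truthKey) else NA_real_
    acc <- NA_real_
    nMatched <- length(matched)
    if (nrow(truthSE)) {
        ti <- as.integer(names(matched))
        predHier <- calls@summary$isHierarchical[as.integer(matched)]
        # truth SEs with no matching pipeline SE count as misclassified
        acc <- sum(predHier == truthHier[ti]) / nrow(truthSE)
    }
    list(sensitivity = sens, precision = prec, accuracy = acc,
         nMatched = nMatched)
}
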