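#' @include simulate.R annotation.R
NULL

pipelineDefaults <- function() {
    list(resolution = 5000, stitchGap = 12500, L = 10000, U = 2e6,
         fdr = 0.01, threshold = 1.5, promoterFlank = 2000, seed = 1,
         backgroundMultiplier = 10)
}

#' Run the full SE-hierarchy pipeline
#'
#' Executes the whole workflow on files: read peaks (and optional blacklist
#' / TSS), filter, stitch, rank and apply the SE cutoff; read raw contacts,
#' ICE-balance, call significant interactions and count per-bin frequencies;
#' compute H-scores, hierarchical SE calls and hub/non-hub labels; and, when
#' variant / TAD / CTCF inputs are provided, the downstream enrichment and
#' context statistics. All outputs plus a machine-readable manifest are
#' written to `outDir`; a repeated run with the same config is byte
#' identical.
#'
#' @param config named list or path to a YAML file. Required fields:
#'   `peaks`, `contacts`, `chromSizes`. Optional inputs: `blacklist`, `tss`,
#'   `variants`, `tads`, `ctcf`. Parameters (with defaults): `resolution`
#'   5000, `stitchGap` 12500, `L` 10000, `U` 2e6, `fdr` 0.01, `threshold`
#'   1.5, `promoterFlank` 2000, `seed` 1, `backgroundMultiplier` 10 (size
#'   multiplier of the shuffled regular-enhancer background).
#' @param outDir output directory (created if needed)
#' @return invisibly, a list with the main in-memory results (`se`,
#'   `hic`, `calls`, and `enrichment` when computed)
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(pipelineDefaults(), config)
    for (key in c("peaks", "contacts", "chromSizes")) {
        if (is.null(cfg[[key]]))
            stop("missing required config field: ", key)
        if (!file.exists(cfg[[key]]))
            stop("input path for --", key, " does not exist: ", cfg[[key]])
    }
    for (key in c("blacklist", "tss", "variants", "tads", "ctcf")) {
        if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
            stop("input path for --", key, " does not exist: ", cfg[[key]])
    }
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    seqinfo <- readChromSizes(cfg$chromSizes)
    peaks <- readIntervals(cfg$peaks, seqinfo = seqinfo)
    blacklist <- if (!is.null(cfg$blacklist)) {
        readIntervals(cfg$blacklist, seqinfo = seqinfo)
    } else GenomicRanges::GRanges()
    promoters <- if (!is.null(cfg$tss)) {
        promotersFromTSS(readIntervals(cfg$tss, seqinfo = seqinfo),
                         flank = cfg$promoterFlank)
    } else GenomicRanges::GRanges()

    sset <- callSuperEnhancers(peaks, blacklist, promoters,
                               gap = cfg$stitchGap)
    writeSuperEnhancers(sset, outDir)

    contacts <- readContacts(cfg$contacts, resolution = cfg$resolution)
    sigCfg <- significanceConfig(L = cfg$L, U = cfg$U, fdr = cfg$fdr)
    hic <- hicSignificant(contacts, seqinfo = seqinfo, config = sigCfg)
    writeBedpe(hic$significant, file.path(outDir, "significant.bedpe"))
    writeBedGraph(hic$track, file.path(outDir, "bin_frequency.bedgraph"))

    calls <- hierarchyCalls(sset, hic$track, threshold = cfg$threshold,
                            resolution = cfg$resolution)
    writeHierarchyCalls(calls, outDir)

    enrich <- NULL
    if (!is.null(cfg$variants) && any(!isSuper(sset), na.rm = TRUE)) {
        variants <- readIntervals(cfg$variants, seqinfo = seqinfo)
        isS <- isSuper(sset)
        reCon <- unlist(sset@constituents[!isS], use.names = FALSE)
        nonHierCon <- {
            hier <- isHierarchical(calls)
            unlist(seConstituents(calls)[!hier], use.names = FALSE)
        }
        background <- shuffleIntervals(
            rep(reCon, cfg$backgroundMultiplier), seqinfo,
            seed = cfg$seed)
        groups <- list(hub = hubEnhancers(calls),
                       `non-hub` = nonhubEnhancers(calls),
                       `non-hierarchical` = nonHierCon,
                       regular = reCon)
        rows <- character(0)
        enrich <- list()
        for (g in names(groups)) {
            if (!length(groups[[g]])) next
            er <- enrichmentScore(groups[[g]], variants, background,
                                  groupName = g)
            enrich[[g]] <- er
            rows <- c(rows, sprintf("%s\t%d\t%d\t%d\t%d\t%s\t%s", g,
                as.integer(er@m), as.integer(er@n), as.integer(er@M),
                as.integer(er@N), fmtNum(er@score, 6),
                fmtNum(er@fisherP, 6)))
        }
        writeLines(c("# group\tm\tn\tM\tN\tscore\tfisher_p", rows),
                   file.path(outDir, "enrichment.tsv"))
    }

    if (!is.null(cfg$ctcf) && !is.null(cfg$tads)) {
        ctcf <- readIntervals(cfg$ctcf, seqinfo = seqinfo)
        tads <- readIntervals(cfg$tads, seqinfo = seqinfo)
        boundaries <- tadBoundaries(tads, resolution = cfg$resolution)
        ctx <- ctcfContext(ctcf, hubEnhancers(calls),
                           nonhubEnhancers(calls), boundaries)
        bed <- grangesToBed0(ctx)
        writeLines(sprintf("%s\t%s\t%s\t%s", bed$chrom, fmtNum(bed$start),
                           fmtNum(bed$end),
                           as.character(S4Vectors::mcols(ctx)$context)),
                   file.path(outDir, "ctcf_context.bed"))
    }

    manifest <- list(
        package = "SEhierarchy",
        version = as.character(utils::packageVersion("SEhierarchy")),
        inputs = lapply(cfg[intersect(names(cfg),
            c("peaks", "contacts", "chromSizes", "blacklist", "tss",
              "variants", "tads", "ctcf"))], basename),
        parameters = cfg[intersect(names(cfg), names(pipelineDefaults()))],
        results = list(
            nPeaks = length(peaks),
            nStitched = length(seRegions(sset)),
            nSuper = sum(isSuper(sset), na.rm = TRUE),
            nSignificant = nrow(contactRecords(hic$significant)),
            nHierarchical = sum(isHierarchical(calls)),
            nHub = length(hubEnhancers(calls)),
            nNonHub = length(nonhubEnhancers(calls))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(se = sset, hic = hic, calls = calls,
                   enrichment = enrich))
}
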