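#' @include SEhierarchy-package.R
NULL

# BED text is 0-based half-open; GRanges is 1-based closed. These two helpers
# are the only place the shift happens.
bed0ToGRanges <- function(chrom, start0, end0, ..., seqinfo = NULL) {
    if (any(start0 < 0) || any(start0 >= end0))
        stop("invalid interval: need 0 <= start < end")
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1L, end = end0), ...)
    if (!is.null(seqinfo)) {
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
        GenomeInfoDb::seqinfo(gr) <- seqinfo
    }
    gr
}

grangesToBed0 <- function(gr) {
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               stringsAsFactors = FALSE)
}

#' Read genomic intervals from BED or ENCODE narrowPeak files
#'
#' Parses BED3/BED6 or 10-column ENCODE narrowPeak into a
#' [GenomicRanges::GRanges]. BED coordinates (0-based half-open) are converted
#' to the 1-based closed GRanges convention. For narrowPeak the `score`
#' metadata column is taken from `signalValue` (column 7) rather than the
#' capped column 5; for BED it is column 5 when present.
#'
#' @param path file path to a headerless tab-separated BED-like file; lines
#'   starting with `#`, `track` or `browser` are skipped.
#' @param format one of `"auto"`, `"bed"`, `"narrowPeak"`; `"auto"` treats
#'   10-column input as narrowPeak.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] to attach (enables
#'   bounds checking downstream).
#' @return a GRanges with metadata columns `name` and `score` where available;
#'   intervals appear in file order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tE1\t7.5", f)
#' readIntervals(f)
#' @export
readIntervals <- function(path, format = c("auto", "bed", "narrowPeak"),
                          seqinfo = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        return(GenomicRanges::GRanges(seqinfo = seqinfo))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols < 3))
        stop("malformed line ", lineNo[which(ncols < 3)[1]],
             ": fewer than 3 fields")
    nc <- min(ncols)
    if (format == "auto")
        format <- if (nc >= 10) "narrowPeak" else "bed"
    if (format == "narrowPeak" && nc < 10)
        stop("narrowPeak requires 10 columns; found ", nc)
    getcol <- function(i) vapply(fields, `[[`, character(1), i)
    chrom <- getcol(1)
    start0 <- suppressWarnings(as.numeric(getcol(2)))
    end0 <- suppressWarnings(as.numeric(getcol(3)))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
        stop("malformed line ", lineNo[bad[1]], ": non-numeric coordinates")
    bad <- which(start0 < 0 | start0 >= end0)
    if (length(bad))
        stop("invalid interval at line ", lineNo[bad[1]],
             ": need 0 <= start < end")
    name <- if (nc >= 4) getcol(4) else NA_character_
    score <- if (format == "narrowPeak") {
        suppressWarnings(as.numeric(getcol(7)))
    } else if (nc >= 5) {
        suppressWarnings(as.numeric(getcol(5)))
    } else NA_real_
    strand <- if (nc >= 6) getcol(6) else "*"
    strand[!strand %in% c("+", "-")] <- "*"
    bed0ToGRanges(chrom, start0, end0, strand = strand,
                  name = name, score = score, seqinfo = seqinfo)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path tab-separated file with columns chromosome name and length.
#' @return a [GenomeInfoDb::Seqinfo]
#' @export
readChromSizes <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "length"))
    if (anyDuplicated(tab$chrom)) stop("duplicated chromosome names")
    if (any(tab$length <= 0)) stop("chromosome lengths must be > 0")
    GenomeInfoDb::Seqinfo(seqnames = tab$chrom,
                          seqlengths = as.integer(tab$length))
}

#' Read raw intra-chromosomal contact records
#'
#' Reads tab-separated contact triples into a [ContactSet]. Two dialects are
#' supported: 3-column `(mid1, mid2, count)` for a single chromosome given
#' via `chrom`, and 5-column `(chrom1, mid1, chrom2, mid2, count)`.
#' Midpoints are bin midpoints on the genome grid (`mid = k*resolution +
#' resolution/2`, 0-based) as in published 5 kb matrix dumps.
#' Inter-chromosomal records in the 5-column dialect are dropped with a
#' message; self-pairs (`mid1 == mid2`) are kept out of the record table (they
#' participate in balancing only when matrices are built from it with
#' `diagonal` supplied separately).
#'
#' @param path file path
#' @param resolution bin size in bp (default 5000)
#' @param chrom chromosome name, required for the 3-column dialect
#' @return a [ContactSet] with `normCount` initialized to `rawCount` and
#'   `p`/`q` set to NA
#' @export
readContacts <- function(path, resolution = 5000, chrom = NULL) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) == 3) {
        if (is.null(chrom))
            stop("3-column contact input requires `chrom`")
        df <- data.frame(chrom = chrom, mid1 = tab[[1]], mid2 = tab[[2]],
                         count = tab[[3]], stringsAsFactors = FALSE)
    } else if (ncol(tab) >= 5) {
        inter <- tab[[1]] != tab[[3]]
        if (any(inter))
            message("dropping ", sum(inter), " inter-chromosomal record(s)")
        tab <- tab[!inter, , drop = FALSE]
        df <- data.frame(chrom = tab[[1]], mid1 = tab[[2]], mid2 = tab[[4]],
                         count = tab[[5]], stringsAsFactors = FALSE)
    } else stop("contact input must have 3 or 5 columns")
    contactSet(df$chrom, df$mid1, df$mid2, df$count, resolution = resolution)
}

#' Construct a ContactSet from vectors
#'
#' Orders each pair so `mid1 < mid2`, sums duplicate pairs, and drops
#' self-pairs (`mid1 == mid2`).
#'
#' @param chrom,mid1,mid2,count parallel vectors of contact records
#' @param normCount optional normalized counts (defaults to `count`)
#' @param resolution bin size in bp
#' @return a [ContactSet]
#' @export
contactSet <- function(chrom, mid1, mid2, count, normCount = NULL,
                       resolution = 5000) {
    lo <- pmin(mid1, mid2)
    hi <- pmax(mid1, mid2)
    keep <- lo < hi
    if (is.null(normCount)) normCount <- count
    df <- data.frame(chrom = as.character(chrom)[keep], mid1 = lo[keep],
                     mid2 = hi[keep], rawCount = count[keep],
                     normCount = normCount[keep],
                     stringsAsFactors = FALSE)
    key <- paste(df$chrom, df$mid1, df$mid2)
    if (anyDuplicated(key)) {
        agg <- rowsum(cbind(df$rawCount, df$normCount), key, reorder = FALSE)
        first <- !duplicated(key)
        df <- df[first, , drop = FALSE]
        df$rawCount <- agg[, 1]
        df$normCount <- agg[, 2]
    }
    df$distance <- df$mid2 - df$mid1
    df$p <- rep(NA_real_, nrow(df))
    df$q <- rep(NA_real_, nrow(df))
    rownames(df) <- NULL
    methods::new("ContactSet", records = df, resolution = resolution)
}

#' Write intervals as headerless BED
#'
#' Emits BED6 when `score` or `name` metadata are present, BED3 otherwise.
#' Coordinates are converted back to 0-based half-open.
#'
#' @param gr a GRanges
#' @param path output file
#' @param scoreDigits significant digits for the score column
#' @return invisibly, the path
#' @export
writeBed <- function(gr, path, scoreDigits = 6) {
    df <- grangesToBed0(gr)
    mc <- S4Vectors::mcols(gr)
    if (any(c("name", "score") %in% names(mc))) {
        df$name <- if ("name" %in% names(mc)) {
            ifelse(is.na(mc$name), ".", mc$name)
        } else "."
        df$score <- if ("score" %in% names(mc)) {
            fmtNum(mc$score, scoreDigits)
        } else "0"
        df$strand <- {
            s <- as.character(BiocGenerics::strand(gr))
            ifelse(s == "*", ".", s)
        }
    }
    lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Write a BinFrequencyTrack as bedGraph
#'
#' @param track a [BinFrequencyTrack]
#' @param path output file
#' @return invisibly, the path
#' @export
writeBedGraph <- function(track, path) {
    cts <- track@counts
    cts <- cts[order(cts$chrom, cts$bin), , drop = FALSE]
    res <- track@resolution
    lines <- sprintf("%s\t%s\t%s\t%s", cts$chrom, fmtNum(cts$bin * res),
                     fmtNum((cts$bin + 1) * res), fmtNum(cts$count))
    writeLines(lines, path)
    invisible(path)
}

#' Write significant contacts as BEDPE
#'
#' One row per significant pair: the two anchor bins (0-based half-open), a
#' name, and `-log10(q)` as score.
#'
#' @param contacts a [ContactSet] (typically from [significantContacts()])
#' @param path output file
#' @return invisibly, the path
#' @export
writeBedpe <- function(contacts, path) {
    r <- contacts@records
    res <- contacts@resolution
    s1 <- r$mid1 - res / 2
    s2 <- r$mid2 - res / 2
    score <- ifelse(is.na(r$q), "NA",
                    fmtNum(-log10(pmax(r$q, 1e-300)), 6))
    lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                     r$chrom, fmtNum(s1), fmtNum(s1 + res),
                     r$chrom, fmtNum(s2), fmtNum(s2 + res),
                     sprintf("pair_%d", seq_len(nrow(r))), score)
    writeLines(lines, path)
    invisible(path)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the JASPAR text layout: a `>` header line then four rows
#' `A [ 4 19 0 ... ]` (brackets optional). Returns the raw count/frequency
#' matrix with rows A, C, G, T.
#'
#' @param path file path
#' @return a 4 x width numeric matrix with rownames A, C, G, T
#' @export
readJaspar <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^>", lines)]
    if (length(lines) < 4) stop("expected 4 base rows in PWM file")
    parseRow <- function(ln) {
        ln <- gsub("[][]", " ", ln)
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        list(base = toupper(parts[1]), vals = as.numeric(parts[-1]))
    }
    rows <- lapply(lines[1:4], parseRow)
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
        stop("PWM rows must be labelled A, C, G, T")
    w <- unique(lengths(lapply(rows, `[[`, "vals")))
    if (length(w) != 1) stop("ragged PWM rows")
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(m) <- bases
    m[c("A", "C", "G", "T"), , drop = FALSE]
}
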