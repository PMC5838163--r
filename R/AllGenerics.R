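#' @include AllClasses.R
NULL

#' Accessors for SEhierarchy containers
#'
#' Accessor generics for the package's S4 containers. `seRegions()` returns
#' the stitched spans of a [SuperEnhancerSet] (or the SE regions behind a
#' [HierarchyCallSet]); `seConstituents()` the parallel GRangesList of member
#' peaks; `totalSignal()`, `seRank()` and `isSuper()` the per-region metadata;
#' `contactRecords()` the data.frame behind a [ContactSet];
#' `significantContacts()` its FDR-passing subset; `binFrequencies()` looks
#' up per-bin counts in a [BinFrequencyTrack]; `hScores()`,
#' `isHierarchical()`, `hubEnhancers()` and `nonhubEnhancers()` read a
#' [HierarchyCallSet].
#'
#' @param x an SEhierarchy container
#' @param ... further arguments passed to methods
#' @return see the method descriptions
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seRegions", function(x, ...) standardGeneric("seRegions"))

#' @rdname accessors
#' @export
setGeneric("seConstituents",
           function(x, ...) standardGeneric("seConstituents"))

#' @rdname accessors
#' @export
setGeneric("totalSignal", function(x, ...) standardGeneric("totalSignal"))

#' @rdname accessors
#' @export
setGeneric("seRank", function(x, ...) standardGeneric("seRank"))

#' @rdname accessors
#' @export
setGeneric("isSuper", function(x, ...) standardGeneric("isSuper"))

#' @rdname accessors
#' @export
setGeneric("contactRecords",
           function(x, ...) standardGeneric("contactRecords"))

#' @rdname accessors
#' @export
setGeneric("significantContacts",
           function(x, ...) standardGeneric("significantContacts"))

#' @rdname accessors
#' @export
setGeneric("binFrequencies",
           function(x, ...) standardGeneric("binFrequencies"))

#' @rdname accessors
#' @export
setGeneric("hScores", function(x, ...) standardGeneric("hScores"))

#' @rdname accessors
#' @export
setGeneric("isHierarchical",
           function(x, ...) standardGeneric("isHierarchical"))

#' @rdname accessors
#' @export
setGeneric("hubEnhancers", function(x, ...) standardGeneric("hubEnhancers"))

#' @rdname accessors
#' @export
setGeneric("nonhubEnhancers",
           function(x, ...) standardGeneric("nonhubEnhancers"))

#' @rdname accessors
#' @export
setMethod("seRegions", "SuperEnhancerSet", function(x, ...) x@regions)

#' @rdname accessors
#' @export
setMethod("seRegions", "HierarchyCallSet", function(x, ...) x@se@regions)

#' @rdname accessors
#' @export
setMethod("seConstituents", "SuperEnhancerSet",
          function(x, ...) x@constituents)

#' @rdname accessors
#' @export
setMethod("seConstituents", "HierarchyCallSet",
          function(x, ...) x@se@constituents)

#' @rdname accessors
#' @export
setMethod("totalSignal", "SuperEnhancerSet",
          function(x, ...) S4Vectors::mcols(x@regions)$totalSignal)

#' @rdname accessors
#' @export
setMethod("seRank", "SuperEnhancerSet",
          function(x, ...) S4Vectors::mcols(x@regions)$rank)

#' @rdname accessors
#' @export
setMethod("isSuper", "SuperEnhancerSet",
          function(x, ...) S4Vectors::mcols(x@regions)$isSuper)

#' @rdname accessors
#' @export
setMethod("contactRecords", "ContactSet", function(x, ...) x@records)

#' @rdname accessors
#' @param fdr FDR threshold applied to the BH-adjusted q-values
#' @export
setMethod("significantContacts", "ContactSet", function(x, fdr = 0.01, ...) {
    r <- x@records
    keep <- !is.na(r$q) & r$q <= fdr
    methods::new("ContactSet", records = r[keep, , drop = FALSE],
                 resolution = x@resolution)
})

#' @rdname accessors
#' @param chrom chromosome name (scalar)
#' @param bins integer vector of 0-based bin indices
#' @export
setMethod("binFrequencies", "BinFrequencyTrack",
          function(x, chrom, bins, ...) {
    cts <- x@counts[x@counts$chrom == chrom, , drop = FALSE]
    out <- cts$count[match(bins, cts$bin)]
    out[is.na(out)] <- 0
    as.integer(out)
})

#' @rdname accessors
#' @export
setMethod("hScores", "HierarchyCallSet", function(x, ...) x@summary$hScore)

#' @rdname accessors
#' @export
setMethod("isHierarchical", "HierarchyCallSet",
          function(x, ...) x@summary$isHierarchical)

#' @rdname accessors
#' @export
setMethod("hubEnhancers", "HierarchyCallSet", function(x, ...) {
    flat <- unlist(x@se@constituents, use.names = FALSE)
    flat[!is.na(x@labels) & x@labels == "hub"]
})

#' @rdname accessors
#' @export
setMethod("nonhubEnhancers", "HierarchyCallSet", function(x, ...) {
    flat <- unlist(x@se@constituents, use.names = FALSE)
    flat[!is.na(x@labels) & x@labels == "non-hub"]
})
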