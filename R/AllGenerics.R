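#' @rdname SiteEvidence-class
#' @param x,object a `SiteEvidence` object.
#' @param pool `"fast"` or `"slow"`.
#' @export
setGeneric("poolCounts", function(x, pool) standardGeneric("poolCounts"))

#' @rdname SiteEvidence-class
#' @export
setGeneric("poolQuals", function(x, pool) standardGeneric("poolQuals"))

#' @rdname SiteEvidence-class
#' @export
setGeneric("poolDepth", function(x, pool) standardGeneric("poolDepth"))

#' @rdname SiteEvidence-class
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @rdname SiteEvidence-class
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' @rdname PoolDiscovery-class
#' @param x a `PoolDiscovery` object.
#' @export
setGeneric("imbalanceRecords", function(x) standardGeneric("imbalanceRecords"))

#' @rdname PoolDiscovery-class
#' @export
setGeneric("paralogRecords", function(x) standardGeneric("paralogRecords"))

#' @rdname PoolDiscovery-class
#' @export
setGeneric("funnelReport", function(x) standardGeneric("funnelReport"))

#' @rdname GenotypeMatrix-class
#' @param x a `GenotypeMatrix` object.
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname SimTruth-class
#' @param x a `SimTruth` object.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
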