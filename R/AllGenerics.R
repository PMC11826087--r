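#' @rdname PoolCounts-accessors
#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))

#' @rdname PoolCounts-accessors
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))

#' @rdname PoolCounts-accessors
#' @export
setGeneric("poolDepth", function(x) standardGeneric("poolDepth"))

#' @rdname PoolCounts-accessors
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))

#' @rdname PoolCounts-accessors
#' @export
setGeneric("poolPanel", function(x) standardGeneric("poolPanel"))

#' @rdname PoolCounts-accessors
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname PoolCounts-accessors
#' @export
setGeneric("haploidSizes", function(x) standardGeneric("haploidSizes"))

#' @rdname filterSnps
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname PoolDist-accessors
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))

#' @rdname PoolDist-accessors
#' @export
setGeneric("distKind", function(x) standardGeneric("distKind"))
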