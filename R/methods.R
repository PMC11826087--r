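#' Accessors for PoolCounts objects
#'
#' `refCounts()` / `altCounts()` return the loci x pools read-count matrices
#' (`NA` = missing observation).  `poolDepth()` is their element-wise sum.
#' `isMissing()` is the logical missingness mask.  `poolPanel()` returns the
#' pool metadata as a data.frame, `lociInfo()` the locus table (contig,
#' position, alleles, indel flag, allele number), and `haploidSizes()` the
#' named vector of haploid pool sizes (2 x maternal plants).
#'
#' @param x a [PoolCounts-class] object.
#' @return matrices, data.frames or named vectors as described.
#' @name PoolCounts-accessors
NULL

#' @rdname PoolCounts-accessors
#' @export
setMethod("refCounts", "PoolCounts", function(x) assay(x, "ref"))

#' @rdname PoolCounts-accessors
#' @export
setMethod("altCounts", "PoolCounts", function(x) assay(x, "alt"))

#' @rdname PoolCounts-accessors
#' @export
setMethod("poolDepth", "PoolCounts",
          function(x) assay(x, "ref") + assay(x, "alt"))

#' @rdname PoolCounts-accessors
#' @export
setMethod("isMissing", "PoolCounts", function(x) is.na(assay(x, "ref")))

#' @rdname PoolCounts-accessors
#' @export
setMethod("poolPanel", "PoolCounts",
          function(x) as.data.frame(colData(x)))

#' @rdname PoolCounts-accessors
#' @export
setMethod("lociInfo", "PoolCounts", function(x) {
  gr <- rowRanges(x)
  data.frame(contig = as.character(seqnames(gr)),
             position = start(gr),
             as.data.frame(mcols(gr)),
             row.names = NULL)
})

#' @rdname PoolCounts-accessors
#' @export
setMethod("haploidSizes", "PoolCounts", function(x) {
  cd <- colData(x)
  stats::setNames(as.integer(cd$haploid_size), cd$pool_id)
})

setMethod("show", "PoolCounts", function(object) {
  cd <- colData(object)
  cat("PoolCounts: ", nrow(object), " loci x ", ncol(object), " pools\n",
      sep = "")
  cat("  origins: ",
      paste(sprintf("%s (%d)", names(table(cd$origin)), table(cd$origin)),
            collapse = ", "), "\n", sep = "")
  nm <- sum(is.na(assay(object, "ref")))
  cat("  missing observations: ", nm, " (",
      sprintf("%.1f%%", 100 * nm / max(1, length(assay(object, "ref")))),
      ")\n", sep = "")
  rep <- metadata(object)$filter_report
  if (!is.null(rep)) cat("  filtered: yes (see filterReport())\n")
})

#' Accessors for PoolDist objects
#'
#' `distValues()` returns the labelled symmetric matrix, `distKind()` its kind
#' (`"fst"` or `"geographic_km"`), and `labels()` the pool labels.
#'
#' @param x,object a [PoolDist-class] object.
#' @param ... ignored.
#' @return matrix, character scalar, or character vector of labels.
#' @name PoolDist-accessors
NULL

#' @rdname PoolDist-accessors
#' @export
setMethod("distValues", "PoolDist", function(x) x@values)

#' @rdname PoolDist-accessors
#' @export
setMethod("distKind", "PoolDist", function(x) x@kind)

#' @rdname PoolDist-accessors
#' @export
setMethod("labels", "PoolDist", function(object, ...) rownames(object@values))

setMethod("show", "PoolDist", function(object) {
  cat("PoolDist (", object@kind, "): ", nrow(object@values), " pools\n",
      sep = "")
  off <- object@values[lower.tri(object@values)]
  if (length(off))
    cat(sprintf("  off-diagonal range: [%.4g, %.4g], mean %.4g\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE),
                mean(off, na.rm = TRUE)))
})

#' Lower-triangle entries of a PoolDist
#'
#' Utility used by the Mantel test and by summaries: the values below the
#' diagonal, in column-major order.
#'
#' @param x a [PoolDist-class] object.
#' @return numeric vector of length `n * (n - 1) / 2`.
#' @export
lowerTriangle <- function(x) {
  v <- distValues(x)
  v[lower.tri(v)]
}
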