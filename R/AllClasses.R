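#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowRanges colData
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

#' PoolCounts: pooled-sequencing read counts for a panel of population pools
#'
#' `PoolCounts` extends [SummarizedExperiment::RangedSummarizedExperiment] and
#' holds, for each biallelic (or multi-allelic, pre-filter) SNP locus and each
#' population pool, the number of sequencing reads carrying the reference and
#' the alternative allele.  Rows are loci (a locus is keyed by contig +
#' 1-based position, VCF convention); columns are pools.  Two assays are
#' mandatory:
#'
#' * `ref` — reads supporting the reference allele,
#' * `alt` — reads supporting the (first) alternative allele.
#'
#' A missing observation (no genotype-depth information for that pool at that
#' locus) is encoded as `NA` in both assays, which keeps it distinct from a
#' genuine zero-depth observation `(0, 0)`.
#'
#' Row metadata carries `ref`, `alt` (allele strings), `is_indel` and
#' `n_alleles`; column metadata is the pool panel: `pool_id`, `origin`
#' (`"native"` or `"invasive"`), `latitude`, `longitude`, `n_maternal`
#' (maternal plants contributing to the pool) and `haploid_size`
#' (`2 * n_maternal`, the number of gene copies in the pool).
#'
#' @name PoolCounts-class
#' @aliases PoolCounts-class
#' @exportClass PoolCounts
setClass("PoolCounts", contains = "RangedSummarizedExperiment")

.validPoolCounts <- function(object) {
  msg <- character()
  if (!all(c("ref", "alt") %in% assayNames(object)))
    msg <- c(msg, "assays 'ref' and 'alt' are required")
  else {
    r <- assay(object, "ref"); a <- assay(object, "alt")
    if (any(r < 0, na.rm = TRUE) || any(a < 0, na.rm = TRUE))
      msg <- c(msg, "read counts must be non-negative")
    if (!identical(is.na(r), is.na(a)))
      msg <- c(msg, "missingness must agree between 'ref' and 'alt' assays")
  }
  cd <- colData(object)
  need <- c("pool_id", "origin", "n_maternal", "haploid_size")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(cd$pool_id)) msg <- c(msg, "pool_ids must be unique")
    if (any(is.na(cd$origin)) || any(!nzchar(as.character(cd$origin))))
      msg <- c(msg, "origin must be non-empty")
    if (any(cd$n_maternal < 1)) msg <- c(msg, "n_maternal must be >= 1")
  }
  rd <- mcols(rowRanges(object))
  if (!all(c("ref", "alt", "is_indel", "n_alleles") %in% colnames(rd)))
    msg <- c(msg, "row metadata must contain ref, alt, is_indel, n_alleles")
  if (length(msg)) msg else TRUE
}
setValidity("PoolCounts", .validPoolCounts)

#' Construct a PoolCounts object
#'
#' @param ref,alt integer matrices (loci x pools) of reference / alternative
#'   read counts. `NA` (in both) marks a missing observation.
#' @param loci data.frame with columns `contig`, `position` (1-based), `ref`,
#'   `alt`; optionally `is_indel` and `n_alleles` (defaults: inferred from
#'   allele lengths, and 2).
#' @param panel pool panel data.frame with columns `pool_id`, `origin`, and
#'   `n_maternal` (and optionally `latitude`, `longitude`, `haploid_size`).
#'   Column order of `ref`/`alt` must follow `panel$pool_id`.
#' @param metadata optional list stored in the object metadata.
#' @return A [PoolCounts-class] object.
#' @examples
#' loci <- data.frame(contig = c("c1", "c2"), position = c(10L, 5L),
#'                    ref = "A", alt = "T")
#' panel <- data.frame(pool_id = c("p1", "p2"), origin = "native",
#'                     n_maternal = 20L)
#' pc <- PoolCounts(ref = matrix(10L, 2, 2), alt = matrix(5L, 2, 2),
#'                  loci = loci, panel = panel)
#' pc
#' @export
PoolCounts <- function(ref, alt, loci, panel, metadata = list()) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  stopifnot(identical(dim(ref), dim(alt)))
  panel <- validatePanel(panel)
  if (nrow(ref) != nrow(loci))
    stop("count matrix rows (", nrow(ref), ") != loci (", nrow(loci), ")")
  if (ncol(ref) != nrow(panel))
    stop("count matrix columns (", ncol(ref), ") != panel pools (",
         nrow(panel), ")")
  if (is.null(loci$is_indel))
    loci$is_indel <- nchar(as.character(loci$ref)) != 1L |
      nchar(as.character(loci$alt)) != 1L
  if (is.null(loci$n_alleles)) loci$n_alleles <- 2L
  gr <- GRanges(seqnames = as.character(loci$contig),
                ranges = IRanges(start = as.integer(loci$position), width = 1L))
  mcols(gr) <- DataFrame(ref = as.character(loci$ref),
                         alt = as.character(loci$alt),
                         is_indel = as.logical(loci$is_indel),
                         n_alleles = as.integer(loci$n_alleles))
  rn <- if (nrow(loci)) paste0(loci$contig, ":", loci$position)
        else character(0)
  dimnames(ref) <- dimnames(alt) <- list(rn, panel$pool_id)
  se <- SummarizedExperiment(
    assays = list(ref = ref, alt = alt),
    rowRanges = gr,
    colData = DataFrame(panel, row.names = panel$pool_id),
    metadata = metadata)
  new("PoolCounts", se)
}

#' Validate a pool panel table
#'
#' Checks the pool metadata table (unique `pool_id`, non-empty `origin`,
#' `n_maternal >= 1`) and fills `haploid_size = 2 * n_maternal` when absent.
#'
#' @param panel data.frame of pool metadata.
#' @return The validated (possibly augmented) data.frame.
#' @export
validatePanel <- function(panel) {
  panel <- as.data.frame(panel)
  need <- c("pool_id", "origin", "n_maternal")
  miss <- setdiff(need, colnames(panel))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "))
  panel$pool_id <- as.character(panel$pool_id)
  if (anyDuplicated(panel$pool_id))
    stop("duplicate pool_ids: ",
         paste(unique(panel$pool_id[duplicated(panel$pool_id)]),
               collapse = ", "))
  if (any(is.na(panel$origin)) || any(!nzchar(as.character(panel$origin))))
    stop("panel origin must be non-empty for every pool")
  panel$n_maternal <- as.integer(panel$n_maternal)
  if (any(is.na(panel$n_maternal)) || any(panel$n_maternal < 1))
    stop("n_maternal must be an integer >= 1")
  if (is.null(panel$haploid_size))
    panel$haploid_size <- 2L * panel$n_maternal
  panel
}

#' PoolDist: a labelled symmetric distance matrix over pools
#'
#' Holds either a pairwise-FST matrix (`kind = "fst"`) or a great-circle
#' geographic distance matrix in kilometres (`kind = "geographic_km"`).
#' The matrix is symmetric with a zero diagonal and labelled by pool id.
#' FST entries typically fall in \[-0.05, 1\]; small negative values are the
#' usual behaviour of unbiased estimators and are retained, not truncated.
#'
#' @name PoolDist-class
#' @aliases PoolDist-class
#' @exportClass PoolDist
setClass("PoolDist",
         representation(values = "matrix", kind = "character"))

.validPoolDist <- function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column labels must be present and identical")
  else if (anyDuplicated(rownames(v)))
    msg <- c(msg, "labels must be unique")
  fin <- v[is.finite(v)]
  if (length(fin) && max(abs(v - t(v)), na.rm = TRUE) > 1e-12)
    msg <- c(msg, "matrix must be symmetric (tolerance 1e-12)")
  if (any(abs(diag(v)) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "diagonal must be zero")
  if (!object@kind %in% c("fst", "geographic_km"))
    msg <- c(msg, "kind must be 'fst' or 'geographic_km'")
  if (object@kind == "fst" && length(fin) && max(fin) > 1 + 1e-9)
    msg <- c(msg, "FST values must not exceed 1")
  if (object@kind == "geographic_km" && length(fin) && min(fin) < 0)
    msg <- c(msg, "geographic distances must be non-negative")
  if (length(msg)) msg else TRUE
}
setValidity("PoolDist", .validPoolDist)

#' Construct a PoolDist object
#'
#' @param values square symmetric matrix with identical row/column labels and
#'   zero diagonal.
#' @param kind `"fst"` or `"geographic_km"`.
#' @return A [PoolDist-class] object.
#' @export
PoolDist <- function(values, kind = c("fst", "geographic_km")) {
  kind <- match.arg(kind)
  new("PoolDist", values = as.matrix(values), kind = kind)
}

#' FilterConfig: thresholds of a tiered SNP filter
#'
#' Bundles the locus- and pool-level thresholds applied by [filterSnps()].
#' Two stock tiers are provided: [preliminaryFilter()] (missingness < 66%,
#' minor allele count 3, read depth 20, pools dropped above 75% missing, one
#' SNP per contig) and [finalFilter()] (missingness < 50%, read depth 40).
#'
#' @name FilterConfig-class
#' @aliases FilterConfig-class
#' @exportClass FilterConfig
setClass("FilterConfig",
         representation(keep_biallelic_only = "logical",
                        drop_indels = "logical",
                        max_missing_fraction = "numeric",
                        min_minor_allele_count = "integer",
                        min_read_depth = "integer",
                        max_pool_missing_fraction = "numeric",
                        one_snp_per_contig = "logical"))

setValidity("FilterConfig", function(object) {
  msg <- character()
  for (s in c("max_missing_fraction", "max_pool_missing_fraction")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste(s, "must be a fraction in [0, 1]"))
  }
  for (s in c("min_minor_allele_count", "min_read_depth")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0)
      msg <- c(msg, paste(s, "must be an integer >= 0"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FilterConfig-class general constructor.
#' @param keep_biallelic_only,drop_indels,one_snp_per_contig logical flags.
#' @param max_missing_fraction drop a locus if its fraction of missing pools is
#'   `>=` this value (strict "less than" retention, see [filterSnps()]).
#' @param min_minor_allele_count minimum total read count of the rarer allele,
#'   summed across pools.
#' @param min_read_depth per-pool observations below this total depth are
#'   converted to missing.
#' @param max_pool_missing_fraction drop a pool if its missing fraction is
#'   strictly greater than this value.
#' @export
filterConfig <- function(keep_biallelic_only = TRUE, drop_indels = TRUE,
                         max_missing_fraction = 0.66,
                         min_minor_allele_count = 3L, min_read_depth = 20L,
                         max_pool_missing_fraction = 0.75,
                         one_snp_per_contig = TRUE) {
  new("FilterConfig",
      keep_biallelic_only = keep_biallelic_only, drop_indels = drop_indels,
      max_missing_fraction = max_missing_fraction,
      min_minor_allele_count = as.integer(min_minor_allele_count),
      min_read_depth = as.integer(min_read_depth),
      max_pool_missing_fraction = max_pool_missing_fraction,
      one_snp_per_contig = one_snp_per_contig)
}

#' @describeIn FilterConfig-class the preliminary tier (depth 20, missingness
#'   66%) used when designing mixtures.
#' @export
preliminaryFilter <- function() filterConfig()

#' @describeIn FilterConfig-class the final tier (depth 40, missingness 50%)
#'   used for the statistics reported on the finished experiment.
#' @export
finalFilter <- function()
  filterConfig(max_missing_fraction = 0.50, min_read_depth = 40L)
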