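#' Read pooled SNP data from a VCF file
#'
#' Loads per-pool allelic read depths (the `AD` genotype field) from a VCF
#' (v4.x) into a [PoolCounts-class] object.  One record is kept per VCF site;
#' multi-allelic sites are retained with their allele number recorded in
#' `n_alleles` so that [filterSnps()] can remove them later.  Sites whose
#' `AD` field is absent for a pool (e.g. a `./.` genotype) become missing
#' observations, distinct from a true zero-depth `(0, 0)`.
#'
#' Only the pools listed in `panel` are loaded, in panel order; the VCF
#' samples may be a superset of the panel.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param panel pool panel data.frame (see [validatePanel()]); `pool_id`
#'   values must match VCF sample names.
#' @return A [PoolCounts-class] object.
#' @examples
#' \dontrun{pc <- readPoolVcf("pools.vcf", panel)}
#' @export
readPoolVcf <- function(path, panel) {
  panel <- validatePanel(panel)
  vcf <- VariantAnnotation::readVcf(path)
  samp <- colnames(vcf)
  unmatched <- setdiff(panel$pool_id, samp)
  if (length(unmatched))
    stop("panel pools absent from VCF samples: ",
         paste(unmatched, collapse = ", "))
  vcf <- vcf[, panel$pool_id]
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad))
    stop("VCF has no per-sample allelic depth (AD) field")
  getA <- function(idx) {
    out <- vapply(ad, function(v) {
      if (length(v) < idx || is.na(v[idx])) NA_integer_ else as.integer(v[idx])
    }, integer(1))
    matrix(out, nrow = nrow(vcf), ncol = ncol(vcf))
  }
  ref <- getA(1L); alt <- getA(2L)
  miss <- is.na(ref) | is.na(alt)
  ref[miss] <- NA_integer_; alt[miss] <- NA_integer_
  rr <- SummarizedExperiment::rowRanges(vcf)
  refal <- as.character(VariantAnnotation::ref(vcf))
  altlist <- VariantAnnotation::alt(vcf)
  n_alleles <- 1L + lengths(altlist)
  alt1 <- vapply(seq_along(altlist), function(i) {
    a <- as.character(altlist[[i]])
    if (length(a)) a[1] else ""
  }, character(1))
  is_indel <- nchar(refal) != 1L |
    vapply(seq_along(altlist), function(i) {
      a <- as.character(altlist[[i]])
      length(a) > 0 && any(nchar(a) != 1L)
    }, logical(1))
  loci <- data.frame(contig = as.character(seqnames(rr)),
                     position = start(rr),
                     ref = refal, alt = alt1,
                     is_indel = is_indel, n_alleles = n_alleles)
  PoolCounts(ref = ref, alt = alt, loci = loci, panel = panel,
             metadata = list(source = path))
}

#' Read and write plain-text read-count tables
#'
#' The tabular interchange format: columns `contig`, `position`, `ref`,
#' `alt`, `is_indel`, `n_alleles`, then one `<pool>_ref` / `<pool>_alt`
#' column pair per pool.  Missing observations are empty/NA fields.
#' `writeCountTable()` followed by `readCountTable()` reproduces the object's
#' counts and locus table exactly.
#'
#' @param path file path; tab-separated if it ends in `.tsv`, otherwise
#'   comma-separated.
#' @param panel pool panel data.frame; pools must match the column pairs
#'   present in the file.
#' @return `readCountTable()` returns a [PoolCounts-class];
#'   `writeCountTable()` returns `path` invisibly.
#' @export
readCountTable <- function(path, panel) {
  panel <- validatePanel(panel)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = c(contig = "character",
                                          ref = "character",
                                          alt = "character"))
  fixed <- c("contig", "position", "ref", "alt", "is_indel", "n_alleles")
  miss <- setdiff(fixed[1:4], colnames(tab))
  if (length(miss))
    stop("count table is missing columns: ", paste(miss, collapse = ", "))
  rc <- paste0(panel$pool_id, "_ref"); ac <- paste0(panel$pool_id, "_alt")
  absent <- setdiff(c(rc, ac), colnames(tab))
  if (length(absent))
    stop("count table lacks pool columns: ", paste(absent, collapse = ", "))
  ref <- as.matrix(tab[, rc, drop = FALSE])
  alt <- as.matrix(tab[, ac, drop = FALSE])
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  loci <- tab[, intersect(fixed, colnames(tab)), drop = FALSE]
  PoolCounts(ref = ref, alt = alt, loci = loci, panel = panel,
             metadata = list(source = path))
}

#' @rdname readCountTable
#' @param x a [PoolCounts-class] object.
#' @export
writeCountTable <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  li <- lociInfo(x)
  ref <- refCounts(x); alt <- altCounts(x)
  colnames(ref) <- paste0(colnames(ref), "_ref")
  colnames(alt) <- paste0(colnames(alt), "_alt")
  ord <- as.vector(rbind(seq_len(ncol(ref)), ncol(ref) + seq_len(ncol(alt))))
  tab <- cbind(li, cbind(ref, alt)[, ord, drop = FALSE])
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pool panel CSV
#'
#' Expected columns: `pool_id`, `origin` (native/invasive), `latitude`,
#' `longitude` (decimal degrees), `n_maternal`.  `haploid_size` is derived as
#' `2 * n_maternal` when not supplied.
#'
#' @param path CSV file path.
#' @return validated panel data.frame.
#' @export
readPoolPanel <- function(path) {
  validatePanel(utils::read.csv(path, stringsAsFactors = FALSE))
}
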