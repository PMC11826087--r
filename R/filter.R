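#' Apply a tiered SNP filter to pooled read counts
#'
#' Implements the two-tier filtering scheme used for pool-seq SNP panels:
#' indels and non-biallelic sites are removed; observations below the
#' per-pool read-depth threshold are converted to missing; loci failing the
#' missingness rule (retain only loci whose missing fraction is strictly
#' *less than* `max_missing_fraction`) or the minor-allele-count rule
#' (total read count of the rarer allele, summed across pools, at least
#' `min_minor_allele_count`) are dropped; pools with a missing fraction
#' strictly *greater than* `max_pool_missing_fraction` are dropped; finally
#' only one SNP per contig is retained (the first by position).
#'
#' Because dropping pools changes locus missing fractions (and vice versa),
#' the locus- and pool-level rules are iterated to a fixed point, and the
#' contig thinning is followed by a second fixed-point pass.  The result is
#' idempotent: filtering an already-filtered object with the same
#' configuration changes nothing.  The minor allele count is evaluated on
#' summed read counts across pools — pooled sequencing has no genotype-level
#' allele counts — after depth masking.
#'
#' @param x a [PoolCounts-class] object.
#' @param cfg a [FilterConfig-class]; defaults to the preliminary tier.
#' @return A filtered [PoolCounts-class].  The per-step removal tally is
#'   stored in the metadata and retrieved with `filterReport()`: a data.frame
#'   with columns `step`, `loci_removed`, `pools_removed`, `obs_masked`.
#'   Step counts of `loci_removed` sum to (input - output) loci.
#' @examples
#' pc <- simulatePools(poolSimConfig(n_pops = 4, n_loci = 50, seed = 1))
#' pf <- filterSnps(pc, preliminaryFilter())
#' filterReport(pf)
#' @export
filterSnps <- function(x, cfg = preliminaryFilter()) {
  stopifnot(is(x, "PoolCounts"), is(cfg, "FilterConfig"))
  validObject(cfg)
  li <- lociInfo(x)
  ref <- refCounts(x); alt <- altCounts(x)
  panel <- poolPanel(x)

  # sort by contig then position (locus key is contig + 1-based position)
  ord <- order(li$contig, li$position)
  li <- li[ord, , drop = FALSE]
  ref <- ref[ord, , drop = FALSE]; alt <- alt[ord, , drop = FALSE]

  steps <- c("indels", "non_biallelic", "low_depth_mask",
             "locus_missingness", "minor_allele_count", "pool_missingness",
             "one_snp_per_contig")
  rep <- data.frame(step = steps, loci_removed = 0L, pools_removed = 0L,
                    obs_masked = 0L)
  tally <- function(step, loci = 0L, pools = 0L, obs = 0L) {
    i <- match(step, rep$step)
    rep$loci_removed[i] <<- rep$loci_removed[i] + as.integer(loci)
    rep$pools_removed[i] <<- rep$pools_removed[i] + as.integer(pools)
    rep$obs_masked[i] <<- rep$obs_masked[i] + as.integer(obs)
  }
  dropLoci <- function(keep, step) {
    tally(step, loci = sum(!keep))
    li <<- li[keep, , drop = FALSE]
    ref <<- ref[keep, , drop = FALSE]; alt <<- alt[keep, , drop = FALSE]
  }

  if (cfg@drop_indels && nrow(li))
    dropLoci(!li$is_indel, "indels")
  if (cfg@keep_biallelic_only && nrow(li))
    dropLoci(li$n_alleles == 2L, "non_biallelic")

  if (nrow(li)) {
    depth <- ref + alt
    mask <- !is.na(depth) & depth < cfg@min_read_depth
    tally("low_depth_mask", obs = sum(mask))
    ref[mask] <- NA_integer_; alt[mask] <- NA_integer_
  }

  locusPoolPass <- function() {
    repeat {
      changed <- FALSE
      if (nrow(li) && nrow(panel)) {
        mf <- rowMeans(is.na(ref))
        keep <- mf < cfg@max_missing_fraction
        if (any(!keep)) { dropLoci(keep, "locus_missingness"); changed <- TRUE }
      }
      if (nrow(li) && nrow(panel)) {
        tr <- rowSums(ref, na.rm = TRUE); ta <- rowSums(alt, na.rm = TRUE)
        keep <- pmin(tr, ta) >= cfg@min_minor_allele_count
        if (any(!keep)) {
          dropLoci(keep, "minor_allele_count"); changed <- TRUE
        }
      }
      if (nrow(li) && nrow(panel)) {
        pmf <- colMeans(is.na(ref))
        keepP <- pmf <= cfg@max_pool_missing_fraction
        if (any(!keepP)) {
          tally("pool_missingness", pools = sum(!keepP))
          panel <<- panel[keepP, , drop = FALSE]
          ref <<- ref[, keepP, drop = FALSE]
          alt <<- alt[, keepP, drop = FALSE]
          changed <- TRUE
        }
      }
      if (!changed || !nrow(li) || !nrow(panel)) break
    }
  }

  locusPoolPass()
  if (cfg@one_snp_per_contig && nrow(li)) {
    dropLoci(!duplicated(li$contig), "one_snp_per_contig")
    locusPoolPass()
  }

  out <- PoolCounts(ref = ref, alt = alt, loci = li, panel = panel,
                    metadata = c(metadata(x)[setdiff(names(metadata(x)),
                                                     "filter_report")],
                                 list(filter_report = rep,
                                      filter_config = cfg)))
  out
}

#' @rdname filterSnps
#' @export
setMethod("filterReport", "PoolCounts",
          function(x) metadata(x)$filter_report)

#' Write a filter report as TSV
#'
#' @param x a filtered [PoolCounts-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFilterReport <- function(x, path) {
  rep <- filterReport(x)
  if (is.null(rep)) stop("object carries no filter report")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
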