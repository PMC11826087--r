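#' Allele frequency from pooled read counts
#'
#' The reference-allele frequency of a pool at a locus is the number of reads
#' carrying the reference allele divided by the total read count.  Vectorised;
#' zero total depth yields `NA` (a missing value, never a division error).
#'
#' @param ref_count,total_count non-negative integer vectors.
#' @return numeric vector of frequencies in \[0, 1\] (`NA` where
#'   `total_count == 0` or inputs are missing).
#' @examples
#' alleleFrequency(13, 52)   # 0.25
#' @export
alleleFrequency <- function(ref_count, total_count) {
  p <- ifelse(is.na(total_count) | total_count == 0, NA_real_,
              ref_count / total_count)
  as.numeric(p)
}

#' Unbiased expected heterozygosity at one locus
#'
#' Nei & Roychoudhury's small-sample-corrected gene diversity computed on
#' pooled read counts: with `c = ref + alt` reads and reference frequency
#' `p = ref / c`,
#' \deqn{H_e = \frac{c}{c - 1}\,(1 - p^2 - q^2), \qquad q = 1 - p.}
#' The read count `c` plays the role of the sample size in the bias
#' correction: read counts are the only per-pool sample-size quantity a
#' pooled library provides.  An alternative correction based on the haploid
#' pool size `n` (factor `n / (n - 1)`) is available via `size`.
#' Vectorised; fewer than 2 reads yields `NA`.
#'
#' @param ref_count,alt_count non-negative integer vectors of reads per
#'   allele.
#' @param size optional haploid pool size(s); when given, the bias-correction
#'   factor is `size / (size - 1)` instead of `c / (c - 1)`.
#' @return numeric vector of per-locus heterozygosities in \[0, 1\].
#' @examples
#' heLocus(20, 20)            # (40/39) * 0.5
#' heLocus(40, 0)             # 0, monomorphic
#' @export
heLocus <- function(ref_count, alt_count, size = NULL) {
  cc <- ref_count + alt_count
  p <- ref_count / cc
  raw <- 1 - p^2 - (1 - p)^2
  fac <- if (is.null(size)) cc / (cc - 1) else size / (size - 1)
  he <- ifelse(is.na(cc) | cc < 2, NA_real_, fac * raw)
  as.numeric(he)
}

#' Per-pool expected heterozygosity averaged across loci
#'
#' Computes [heLocus()] at every locus with a non-missing observation for the
#' pool and returns the mean across those loci.  Loci that are monomorphic
#' after filtering contribute 0 by default; `drop_monomorphic = TRUE`
#' excludes them from the average.
#'
#' @param x a [PoolCounts-class] object.
#' @param pool_id pool identifier (must be a column of `x`).
#' @param size optional haploid size passed to [heLocus()].
#' @param drop_monomorphic exclude loci where the pool shows only one allele.
#' @return list with `He` (the mean) and `n_loci` (loci that entered it).
#' @export
poolHe <- function(x, pool_id, size = NULL, drop_monomorphic = FALSE) {
  if (!pool_id %in% colnames(x))
    stop("unknown pool: ", pool_id)
  r <- refCounts(x)[, pool_id]; a <- altCounts(x)[, pool_id]
  he <- heLocus(r, a, size = size)
  if (drop_monomorphic) he[!is.na(he) & he == 0] <- NA_real_
  list(He = mean(he, na.rm = TRUE), n_loci = sum(!is.na(he)))
}

#' Per-pool heterozygosity table
#'
#' Convenience wrapper running [poolHe()] for every pool.
#'
#' @inheritParams poolHe
#' @return data.frame with columns `pool_id`, `origin`, `He`, `n_loci`.
#' @export
poolHeTable <- function(x, size = NULL, drop_monomorphic = FALSE) {
  panel <- poolPanel(x)
  res <- lapply(panel$pool_id, poolHe, x = x, size = size,
                drop_monomorphic = drop_monomorphic)
  data.frame(pool_id = panel$pool_id, origin = panel$origin,
             He = vapply(res, `[[`, numeric(1), "He"),
             n_loci = vapply(res, `[[`, numeric(1), "n_loci"),
             row.names = NULL)
}

#' Total gene diversity of a set of pools
#'
#' H_T is obtained by summing the reference and alternative read counts
#' element-wise across the listed pools (missing observations contribute
#' nothing) and applying the per-locus unbiased heterozygosity to the summed
#' column, averaged across loci.  With a single pool this reduces to that
#' pool's He.
#'
#' @param x a [PoolCounts-class] object.
#' @param pool_ids character vector of pools to pool together (default: all).
#' @return H_T value in \[0, 1\]; `NA` (with a warning) when no locus reaches
#'   a summed depth of 2.
#' @export
totalHe <- function(x, pool_ids = colnames(x)) {
  if (length(pool_ids) < 1) stop("at least one pool required")
  bad <- setdiff(pool_ids, colnames(x))
  if (length(bad))
    stop("pools absent from counts table: ", paste(bad, collapse = ", "))
  r <- rowSums(refCounts(x)[, pool_ids, drop = FALSE], na.rm = TRUE)
  a <- rowSums(altCounts(x)[, pool_ids, drop = FALSE], na.rm = TRUE)
  he <- heLocus(r, a)
  if (all(is.na(he))) {
    warning("no locus with summed depth >= 2")
    return(NA_real_)
  }
  mean(he, na.rm = TRUE)
}

# Unbiased probabilities of identity from one pool's read counts.
# D = P(two distinct reads identical); E[D] = 1/n + (1 - 1/n) Q1 for a pool
# of n haploid genomes, so Q1-hat = (n D - 1) / (n - 1).
.q1hat <- function(r, a, n) {
  cc <- r + a
  d <- (r * (r - 1) + a * (a - 1)) / (cc * (cc - 1))
  (n * d - 1) / (n - 1)
}

#' Pairwise FST between two pools from read counts
#'
#' An analysis-of-variance (identity-probability) estimator for pooled
#' sequencing data.  For each locus, unbiased estimates of the within-pool
#' identity Q1 (corrected for reads re-sampling the same gene copy among the
#' `n` haploid genomes of a pool) and the between-pool identity Q2 are formed
#' from read counts; the multilocus estimate is the ratio of sums
#' \deqn{\hat F_{ST} = \frac{\sum_l (\bar Q_{1,l} - \hat Q_{2,l})}
#'                          {\sum_l (1 - \hat Q_{2,l})}.}
#' Loci need a read depth of at least 2 in both pools.  Negative estimates
#' are retained (unbiased-estimator convention).
#'
#' @param x a [PoolCounts-class] object.
#' @param pool_a,pool_b pool identifiers.
#' @param haploid_sizes named vector of haploid pool sizes; defaults to the
#'   panel's `haploid_size` column.
#' @return FST estimate; `NA` with a warning when no informative locus is
#'   shared.
#' @examples
#' pc <- simulatePools(poolSimConfig(n_pops = 2, n_loci = 500,
#'                                   true_F = 0.05, seed = 7))
#' pairwiseFst(pc, "pool01", "pool02")
#' @export
pairwiseFst <- function(x, pool_a, pool_b, haploid_sizes = haploidSizes(x)) {
  for (p in c(pool_a, pool_b))
    if (!p %in% colnames(x)) stop("unknown pool: ", p)
  ra <- refCounts(x)[, pool_a]; aa <- altCounts(x)[, pool_a]
  rb <- refCounts(x)[, pool_b]; ab <- altCounts(x)[, pool_b]
  ca <- ra + aa; cb <- rb + ab
  ok <- !is.na(ca) & !is.na(cb) & ca >= 2 & cb >= 2
  if (!any(ok)) {
    warning("no shared informative loci between ", pool_a, " and ", pool_b)
    return(NA_real_)
  }
  na <- haploid_sizes[[pool_a]]; nb <- haploid_sizes[[pool_b]]
  q1 <- (.q1hat(ra[ok], aa[ok], na) + .q1hat(rb[ok], ab[ok], nb)) / 2
  q2 <- (ra[ok] * rb[ok] + aa[ok] * ab[ok]) / (ca[ok] * cb[ok])
  sum(q1 - q2) / sum(1 - q2)
}

#' Pairwise FST matrix across a panel
#'
#' Computes [pairwiseFst()] for every pool pair.  With `by_origin = TRUE`
#' only within-origin pairs are computed (cross-origin cells are `NA`),
#' matching the convention of reporting differentiation separately per range.
#'
#' @param x a [PoolCounts-class] object.
#' @param by_origin restrict to within-origin pairs.
#' @return A [PoolDist-class] of kind `"fst"`.
#' @export
fstMatrix <- function(x, by_origin = FALSE) {
  panel <- poolPanel(x)
  ids <- panel$pool_id
  n <- length(ids)
  v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(v) <- 0
  hs <- haploidSizes(x)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (by_origin && panel$origin[i] != panel$origin[j]) next
    f <- pairwiseFst(x, ids[i], ids[j], hs)
    v[i, j] <- v[j, i] <- f
  }
  PoolDist(v, kind = "fst")
}

#' Welch's two-sample t test (unequal variances)
#'
#' Thin wrapper around [stats::t.test()] returning the Welch statistic,
#' Satterthwaite degrees of freedom and two-sided p value.  Used to compare
#' pairwise-FST distributions between the native and invasive range (the
#' pairwise values are treated as independent observations — a simplification
#' shared with the study design this mirrors).
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welchTTest <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Mantel test for matrix association (isolation by distance)
#'
#' Pearson correlation `r` between the lower triangles of two labelled
#' distance matrices, with a one-sided (positive association) permutation
#' p value: rows and columns of `m2` are permuted jointly `n_perm` times and
#' \deqn{p = \frac{1 + \#\{r_{perm} \ge r_{obs}\}}{n_{perm} + 1}.}
#' Deterministic given `seed`.
#'
#' @param m1,m2 [PoolDist-class] objects with identical labels in identical
#'   order (e.g. FST vs. geographic distance).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantelTest <- function(m1, m2, n_perm = 999L, seed = 1L) {
  if (!identical(labels(m1), labels(m2)))
    stop("distance matrices must share labels in identical order")
  if (n_perm < 1) stop("n_perm must be >= 1")
  v1 <- distValues(m1); v2 <- distValues(m2)
  lt <- lower.tri(v1)
  x <- v1[lt]; y <- v2[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant distance matrix: Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_, n_perm = as.integer(n_perm)))
  }
  r_obs <- stats::cor(x, y)
  n <- nrow(v1)
  set.seed(seed)
  ge <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_p <- stats::cor(x, v2[idx, idx][lt])
    if (r_p >= r_obs) ge <- ge + 1L
  }
  list(r = r_obs, p = (1 + ge) / (n_perm + 1), n_perm = as.integer(n_perm))
}

#' Great-circle distance matrix of a pool panel
#'
#' Haversine distances in kilometres between pool coordinates, using a mean
#' Earth radius of 6371 km.
#'
#' @param panel pool panel data.frame with `latitude` and `longitude` in
#'   decimal degrees.
#' @return A [PoolDist-class] of kind `"geographic_km"`.
#' @export
geoDistMatrix <- function(panel) {
  panel <- validatePanel(panel)
  if (is.null(panel$latitude) || is.null(panel$longitude))
    stop("panel must provide latitude and longitude")
  m <- geosphere::distm(cbind(panel$longitude, panel$latitude),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(m) <- list(panel$pool_id, panel$pool_id)
  PoolDist(m, kind = "geographic_km")
}
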