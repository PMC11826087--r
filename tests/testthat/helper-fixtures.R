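# Shared fixtures, all built in code at test time.

toyPanel <- function(n = 2L, origin = "native", prefix = "p") {
  data.frame(pool_id = paste0(prefix, seq_len(n)),
             origin = rep_len(origin, n),
             latitude = 50 + seq_len(n) / 10,
             longitude = 8 + seq_len(n) / 10,
             n_maternal = 20L)
}

toyCounts <- function(ref, alt, panel = NULL, contigs = NULL,
                      positions = NULL, is_indel = FALSE, n_alleles = 2L) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (is.null(panel)) panel <- toyPanel(ncol(ref))
  if (is.null(contigs)) contigs <- sprintf("ctg%04d", seq_len(nrow(ref)))
  if (is.null(positions)) positions <- rep(100L, nrow(ref))
  loci <- data.frame(contig = contigs, position = positions,
                     ref = rep_len("A", nrow(ref)),
                     alt = rep_len("T", nrow(ref)),
                     is_indel = rep_len(is_indel, nrow(ref)),
                     n_alleles = rep_len(n_alleles, nrow(ref)))
  PoolCounts(ref = ref, alt = alt, loci = loci, panel = panel)
}

# Minimal VCF with AD genotype fields. `calls` is a character matrix
# (sites x samples) of GT:AD strings, e.g. "0/1:12,8" or "./.:." (missing).
writeToyVcf <- function(path, chrom, pos, ref, alt, calls, samples) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".",
            "GT:AD", calls[i, ]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}

# Two pools sampled independently from the same populations: the
# no-differentiation reference case for the FST estimator.
samePopPools <- function(n_loci = 2000, depth = 100, haploid = 40L,
                         seed = 1) {
  set.seed(seed)
  p <- runif(n_loci, 0.1, 0.9)
  mk <- function() {
    pf <- rbinom(n_loci, haploid, p) / haploid
    d <- rep(depth, n_loci)
    r <- rbinom(n_loci, d, pf)
    cbind(r, d - r)
  }
  a <- mk(); b <- mk()
  toyCounts(ref = cbind(a[, 1], b[, 1]), alt = cbind(a[, 2], b[, 2]))
}

# All permutations of 1..n (for exhaustive Mantel enumeration).
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}

# Exact one-sided Mantel tail probability over all n! joint permutations
# (identity included), mirroring the add-one permutation p convention.
exactMantelP <- function(m1, m2) {
  v1 <- distValues(m1); v2 <- distValues(m2)
  lt <- lower.tri(v1)
  x <- v1[lt]
  r_obs <- cor(x, v2[lt])
  perms <- allPerms(nrow(v1))
  r_all <- apply(perms, 1, function(idx) cor(x, v2[idx, idx][lt]))
  mean(r_all >= r_obs - 1e-12)
}
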