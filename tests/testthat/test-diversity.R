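test_that("allele frequency is ref reads over total reads, NA at zero depth", {
  expect_equal(alleleFrequency(20, 40), 0.5)
  expect_equal(alleleFrequency(0, 40), 0)
  expect_equal(alleleFrequency(13, 52), 0.25)
  expect_true(is.na(alleleFrequency(0, 0)))
  expect_equal(alleleFrequency(c(10, 0), c(20, 0)), c(0.5, NA))
})

test_that("per-locus He matches the closed form over all small read splits", {
  # brute-force oracle: enumerate every ref/alt split with total depth <= 60
  for (cc in 2:60) {
    r <- 0:cc
    p <- r / cc
    expected <- (cc / (cc - 1)) * (1 - p^2 - (1 - p)^2)
    expect_equal(heLocus(r, cc - r), expected)
  }
  expect_equal(heLocus(20, 20), (40 / 39) * 0.5)
  expect_equal(heLocus(40, 0), 0)
  expect_equal(heLocus(1, 1), 1)           # c = 2: (2/1) * 0.5
  expect_true(is.na(heLocus(1, 0)))        # c < 2
  # alternative correction using haploid pool size
  expect_equal(heLocus(20, 20, size = 40), (40 / 39) * 0.5)
  expect_equal(heLocus(30, 30, size = 40), (40 / 39) * 0.5)
})

test_that("pool He is the missing-aware mean across loci", {
  # two loci with He exactly 0.4 and 0.6 -> mean 0.5:
  # (1,4): (5/4)(1 - .2^2 - .8^2) = 0.4; (3,3): (6/5)(1 - 2 * .5^2) = 0.6
  pc <- toyCounts(cbind(c(1L, 3L), c(10L, 10L)),
                  cbind(c(4L, 3L), c(10L, 10L)))
  expect_equal(heLocus(1, 4), 0.4)
  expect_equal(heLocus(3, 3), 0.6)
  res <- poolHe(pc, "p1")
  expect_equal(res$He, 0.5)
  expect_equal(res$n_loci, 2L)
  # one locus missing, one with data -> mean over the observed locus only
  pc2 <- toyCounts(cbind(c(NA, 30L), c(10L, 10L)),
                   cbind(c(NA, 10L), c(10L, 10L)))
  res2 <- poolHe(pc2, "p1")
  expect_equal(res2$n_loci, 1L)
  expect_equal(res2$He, heLocus(30, 10))
  # all loci monomorphic -> 0
  pc3 <- toyCounts(cbind(c(40L, 40L)), cbind(c(0L, 0L)),
                   panel = toyPanel(1))
  expect_equal(poolHe(pc3, "p1")$He, 0)
})

test_that("He is invariant to swapping reference and alternative labels", {
  pc <- simulatePools(poolSimConfig(n_pops = 3, n_loci = 200, seed = 8))
  ref <- refCounts(pc); alt <- altCounts(pc)
  set.seed(1)
  flip <- sample(c(TRUE, FALSE), nrow(ref), replace = TRUE)
  ref2 <- ref; alt2 <- alt
  ref2[flip, ] <- alt[flip, ]; alt2[flip, ] <- ref[flip, ]
  pc2 <- toyCounts(ref2, alt2, panel = toyPanel(3))
  for (i in 1:3)
    expect_equal(poolHe(pc2, paste0("p", i))$He,
                 poolHe(pc, sprintf("pool%02d", i))$He)
})

test_that("H_T pools read counts across samples before the He formula", {
  # two pools each (10 ref, 10 alt) -> summed (20, 20), H_T = (40/39)/2
  pc <- toyCounts(cbind(10L, 10L), cbind(10L, 10L))
  expect_equal(totalHe(pc), (40 / 39) * 0.5)
  # single pool: identity with that pool's He
  pc1 <- simulatePools(poolSimConfig(n_pops = 2, n_loci = 100, seed = 3))
  expect_equal(totalHe(pc1, "pool01"), poolHe(pc1, "pool01")$He)
  # opposite fixation: summed p = 0.5, H_T = (80/79)/2
  pc2 <- toyCounts(cbind(40L, 0L), cbind(0L, 40L))
  expect_equal(totalHe(pc2), (80 / 79) * 0.5)
  expect_error(totalHe(pc2, character()), "at least one")
  expect_warning(ht <- totalHe(toyCounts(cbind(0L, 1L), cbind(0L, 0L))),
                 "summed depth")
  expect_true(is.na(ht))
})

test_that("H_T of identical pools equals each pool's He up to the bias factor", {
  set.seed(6)
  r <- rbinom(150, 60, runif(150, 0.2, 0.8))
  pc <- toyCounts(cbind(r, r, r), cbind(60L - r, 60L - r, 60L - r),
                  panel = toyPanel(3))
  c_min <- 60
  expect_lt(abs(totalHe(pc) - poolHe(pc, "p1")$He), 1 / c_min)
})

test_that("FST is near zero for undifferentiated pools, one for fixed ones", {
  pc0 <- samePopPools(n_loci = 5000, depth = 100, seed = 31)
  expect_lt(abs(pairwiseFst(pc0, "p1", "p2")), 0.01)
  # complete differentiation: opposite fixation at every locus
  L <- 200
  pcd <- toyCounts(cbind(rep(100L, L), rep(0L, L)),
                   cbind(rep(0L, L), rep(100L, L)))
  expect_gt(pairwiseFst(pcd, "p1", "p2"), 0.95)
  # no shared informative loci -> NA with warning
  pcm <- toyCounts(cbind(c(10L, NA), c(NA, 10L)),
                   cbind(c(10L, NA), c(NA, 10L)))
  expect_warning(f <- pairwiseFst(pcm, "p1", "p2"), "informative")
  expect_true(is.na(f))
})

test_that("FST estimator recovers the island-model truth", {
  for (f_true in c(0.05, 0.15)) {
    est <- vapply(1:3, function(s) {
      pc <- simulatePools(poolSimConfig(n_pops = 2, n_loci = 3000,
                                        true_F = f_true, mean_depth = 60,
                                        seed = 400 + s))
      pairwiseFst(pc, "pool01", "pool02")
    }, numeric(1))
    expect_lt(abs(mean(est) - f_true), 0.015)
  }
})

test_that("FST matrix is symmetric, zero-diagonal, and permutation-consistent", {
  pc <- simulatePools(poolSimConfig(n_pops = 4, n_loci = 400, true_F = 0.1,
                                    seed = 9))
  m <- fstMatrix(pc)
  v <- distValues(m)
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(0, 4))
  expect_equal(sum(!is.na(lowerTriangle(m))), choose(4, 2))
  # permuting the panel permutes rows/columns consistently
  perm <- c(3, 1, 4, 2)
  pc2 <- toyCounts(refCounts(pc)[, perm], altCounts(pc)[, perm],
                   panel = {
                     p <- poolPanel(pc)[perm, ]
                     rownames(p) <- NULL
                     p
                   })
  v2 <- distValues(fstMatrix(pc2))
  expect_equal(v2, v[perm, perm])
  # grouped: cross-origin pairs are not computed
  mg <- fstMatrix(pc, by_origin = TRUE)   # 2 native + 2 invasive
  vg <- distValues(mg)
  expect_true(is.na(vg["pool01", "pool03"]))
  expect_equal(vg["pool01", "pool02"], v["pool01", "pool02"])
})

test_that("Welch's t test matches the Satterthwaite closed form", {
  a <- c(4.1, 5.2, 6.3, 5.8, 4.9)
  b <- c(7.4, 8.1, 6.9, 7.7, 8.5, 7.2)
  res <- welchTTest(a, b)
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand))
  same <- welchTTest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welchTTest(a, 1), "at least 2")
})

test_that("Mantel p matches exhaustive enumeration on small label sets", {
  set.seed(14)
  for (n in 4:6) {
    v <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    v[lower.tri(v)] <- runif(choose(n, 2), 10, 500)
    v <- v + t(v)
    m1 <- PoolDist(v, "geographic_km")
    m2 <- PoolDist(2 * v + 1 - diag(1, n), "geographic_km")
    res <- mantelTest(m1, m2, n_perm = 1999, seed = 3)
    expect_equal(res$r, 1)
    p_exact <- exactMantelP(m1, m2)
    # sampled permutation p estimates the exact tail probability
    expect_lt(abs(res$p - p_exact), 0.03)
    expect_true(res$p > 0 && res$p <= 1)
  }
})

test_that("Mantel test handles self-comparison, noise, and degeneracy", {
  set.seed(20)
  n <- 8
  v <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  v[lower.tri(v)] <- runif(choose(n, 2))
  v <- v + t(v)
  m1 <- PoolDist(v, "geographic_km")
  expect_equal(mantelTest(m1, m1, 99, seed = 1)$r, 1)
  # independent matrix: association should not be called significant
  w <- matrix(0, n, n, dimnames = dimnames(v))
  w[lower.tri(w)] <- runif(choose(n, 2))
  w <- w + t(w)
  expect_gt(mantelTest(m1, PoolDist(w, "geographic_km"), 999, seed = 2)$p,
            0.001)
  # determinism
  expect_identical(mantelTest(m1, m1, 999, seed = 7),
                   mantelTest(m1, m1, 999, seed = 7))
  # constant off-diagonal -> undefined r
  k <- matrix(1, n, n, dimnames = dimnames(v)); diag(k) <- 0
  expect_warning(res <- mantelTest(PoolDist(k, "geographic_km"), m1, 99,
                                   seed = 1), "constant")
  expect_true(is.na(res$r))
  # label mismatch
  u <- v; dimnames(u) <- list(paste0("x", 1:n), paste0("x", 1:n))
  expect_error(mantelTest(m1, PoolDist(u, "geographic_km"), 99, seed = 1),
               "labels")
})

test_that("Mantel statistic agrees with an established implementation", {
  skip_if_not_installed("vegan")
  set.seed(33)
  n <- 10
  v <- as.matrix(dist(matrix(runif(n * 2), n)))
  w <- as.matrix(dist(matrix(runif(n * 2), n)))
  dimnames(v) <- dimnames(w) <- list(paste0("s", 1:n), paste0("s", 1:n))
  ours <- mantelTest(PoolDist(v, "geographic_km"),
                     PoolDist(w, "geographic_km"), n_perm = 999, seed = 5)
  ref <- vegan::mantel(v, w, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic))
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("geographic distances follow the haversine closed form", {
  panel <- data.frame(pool_id = c("a", "b", "c"), origin = "native",
                      n_maternal = 20L,
                      latitude = c(0, 0, 0), longitude = c(0, 90, 0))
  m <- geoDistMatrix(panel)
  v <- distValues(m)
  expect_equal(v["a", "c"], 0)
  # quarter of a great circle at mean Earth radius 6371 km
  expect_equal(v["a", "b"], pi / 2 * 6371, tolerance = 1e-6)
  expect_equal(v, t(v))
  expect_equal(distKind(m), "geographic_km")
})
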