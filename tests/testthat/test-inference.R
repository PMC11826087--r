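nullGarden <- function(seed, weeks = 2, dispersion = 8,
                       zi = c(high = 0, medium = 0, low = 0), ...) {
  simulateGarden(gardenSimConfig(seed = seed, weeks = weeks,
                                 count_dispersion = dispersion,
                                 zero_inflation = zi, ...))
}

modelData <- function(g, week = 2) {
  d <- buildModelData(g$design, g$mixtures, g$monitoring, week = week)
  merge(d, g$harvest, by = "unit_id")
}

test_that("z-standardization centres and scales within each group", {
  expect_equal(zStandardizeWithin(c(1, 2, 3), rep("a", 3)), c(-1, 0, 1))
  v <- c(1, 2, 3, 10, 20, 30)
  gl <- rep(c("a", "b"), each = 3)
  z <- zStandardizeWithin(v, gl)
  # each group standardizes independently of the other
  expect_equal(z[1:3], z[4:6])
  set.seed(8)
  v2 <- rnorm(40, 5, 2); g2 <- rep(c("x", "y"), 20)
  z2 <- zStandardizeWithin(v2, g2)
  for (gg in c("x", "y")) {
    expect_lt(abs(mean(z2[g2 == gg])), 1e-12)
    expect_lt(abs(sd(z2[g2 == gg]) - 1), 1e-12)
  }
  expect_error(zStandardizeWithin(c(1, 1, 1), rep("a", 3)), "zero standard")
  expect_error(zStandardizeWithin(c(1, 2), c("a", "b")), "fewer than 2")
})

test_that("linear model detects exact signal and rejects collinearity", {
  g <- nullGarden(seed = 301)
  d <- modelData(g)
  set.seed(1)
  d$resp <- 2 + 3 * d$GD + rnorm(nrow(d), 0, 1e-3)
  fit <- fitLm(d, "resp")
  expect_gt(summary(fit$fit)$r.squared, 1 - 1e-6)
  expect_gt(fit$anova$statistic[fit$anova$term == "GD"], 1e6)
  d$dup <- d$GD
  expect_error(fitLm(d, "resp", covariates = c("dup", "dup")), "aliased|rank")
})

test_that("quasi-Poisson estimates equal Poisson estimates; Wald = (est/se)^2", {
  g <- nullGarden(seed = 302, dispersion = 4)
  d <- modelData(g)
  fit <- fitQuasipoisson(d, "n_ind", "seed_size")
  pois <- glm(n_ind ~ GD * msa * origin + seed_size, data = d,
              family = poisson())
  expect_equal(unname(coef(fit$fit)), unname(coef(pois)), tolerance = 1e-10)
  # dispersion scales SEs only
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(pois)) * fit$dispersion)),
               tolerance = 1e-8)
  # a 1-df interaction-free term has Wald chi-square = (estimate/se)^2
  a <- fit$anova
  ct <- fit$coefficients
  z2 <- (ct$estimate[ct$term == "seed_size"] /
           ct$se[ct$term == "seed_size"])^2
  expect_equal(a$statistic[a$term == "seed_size"], z2, tolerance = 1e-10)
  # a multi-df term is the quadratic form in its own coefficients
  V <- vcov(fit$fit); b <- coef(fit$fit)
  idx <- grep("^GD:msa.*:origin", names(b))
  w3 <- drop(t(b[idx]) %*% solve(V[idx, idx]) %*% b[idx])
  expect_equal(a$statistic[a$term == "GD:msa:origin"], w3,
               tolerance = 1e-10)
  expect_equal(pchisq(a$statistic[a$term == "GD"], 1, lower.tail = FALSE),
               a$p[a$term == "GD"])
  # intercept-only structure: constant counts give log(c) and zero slopes
  d$flat <- 7L
  flatfit <- glm(flat ~ 1, data = d, family = quasipoisson())
  expect_equal(unname(coef(flatfit)), log(7))
})

test_that("Pearson dispersion is near 1 for equi-dispersed counts", {
  set.seed(41)
  n <- 500
  d <- data.frame(GD = rnorm(n),
                  msa = factor(sample(c("high", "medium", "low"), n, TRUE)),
                  origin = factor(sample(c("native", "invasive"), n, TRUE)))
  d$n_ind <- rpois(n, exp(3 + 0.1 * d$GD))
  fit <- fitQuasipoisson(d, "n_ind")
  expect_lt(abs(fit$dispersion - 1), 0.15)
})

test_that("quasi-Poisson recovers known coefficients under NB noise", {
  set.seed(42)
  n <- 1000
  d <- data.frame(GD = rnorm(n),
                  msa = factor(sample(c("high", "medium", "low"), n, TRUE),
                               levels = c("high", "medium", "low")),
                  origin = factor(sample(c("native", "invasive"), n, TRUE)))
  d$n_ind <- rnbinom(n, mu = exp(1.0 + 0.3 * d$GD), size = 5)
  fit <- fitQuasipoisson(d, "n_ind")
  ct <- fit$coefficients
  for (tt in list(c("(Intercept)", 1.0), c("GD", 0.3))) {
    row <- ct[ct$term == tt[1], ]
    expect_lt(abs(row$estimate - as.numeric(tt[2])), 3 * row$se)
  }
})

test_that("zero-inflated Gamma with no zeros equals the plain Gamma GLM", {
  g <- nullGarden(seed = 303)
  d <- modelData(g)
  d <- d[d$mean_size > 0, ]
  fz <- fitZiGamma(d, "mean_size", zi_formula = ~msa)
  fg <- glm(mean_size ~ GD * msa * origin, data = d,
            family = Gamma(link = "log"))
  expect_lt(max(abs(coef(fz$fit) - coef(fg))), 1e-4)
  expect_equal(fz$n_zero, 0L)
  expect_null(fz$zero_fit)
  # constant positive response: intercept log(c)
  d$flat <- 5.5
  cfit <- glm(flat ~ 1, data = d, family = Gamma(link = "log"))
  expect_equal(unname(coef(cfit)), log(5.5))
  # error paths
  d$neg <- d$mean_size; d$neg[1] <- -1
  expect_error(fitZiGamma(d, "neg"), "non-negative")
  d$zero <- 0
  expect_error(fitZiGamma(d, "zero"), "all zero")
})

test_that("zero-inflated Gamma recovers zero rates and mean coefficients", {
  # structural zeros by microsite level, Gamma positives with known GD slope
  cfg <- gardenSimConfig(seed = 304, weeks = 2, count_dispersion = 8,
                         zero_inflation = c(high = 0.05, medium = 0.3,
                                            low = 0.6),
                         beta_bio_gd = c(high = 0.2, medium = 0.2,
                                         low = 0.2))
  gs <- lapply(1:10, function(i) {
    cfg$seed <- 304 + i
    simulateGarden(cfg)
  })
  d <- do.call(rbind, lapply(gs, modelData))       # 2700 units
  fit <- fitZiGamma(d, "total_biomass_g", zi_formula = ~msa)
  # zero-inflation probabilities on the logit scale per microsite level
  zc <- coef(fit$zero_fit)
  p_hat <- plogis(c(zc[1], zc[1] + zc[2], zc[1] + zc[3]))
  expect_equal(unname(p_hat), c(0.05, 0.3, 0.6), tolerance = 0.25)
  # conditional-mean GD slope recovered within 3 SE
  ct <- fit$coefficients
  row <- ct[ct$term == "GD", ]
  expect_lt(abs(row$estimate - 0.2), 3 * row$se)
  expect_true(fit$converged)
  expect_gt(fit$shape, 0)
})

test_that("two-part fit agrees with the joint TMB zero-inflated Gamma", {
  skip_if_not_installed("glmmTMB")
  g <- nullGarden(seed = 305, zi = c(high = 0.05, medium = 0.3, low = 0.6))
  d <- modelData(g)
  fz <- fitZiGamma(d, "total_biomass_g", zi_formula = ~msa)
  tm <- glmmTMB::glmmTMB(total_biomass_g ~ GD * msa * origin,
                         ziformula = ~msa,
                         family = glmmTMB::ziGamma(link = "log"), data = d)
  expect_lt(max(abs(coef(fz$fit) - glmmTMB::fixef(tm)$cond)), 1e-4)
  expect_lt(max(abs(coef(fz$zero_fit) - glmmTMB::fixef(tm)$zi)), 1e-3)
  expect_equal(fz$shape, 1 / glmmTMB::sigma(tm)^2, tolerance = 1e-3)
})

test_that("subset trends drop the separating factor and recover signs", {
  g <- nullGarden(seed = 306)
  d <- modelData(g)
  # no subsetting: reduced formula equals the full model's GD slope
  full <- fitQuasipoisson(d, "n_ind")
  st0 <- subsetTrend(d, "n_ind", "quasipoisson")
  gd <- full$coefficients[full$coefficients$term == "GD", ]
  expect_equal(st0$estimate, gd$estimate)
  expect_equal(st0$se, gd$se)
  # origin-specific slopes: +0.06 invasive, -0.07 native at 10x replication
  cfg <- gardenSimConfig(seed = 307, weeks = 2,
                         beta_gd = c(native = -0.07, invasive = 0.06))
  gs <- lapply(1:10, function(i) {
    cfg$seed <- 307 + i
    simulateGarden(cfg)
  })
  d10 <- do.call(rbind, lapply(gs, modelData))    # 1350 per origin
  st_inv <- subsetTrend(d10, "n_ind", "quasipoisson",
                        subset = list(origin = "invasive"))
  st_nat <- subsetTrend(d10, "n_ind", "quasipoisson",
                        subset = list(origin = "native"))
  expect_gt(st_inv$estimate, 0)
  expect_lt(st_nat$estimate, 0)
  expect_lt(abs(st_inv$estimate - 0.06), 3 * st_inv$se)
  expect_lt(abs(st_nat$estimate + 0.07), 3 * st_nat$se)
  # double subset leaves a pure GD regression
  st2 <- subsetTrend(d, "n_ind", "quasipoisson",
                     subset = list(origin = "native", msa = "high"))
  expect_equal(st2$n, sum(d$origin == "native" & d$msa == "high"))
  expect_error(subsetTrend(d, "n_ind", "quasipoisson",
                           subset = list(origin = "martian")), "empty")
})

test_that("Tukey contrasts reduce to the t test for two groups", {
  set.seed(51)
  d <- data.frame(y = rnorm(40, rep(c(0, 0.7), each = 20)),
                  g = factor(rep(c("a", "b"), each = 20)))
  fit <- lm(y ~ g, data = d)
  tk <- tukeyPosthoc(fit, ~g)
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(nrow(tk), 1L)
  expect_equal(tk$p, tt$p.value)
  expect_equal(abs(tk$statistic), abs(unname(tt$statistic)))
})

test_that("Tukey adjusted p matches the studentized-range distribution", {
  set.seed(52)
  n <- 15
  d <- data.frame(y = rnorm(3 * n, rep(c(0, 0.5, 1.4), each = n)),
                  g = factor(rep(c("a", "b", "c"), each = n)))
  fit <- lm(y ~ g, data = d)
  tk <- tukeyPosthoc(fit, ~g)
  expect_equal(nrow(tk), 3L)
  # hand-computed q statistic for each contrast
  s2 <- summary(fit)$sigma^2
  for (i in seq_len(3)) {
    pair <- strsplit(tk$contrast[i], " - ")[[1]]
    diffm <- mean(d$y[d$g == pair[1]]) - mean(d$y[d$g == pair[2]])
    q <- abs(diffm) / sqrt(s2 / n)
    expect_equal(tk$p[i],
                 ptukey(q, nmeans = 3, df = 3 * n - 3, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
  # identical group means: adjusted p near 1
  d$flat <- rep(rnorm(n), 3)
  tk2 <- tukeyPosthoc(lm(flat ~ g, data = d), ~g)
  expect_true(all(tk2$p > 0.999))
})

test_that("the full analysis emits models per week and harvest response", {
  g <- simulateGarden(gardenSimConfig(seed = 310,
                                      weeks = c(1, 2, 4, 11, 16, 40, 45)))
  res <- runFullAnalysis(g$design, g$mixtures, g$monitoring, g$harvest)
  expect_setequal(
    names(res$fits),
    c(paste0("count_w", c(1, 2, 4, 11, 16, 40, 45)),
      paste0("size_w", c(1, 2, 4, 11, 16, 40, 45)),
      "veg_biomass", "total_biomass", "life_stage"))
  # seed-size covariate only until week 4
  expect_true("seed_size" %in% res$fits$count_w2$anova$term)
  expect_false("seed_size" %in% res$fits$count_w11$anova$term)
  # zero-inflation weeks use the zi-Gamma size model
  expect_equal(res$fits$size_w11$family, "zi_gamma")
  expect_equal(res$fits$size_w2$family, "gaussian")
  expect_equal(res$fits$veg_biomass$family, "zi_gamma")
  # combined table covers all fixed terms for every model
  a <- res$anova
  for (k in c("count", "size")) {
    sub <- a[a$response == k & a$week == 2, ]
    expect_true(all(c("GD", "msa", "origin", "GD:msa:origin") %in% sub$term))
  }
  expect_true(all(a$p >= 0 & a$p <= 1, na.rm = TRUE))
  # missing week column in monitoring is a schema error
  expect_error(runFullAnalysis(g$design, g$mixtures,
                               g$monitoring[, -2], g$harvest))
})

test_that("an injected GD x origin interaction is flagged at its week", {
  cfg <- gardenSimConfig(seed = 311, weeks = c(1, 2),
                         beta_gd = c(native = -0.25, invasive = 0.25))
  g <- simulateGarden(cfg)
  res <- runFullAnalysis(g$design, g$mixtures, g$monitoring)
  a <- res$anova
  p_int <- a$p[a$response == "count" & a$week == 2 & a$term == "GD:origin"]
  expect_lt(p_int, 0.01)
})
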