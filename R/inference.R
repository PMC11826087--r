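#' Z-standardize values within groups
#'
#' Centres and scales to unit sample standard deviation (n - 1 denominator)
#' separately within each group.  Used to put the realized-He gradient of the
#' native and invasive mixtures on a common scale before modelling, because
#' the two origins span very different He ranges.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return numeric vector; each group has mean 0 and SD 1.
#' @examples
#' zStandardizeWithin(c(1, 2, 3), rep("a", 3))   # -1 0 1
#' @export
zStandardizeWithin <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- numeric(length(values))
  for (g in unique(groups)) {
    i <- which(groups == g)
    if (length(i) < 2)
      stop("group '", g, "' has fewer than 2 values")
    s <- stats::sd(values[i])
    if (s == 0) stop("group '", g, "' has zero standard deviation")
    out[i] <- (values[i] - mean(values[i])) / s
  }
  out
}

.fixedFormula <- function(response, covariates = character()) {
  rhs <- c("GD * msa * origin", covariates)
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

.checkModelData <- function(data, response, covariates) {
  need <- c(response, "GD", "msa", "origin", covariates)
  miss <- setdiff(need, colnames(data))
  if (length(miss))
    stop("model data lacks columns: ", paste(miss, collapse = ", "))
  invisible(data)
}

.anovaFromCar <- function(a) {
  a <- as.data.frame(a)
  term <- rownames(a)
  keep <- !term %in% c("Residuals", "(Intercept)")
  a <- a[keep, , drop = FALSE]; term <- term[keep]
  if ("F value" %in% colnames(a)) {
    data.frame(term = term, statistic = a[["F value"]], df = a[["Df"]],
               sum_sq = a[["Sum Sq"]], p = a[["Pr(>F)"]],
               stat_type = "F", row.names = NULL)
  } else {
    data.frame(term = term, statistic = a[["Chisq"]], df = a[["Df"]],
               p = a[["Pr(>Chisq)"]],
               stat_type = "Wald chisq", row.names = NULL)
  }
}

.coefTable <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             statistic = s[, 3], p = s[, ncol(s)], row.names = NULL)
}

#' Linear model for a size statistic at one monitoring date
#'
#' Least-squares fit of `response ~ GD * msa * origin` (all interactions up
#' to the three-way term) plus optional covariates (the seed-size covariate
#' during the establishment weeks), with a Type-II F-test ANOVA table.
#'
#' @param data data.frame with columns `GD` (z-scored He), `msa` (3-level
#'   factor), `origin` (2-level factor), the response, and any covariates.
#' @param response response column name.
#' @param covariates character vector of covariate column names.
#' @return An object of class `pgFit`: list with `fit` (the underlying
#'   model), `family`, `coefficients` (tidy table), `anova` (tidy Type-II
#'   table), `dispersion`, `converged`.
#' @export
fitLm <- function(data, response, covariates = character()) {
  .checkModelData(data, response, covariates)
  fo <- .fixedFormula(response, covariates)
  fit <- stats::lm(fo, data = data)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: aliased terms ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  structure(list(fit = fit, family = "gaussian",
                 coefficients = .coefTable(fit),
                 anova = .anovaFromCar(car::Anova(fit, type = "II")),
                 dispersion = summary(fit)$sigma^2, converged = TRUE,
                 response = response),
            class = "pgFit")
}

#' Quasi-Poisson model for individual counts
#'
#' Log-link Poisson regression of `response ~ GD * msa * origin` (plus
#' covariates) with a free dispersion parameter estimated from the Pearson
#' statistic, `phi = X^2_Pearson / (n - p)`.  Point estimates equal the
#' Poisson-GLM estimates; standard errors are scaled by `sqrt(phi)`.  The
#' ANOVA table holds Type-II Wald chi-square statistics.
#'
#' @inheritParams fitLm
#' @return A `pgFit` (see [fitLm()]); `dispersion` is the Pearson phi.
#' @export
fitQuasipoisson <- function(data, response, covariates = character()) {
  .checkModelData(data, response, covariates)
  fo <- .fixedFormula(response, covariates)
  fit <- stats::glm(fo, data = data, family = stats::quasipoisson())
  structure(list(fit = fit, family = "quasipoisson",
                 coefficients = .coefTable(fit),
                 anova = .anovaFromCar(
                   car::Anova(fit, type = "II", test.statistic = "Wald")),
                 dispersion = summary(fit)$dispersion,
                 converged = fit$converged, response = response),
            class = "pgFit")
}

#' Zero-inflated Gamma model
#'
#' Mixture model for a non-negative response: with probability `pi(z)`
#' (logit-linear in the zero-inflation covariates, by default the microsite
#' treatment that suppresses establishment) the response is exactly zero;
#' otherwise it is Gamma distributed with log-link mean `exp(X beta)` and
#' shape `alpha`.  Because the Gamma density has no mass at zero, the joint
#' likelihood factorises exactly into a Bernoulli GLM on the zero indicator
#' and a Gamma GLM on the positive observations; the maximum-likelihood
#' estimates are therefore computed by those two fits — no iterative joint
#' optimisation is needed, and with zero inflation removed the fit *is* the
#' plain Gamma GLM.  Wald tests (Type II chi-square) are reported for the
#' conditional-mean terms.
#'
#' @inheritParams fitLm
#' @param zi_formula one-sided formula for the zero-inflation part:
#'   `~ msa` (default), `~ 1`, or `~ 0` (no zero inflation; zeros then raise
#'   an error).
#' @return A `pgFit` with additional elements `zero_fit`,
#'   `zero_coefficients` (logit scale), `shape` (Gamma shape MLE), and
#'   `n_zero`.
#' @export
fitZiGamma <- function(data, response, covariates = character(),
                       zi_formula = ~msa) {
  .checkModelData(data, response, covariates)
  y <- data[[response]]
  if (any(is.na(y))) stop("response contains NA")
  if (any(y < 0)) stop("zero-inflated Gamma requires a non-negative response")
  if (all(y == 0)) stop("response is all zero: nothing to fit")
  zi_none <- identical(stats::terms(zi_formula), stats::terms(~0)) ||
    length(all.vars(zi_formula)) == 0 && attr(stats::terms(zi_formula),
                                              "intercept") == 0
  is_zero <- y == 0
  if (zi_none && any(is_zero))
    stop("response has zeros but zi_formula = ~0 disables zero inflation")
  zero_fit <- NULL; zero_coefs <- NULL
  if (!zi_none && any(is_zero)) {
    zfo <- stats::update(zi_formula, is_zero_ ~ .)
    zdat <- data; zdat$is_zero_ <- as.numeric(is_zero)
    zero_fit <- stats::glm(zfo, data = zdat, family = stats::binomial())
    zero_coefs <- .coefTable(zero_fit)
  }
  pos <- data[!is_zero, , drop = FALSE]
  fo <- .fixedFormula(response, covariates)
  cond <- stats::glm(fo, data = pos, family = stats::Gamma(link = "log"))
  shape <- tryCatch(MASS::gamma.shape(cond)$alpha, error = function(e) NA_real_)
  structure(list(fit = cond, family = "zi_gamma",
                 coefficients = .coefTable(cond),
                 anova = .anovaFromCar(
                   car::Anova(cond, type = "II", test.statistic = "Wald")),
                 dispersion = summary(cond)$dispersion, shape = shape,
                 zero_fit = zero_fit, zero_coefficients = zero_coefs,
                 zi_formula = zi_formula, n_zero = sum(is_zero),
                 converged = cond$converged &&
                   (is.null(zero_fit) || zero_fit$converged),
                 response = response),
            class = "pgFit")
}

#' @export
print.pgFit <- function(x, ...) {
  cat("pgFit (", x$family, "): ", x$response, "\n", sep = "")
  cat("  dispersion:", format(x$dispersion, digits = 4))
  if (!is.null(x$shape)) cat("  shape:", format(x$shape, digits = 4))
  if (!is.null(x$n_zero)) cat("  zeros:", x$n_zero)
  cat("\n  Type-II ANOVA:\n")
  print(x$anova, digits = 4)
  invisible(x)
}

#' Genetic-diversity trend within a data subset
#'
#' Refits the model on the subset of the data defined by fixing one or more
#' design factors, with those factors removed from the fixed-effects formula,
#' and returns the slope of the genetic-diversity gradient (`GD` main
#' effect), its standard error and Wald p value.  For zero-inflated Gamma
#' fits the subset model uses an intercept-only zero-inflation term
#' (`~ 1`), since the factor explaining the zeros may be the one fixed.
#'
#' @param data full model data.frame.
#' @param response response column name.
#' @param family `"gaussian"`, `"quasipoisson"`, or `"zi_gamma"`.
#' @param subset named list fixing factor levels, e.g.
#'   `list(origin = "native")` or `list(origin = "native", msa = "medium")`.
#' @param covariates covariate column names kept in the reduced model.
#' @return list with `estimate`, `se`, `p`, `n` (subset size) and `fit`.
#' @export
subsetTrend <- function(data, response, family = c("gaussian", "quasipoisson",
                                                   "zi_gamma"),
                        subset = list(), covariates = character()) {
  family <- match.arg(family)
  keep <- rep(TRUE, nrow(data))
  for (f in names(subset)) {
    if (!f %in% colnames(data)) stop("unknown subsetting column: ", f)
    keep <- keep & data[[f]] == subset[[f]]
  }
  sub <- droplevels(data[keep, , drop = FALSE])
  if (!nrow(sub)) stop("empty subset")
  remaining <- setdiff(c("msa", "origin"), names(subset))
  rhs <- if (length(remaining))
    paste(c("GD", remaining), collapse = " * ") else "GD"
  fo <- stats::as.formula(paste(response, "~",
                                paste(c(rhs, covariates), collapse = " + ")))
  fit <- switch(family,
    gaussian = stats::lm(fo, data = sub),
    quasipoisson = stats::glm(fo, data = sub,
                              family = stats::quasipoisson()),
    zi_gamma = {
      y <- sub[[response]]
      pos <- sub[y > 0, , drop = FALSE]
      stats::glm(fo, data = pos, family = stats::Gamma(link = "log"))
    })
  ct <- .coefTable(fit)
  row <- ct[ct$term == "GD", , drop = FALSE]
  if (!nrow(row)) stop("GD term missing from reduced model")
  list(estimate = row$estimate, se = row$se, p = row$p,
       n = nrow(sub), fit = fit)
}

#' Tukey post hoc contrasts
#'
#' All pairwise differences of factor-level (or factor-combination) means
#' with studentized-range ("Tukey") adjusted p values, via estimated
#' marginal means on the fitted model.
#'
#' @param fit a `pgFit` (from [fitLm()], [fitQuasipoisson()] or
#'   [fitZiGamma()]) or a bare `lm`/`glm`.
#' @param specs one-sided formula naming the factor(s), e.g. `~ msa` or
#'   `~ msa * origin` for all cell-mean contrasts.
#' @return data.frame of contrasts: `contrast`, `estimate`, `se`, `df`,
#'   `statistic`, `p` (Tukey-adjusted).
#' @export
tukeyPosthoc <- function(fit, specs = ~msa) {
  mod <- if (inherits(fit, "pgFit")) fit$fit else fit
  emm <- emmeans::emmeans(mod, specs = specs)
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "tukey"))
  out <- as.data.frame(prs)
  stat_col <- intersect(c("t.ratio", "z.ratio"), colnames(out))[1]
  data.frame(contrast = as.character(out$contrast), estimate = out$estimate,
             se = out$SE, df = if ("df" %in% colnames(out)) out$df else NA,
             statistic = out[[stat_col]], p = out$p.value, row.names = NULL)
}

#' Assemble the per-unit modelling table
#'
#' Joins the design table with the mixture table (realized He), z-scores He
#' within origin into the `GD` column, and attaches monitoring statistics for
#' one week (`n_ind`, `size_class_ratio`, `rosette_ratio`, `life_stage`,
#' and `mean_size` when present) and/or harvest responses.
#'
#' @param design design table from [expandDesign()].
#' @param mixtures mixture table with `mixture_id` and `realized_He`.
#' @param monitoring optional wide monitoring table (see [readMonitoring()]).
#' @param week week to pull monitoring statistics from.
#' @param harvest optional harvest table.
#' @return data.frame, one row per experimental unit.
#' @export
buildModelData <- function(design, mixtures, monitoring = NULL, week = NULL,
                           harvest = NULL) {
  need <- c("mixture_id", "realized_He")
  miss <- setdiff(need, colnames(mixtures))
  if (length(miss))
    stop("mixtures table lacks columns: ", paste(miss, collapse = ", "))
  dat <- merge(design, mixtures[, c("mixture_id", "realized_He")],
               by = "mixture_id", sort = FALSE)
  dat$origin <- factor(dat$origin)
  if (!is.factor(dat$msa)) dat$msa <- factor(dat$msa)
  dat$GD <- zStandardizeWithin(dat$realized_He, dat$origin)
  if (!is.null(monitoring)) {
    if (is.null(week)) stop("week must be given with monitoring data")
    mw <- monitoring[monitoring$week == week, , drop = FALSE]
    if (!nrow(mw)) stop("no monitoring rows for week ", week)
    mw$n_ind <- totalIndividuals(mw)
    mw$size_class_ratio <- sizeClassRatio(mw)
    mw$rosette_ratio <- rosetteSizeRatio(mw)
    mw$life_stage <- lifeStageRatio(mw)
    keep <- c("unit_id", "n_ind", "size_class_ratio", "rosette_ratio",
              "life_stage", intersect("mean_size", colnames(mw)))
    dat <- merge(dat, mw[, keep], by = "unit_id", sort = FALSE)
  }
  if (!is.null(harvest))
    dat <- merge(dat, harvest, by = "unit_id", sort = FALSE)
  dat[order(dat$unit_id), , drop = FALSE]
}

#' Run the full statistical analysis over weeks and harvest
#'
#' Orchestrates the modelling layer: for every monitored week, individual
#' counts are fitted with the quasi-Poisson GLM and the size statistic with a
#' Gaussian LM (the size-class ratio up to `rosette_from` weeks, the
#' rosette-size ratio afterwards) — except for the designated zero-inflation
#' weeks, where a non-negative per-unit mean size (`mean_size` column, zeros
#' arising when a unit holds no plants) is fitted with the zero-inflated
#' Gamma model using the microsite treatment as zero-inflation predictor.
#' The seed-size covariate (`seed_size` column of the design, average
#' projected seed area) is included for weeks up to `seed_size_until`.
#' Harvest biomass responses are fitted with the zero-inflated Gamma model;
#' the life-stage ratio with a Gaussian LM.
#'
#' @param design design table (optionally with a `seed_size` column).
#' @param mixtures mixture table with `realized_He`.
#' @param monitoring wide monitoring table.
#' @param harvest optional harvest table.
#' @param zi_weeks weeks modelled with the zero-inflated Gamma size model
#'   (default 11 and 16).
#' @param seed_size_until last week that includes the seed-size covariate
#'   (default 4).
#' @param rosette_from first week using the rosette-size ratio instead of
#'   the size-class ratio (default 5).
#' @return list with `fits` (named `pgFit` list, keys like `count_w2`,
#'   `size_w2`, `veg_biomass`) and `anova` (combined tidy table with
#'   `response`, `week`, `term`, `statistic`, `df`, `p`).
#' @export
runFullAnalysis <- function(design, mixtures, monitoring, harvest = NULL,
                            zi_weeks = c(11, 16), seed_size_until = 4,
                            rosette_from = 5) {
  miss <- setdiff(c("unit_id", "week", sizeClassColumns()),
                  colnames(monitoring))
  if (length(miss))
    stop("monitoring table lacks columns: ", paste(miss, collapse = ", "))
  weeks <- sort(unique(monitoring$week))
  has_seed <- "seed_size" %in% colnames(design)
  fits <- list()
  for (w in weeks) {
    dat <- buildModelData(design, mixtures, monitoring, week = w)
    covs <- if (has_seed && w <= seed_size_until) "seed_size" else character()
    fits[[paste0("count_w", w)]] <- fitQuasipoisson(dat, "n_ind", covs)
    if (w %in% zi_weeks && "mean_size" %in% colnames(dat)) {
      fits[[paste0("size_w", w)]] <-
        fitZiGamma(dat, "mean_size", covs, zi_formula = ~msa)
    } else {
      resp <- if (w < rosette_from) "size_class_ratio" else "rosette_ratio"
      fits[[paste0("size_w", w)]] <- fitLm(dat, resp, covs)
    }
  }
  if (!is.null(harvest)) {
    dat <- buildModelData(design, mixtures, monitoring, week = max(weeks),
                          harvest = harvest)
    for (resp in intersect(c("vegetative_biomass_g", "total_biomass_g"),
                           colnames(dat))) {
      key <- if (resp == "vegetative_biomass_g") "veg_biomass"
             else "total_biomass"
      fits[[key]] <- fitZiGamma(dat, resp, zi_formula = ~msa)
    }
    fits[["life_stage"]] <- fitLm(dat, "life_stage")
  }
  anova <- do.call(rbind, lapply(names(fits), function(k) {
    a <- fits[[k]]$anova[, c("term", "statistic", "df", "p", "stat_type")]
    a$response <- sub("_w[0-9]+$", "", k)
    a$week <- if (grepl("_w", k)) as.numeric(sub("^.*_w", "", k)) else
      NA_real_
    a
  }))
  rownames(anova) <- NULL
  list(fits = fits,
       anova = anova[, c("response", "week", "term", "statistic", "df", "p",
                         "stat_type")])
}
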