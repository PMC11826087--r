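#' Configuration for the pool-seq read-count simulator
#'
#' Parameters of the Beta island model used to generate pooled read counts
#' with a known differentiation truth: per locus an ancestral frequency `p`
#' is drawn uniformly from `ancestral_freq_range`; each population's
#' frequency is Beta-distributed with mean `p` and variance `F p (1 - p)`
#' (shapes `p (1 - F) / F` and `(1 - p)(1 - F) / F`); a pool of
#' `haploid_pool_size` gene copies is binomially sampled from the population;
#' sequencing depth is negative-binomial (mean `mean_depth`, size
#' `depth_dispersion`, emulating the coverage heterogeneity of
#' reduced-representation libraries); and reference reads are binomial in the
#' pool allele frequency.
#'
#' @param n_pops number of population pools.
#' @param n_loci number of biallelic loci (one per contig).
#' @param true_F differentiation parameter in (0, 1).
#' @param haploid_pool_size gene copies per pool (default 40 = 2 x 20
#'   maternal plants).
#' @param mean_depth,depth_dispersion negative-binomial depth model.
#' @param ancestral_freq_range range of ancestral allele frequencies.
#' @param missing_rate fraction of observations replaced by missing values.
#' @param origins optional character vector of per-pool origins; default
#'   splits the panel into a native first half and invasive second half.
#' @param seed mandatory integer seed.
#' @return a `poolSimConfig` list.
#' @export
poolSimConfig <- function(n_pops = 5L, n_loci = 1000L, true_F = 0.05,
                          haploid_pool_size = 40L, mean_depth = 60,
                          depth_dispersion = 5,
                          ancestral_freq_range = c(0.1, 0.9),
                          missing_rate = 0, origins = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (true_F <= 0 || true_F >= 1) stop("true_F must be in (0, 1)")
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (is.null(origins))
    origins <- rep(c("native", "invasive"),
                   c(ceiling(n_pops / 2), floor(n_pops / 2)))
  stopifnot(length(origins) == n_pops)
  structure(list(n_pops = as.integer(n_pops), n_loci = as.integer(n_loci),
                 true_F = true_F,
                 haploid_pool_size = as.integer(haploid_pool_size),
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate, origins = origins,
                 seed = as.integer(seed)),
            class = "poolSimConfig")
}

#' Simulate pooled read counts under the Beta island model
#'
#' See [poolSimConfig()] for the generative model.  The returned
#' [PoolCounts-class] carries a `truth` record in its metadata with the
#' latent ancestral frequencies, per-population frequencies and pool allele
#' frequencies, so estimators can be validated against ground truth.
#' Deterministic given the config seed.
#'
#' @param cfg a [poolSimConfig()].
#' @return A [PoolCounts-class]; `metadata(x)$truth` holds the latent state.
#' @examples
#' pc <- simulatePools(poolSimConfig(n_pops = 2, n_loci = 200, seed = 42))
#' pc
#' @export
simulatePools <- function(cfg) {
  stopifnot(inherits(cfg, "poolSimConfig"))
  set.seed(cfg$seed)
  L <- cfg$n_loci; K <- cfg$n_pops; n <- cfg$haploid_pool_size
  p_anc <- stats::runif(L, cfg$ancestral_freq_range[1],
                        cfg$ancestral_freq_range[2])
  f <- cfg$true_F
  pop_freq <- matrix(stats::rbeta(L * K,
                                  shape1 = rep(p_anc * (1 - f) / f, K),
                                  shape2 = rep((1 - p_anc) * (1 - f) / f, K)),
                     nrow = L, ncol = K)
  pool_freq <- matrix(stats::rbinom(L * K, n, as.vector(pop_freq)) / n,
                      nrow = L, ncol = K)
  depth <- matrix(stats::rnbinom(L * K, mu = cfg$mean_depth,
                                 size = cfg$depth_dispersion),
                  nrow = L, ncol = K)
  ref <- matrix(stats::rbinom(L * K, as.vector(depth),
                              as.vector(pool_freq)),
                nrow = L, ncol = K)
  alt <- depth - ref
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(L * K) < cfg$missing_rate, L, K)
    ref[miss] <- NA_integer_; alt[miss] <- NA_integer_
  }
  panel <- data.frame(pool_id = sprintf("pool%02d", seq_len(K)),
                      origin = cfg$origins,
                      latitude = round(stats::runif(K, 45, 55), 4),
                      longitude = round(stats::runif(K, -125, 15), 4),
                      n_maternal = n %/% 2L, haploid_size = n)
  loci <- data.frame(contig = sprintf("ctg%06d", seq_len(L)),
                     position = 100L, ref = "A", alt = "T",
                     is_indel = FALSE, n_alleles = 2L)
  PoolCounts(ref = ref, alt = alt, loci = loci, panel = panel,
             metadata = list(truth = list(true_F = f, ancestral_freq = p_anc,
                                          pop_freq = pop_freq,
                                          pool_freq = pool_freq),
                             sim_config = cfg))
}

#' Configuration for the common-garden outcome simulator
#'
#' Generative model for monitoring and harvest data on an experimental
#' design with known effect sizes.  Per experimental unit:
#'
#' * each mixture receives a realized He drawn uniformly from its origin's
#'   `he_ranges` (defaults are the observed de-novo ranges: 0.2377-0.2795
#'   native, 0.2593-0.2676 invasive); `GD` is the within-origin z-score;
#' * the germinant count is negative-binomial (size `count_dispersion`;
#'   Poisson when infinite) with log-mean
#'   `log(base_count) + beta_gd[origin] * GD + beta_msa[msa] +
#'    beta_origin * [invasive] + beta_gd_msa[msa] * GD`;
#' * with probability `zero_inflation[msa]` a unit fails after week
#'   `fail_after` (its later censuses, mean size and biomass are structural
#'   zeros) — the zero-generating process the zero-inflated Gamma model
#'   attributes to the microsite treatment;
#' * surviving individuals thin weekly at rate `survival` and drift through
#'   the ten size classes; per-unit mean rosette size and harvest biomass
#'   are Gamma with shape `gamma_shape` and log-mean linear in
#'   `beta_bio_gd[msa] * GD`.
#'
#' A seed-size covariate (average projected seed area, cm^2) is drawn per
#' unit from `Normal(seed_size_mean, seed_size_sd)` and has no effect on any
#' outcome (its model term is a pure type-I-error check).
#'
#' @param design design table from [expandDesign()]; `NULL` builds the
#'   default 15-mixtures x 2-origins x 3-microsites x 3-replicates layout
#'   (270 units).
#' @param he_ranges named list of per-origin realized-He ranges.
#' @param base_count expected germinants per 100-seed sample at baseline.
#' @param beta_gd named per-origin GD slopes (log scale).
#' @param beta_msa,beta_gd_msa named per-microsite offsets / GD slopes.
#' @param beta_origin log-scale offset of invasive vs native.
#' @param count_dispersion negative-binomial size; `Inf` = Poisson.
#' @param survival weekly survival probability.
#' @param zero_inflation named per-microsite failure probabilities.
#' @param fail_after failures occur after this week.
#' @param base_biomass,base_size Gamma means (g; cm) at baseline.
#' @param beta_bio_gd named per-microsite GD slopes for size/biomass.
#' @param gamma_shape Gamma shape of size and biomass outcomes.
#' @param weeks monitored weeks.
#' @param seed_size_mean,seed_size_sd seed-size covariate distribution.
#' @param seed mandatory integer seed.
#' @return a `gardenSimConfig` list.
#' @export
gardenSimConfig <- function(design = NULL,
                            he_ranges = list(native = c(0.2377, 0.2795),
                                             invasive = c(0.2593, 0.2676)),
                            base_count = 40,
                            beta_gd = c(native = 0, invasive = 0),
                            beta_msa = c(high = 0, medium = 0, low = 0),
                            beta_gd_msa = c(high = 0, medium = 0, low = 0),
                            beta_origin = 0, count_dispersion = 8,
                            survival = 0.96,
                            zero_inflation = c(high = 0, medium = 0.3,
                                               low = 0.6),
                            fail_after = 4, base_biomass = 20, base_size = 8,
                            beta_bio_gd = c(high = 0, medium = 0, low = 0),
                            gamma_shape = 2,
                            weeks = c(1, 2, 4, 11, 16, 40, 45),
                            seed_size_mean = 0.04, seed_size_sd = 0.005,
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(zero_inflation < 0 | zero_inflation >= 1))
    stop("zero_inflation probabilities must be in [0, 1)")
  if (survival < 0 || survival > 1) stop("survival must be in [0, 1]")
  structure(list(design = design, he_ranges = he_ranges,
                 base_count = base_count, beta_gd = beta_gd,
                 beta_msa = beta_msa, beta_gd_msa = beta_gd_msa,
                 beta_origin = beta_origin,
                 count_dispersion = count_dispersion, survival = survival,
                 zero_inflation = zero_inflation, fail_after = fail_after,
                 base_biomass = base_biomass, base_size = base_size,
                 beta_bio_gd = beta_bio_gd, gamma_shape = gamma_shape,
                 weeks = weeks, seed_size_mean = seed_size_mean,
                 seed_size_sd = seed_size_sd, seed = as.integer(seed)),
            class = "gardenSimConfig")
}

.defaultGardenDesign <- function(n_mixtures = 15L, n_replicates = 3L,
                                 seed = 1L) {
  mx <- data.frame(
    mixture_id = c(sprintf("nat%02d", seq_len(n_mixtures)),
                   sprintf("inv%02d", seq_len(n_mixtures))),
    origin = rep(c("native", "invasive"), each = n_mixtures))
  expandDesign(mx, n_replicates = n_replicates, seed = seed)
}

#' Simulate common-garden monitoring and harvest data
#'
#' See [gardenSimConfig()] for the generative model.  Returns everything the
#' inference layer consumes, plus the latent truth.  Deterministic given the
#' config seed.
#'
#' @param cfg a [gardenSimConfig()].
#' @return list with `design` (including `seed_size`), `mixtures`
#'   (`mixture_id`, `origin`, `realized_He`), `monitoring` (wide census with
#'   class counts and `mean_size`), `harvest`, and `truth` (config plus
#'   per-unit latent state: germinant count, failure flag).
#' @examples
#' g <- simulateGarden(gardenSimConfig(seed = 11))
#' nrow(g$design)       # 270 experimental units
#' @export
simulateGarden <- function(cfg) {
  stopifnot(inherits(cfg, "gardenSimConfig"))
  set.seed(cfg$seed)
  design <- if (is.null(cfg$design)) .defaultGardenDesign(seed = cfg$seed)
            else cfg$design
  stopifnot(all(c("unit_id", "mixture_id", "origin", "msa") %in%
                  colnames(design)))
  mix_ids <- unique(design[, c("mixture_id", "origin")])
  he <- numeric(nrow(mix_ids))
  for (og in unique(mix_ids$origin)) {
    i <- mix_ids$origin == og
    rg <- cfg$he_ranges[[og]]
    he[i] <- stats::runif(sum(i), rg[1], rg[2])
  }
  mixtures <- data.frame(mix_ids, realized_He = he, row.names = NULL)
  design$seed_size <- stats::rnorm(nrow(design), cfg$seed_size_mean,
                                   cfg$seed_size_sd)
  dat <- merge(design, mixtures, by = c("mixture_id", "origin"),
               sort = FALSE)
  dat$GD <- zStandardizeWithin(dat$realized_He, dat$origin)
  dat <- dat[order(dat$unit_id), , drop = FALSE]
  msa <- as.character(dat$msa)
  og <- as.character(dat$origin)
  eta <- log(cfg$base_count) + cfg$beta_gd[og] * dat$GD +
    cfg$beta_msa[msa] + cfg$beta_origin * (og == "invasive") +
    cfg$beta_gd_msa[msa] * dat$GD
  nu <- nrow(dat)
  n0 <- if (is.infinite(cfg$count_dispersion))
    stats::rpois(nu, exp(eta))
  else stats::rnbinom(nu, mu = exp(eta), size = cfg$count_dispersion)
  failed <- stats::runif(nu) < cfg$zero_inflation[msa]
  mu_size <- cfg$base_size * exp(cfg$beta_bio_gd[msa] * dat$GD)
  mu_bio <- cfg$base_biomass * exp(cfg$beta_bio_gd[msa] * dat$GD)

  classes <- sizeClassColumns()
  mon <- do.call(rbind, lapply(cfg$weeks, function(w) {
    alive <- stats::rbinom(nu, n0, cfg$survival^(w - 1))
    alive[failed & w > cfg$fail_after] <- 0L
    mcl <- min(1 + 0.18 * w, 8.5)
    pr <- stats::dnorm(1:10, mean = mcl, sd = 1.2)
    pr <- pr / sum(pr)
    cc <- t(vapply(alive, function(a) {
      if (a == 0) integer(10) else as.integer(stats::rmultinom(1, a, pr))
    }, integer(10)))
    colnames(cc) <- classes
    msz <- ifelse(alive > 0,
                  stats::rgamma(nu, shape = cfg$gamma_shape,
                                rate = cfg$gamma_shape / mu_size), 0)
    data.frame(unit_id = dat$unit_id, week = w, cc, mean_size = msz)
  }))
  rownames(mon) <- NULL

  bio <- ifelse(failed, 0,
                stats::rgamma(nu, shape = cfg$gamma_shape,
                              rate = cfg$gamma_shape / mu_bio))
  rep_frac <- stats::rbeta(nu, 2, 8)
  harvest <- data.frame(unit_id = dat$unit_id,
                        vegetative_biomass_g = bio * (1 - rep_frac),
                        reproductive_biomass_g = bio * rep_frac)
  harvest$total_biomass_g <- harvest$vegetative_biomass_g +
    harvest$reproductive_biomass_g

  list(design = design, mixtures = mixtures,
       monitoring = mon[order(mon$unit_id, mon$week), , drop = FALSE],
       harvest = harvest,
       truth = list(config = cfg, germinants = stats::setNames(n0, dat$unit_id),
                    failed = stats::setNames(failed, dat$unit_id),
                    GD = stats::setNames(dat$GD, dat$unit_id)))
}
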