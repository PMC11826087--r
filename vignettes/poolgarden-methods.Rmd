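---
title: "From pooled reads to common-garden inference: models and design choices"
author: "poolgarden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pooled reads to common-garden inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolgarden)
```

## The problem this package addresses

Common-garden experiments that manipulate the *genetic diversity* of
experimental plant populations need a quantitative chain that is rarely
assembled in one place: estimate diversity of candidate source populations
from pooled sequencing, design artificial ("de-novo") populations that span
a diversity gradient, monitor their performance, and model the outcomes.
`poolgarden` implements that chain for the pool-seq setting, where each
population is sequenced as a single pooled DNA library (here: equal leaf
material from 20 maternal plants, so a pool of 40 haploid genomes) and
allele frequencies are only available as read counts.

The motivating system is an invasive ruderal plant sampled in its native
(European) and invaded (Pacific Northwest) ranges; the experimental layout
is 15 five-population mixtures per origin, crossed with three microsite
availability levels (0, 5 or 10 matrix-grass plants per container) and
three replicates — 270 experimental units monitored over 45 weeks.

## Diversity from read counts

The reference-allele frequency of a pool at a locus is `p = c_ref / c`,
with `c` the total read count.  Per-locus expected heterozygosity uses the
small-sample correction of Nei and Roychoudhury,

$$H_e = \frac{c}{c-1}\left(1 - p^2 - q^2\right),$$

with the **read count** `c` as the sample size.  This is a deliberate
choice: in a pooled library the reads are the only observable sample of the
pool, and the workflow this package mirrors computes He directly from
read-count frequencies.  The bias factor is therefore a read-sampling
correction, not a pool-size correction; an alternative correction using the
haploid pool size (`heLocus(..., size = )`) is provided for users who
prefer the classical form.  Per-pool He averages the per-locus values over
non-missing loci; loci that are monomorphic after filtering contribute 0 by
default (the `drop_monomorphic` flag excludes them instead — the upstream
convention is not documented, so both are first-class).

Total diversity `H_T` of any pool set sums read counts element-wise across
pools first and applies the same per-locus formula to the summed column.
The realized diversity of a designed mixture (`mixtureHe()`) is exactly
this quantity over its five members.

## The pool-seq FST estimator

Pairwise differentiation uses an analysis-of-variance (probability of
identity) estimator built for pooled reads.  Within a pool of `n` haploid
genomes, the probability that two *distinct* reads carry the same allele is

$$D = \frac{\sum_a c_a(c_a-1)}{c(c-1)}, \qquad
E[D] = \frac{1}{n} + \left(1-\frac{1}{n}\right) Q_1,$$

because two reads re-sample the same gene copy with probability `1/n`.
Solving gives the unbiased within-pool identity
$\hat Q_1 = (nD - 1)/(n - 1)$.  Between pools, reads are independent, so
$\hat Q_2 = (c_{ref,1} c_{ref,2} + c_{alt,1} c_{alt,2})/(c_1 c_2)$ is
directly unbiased.  The multilocus estimate is the ratio of sums

$$\hat F_{ST} = \frac{\sum_l (\bar Q_{1,l} - \hat Q_{2,l})}
{\sum_l (1 - \hat Q_{2,l})}.$$

Negative estimates are retained, never truncated: they are the expected
behaviour of an unbiased estimator near zero differentiation, and
truncation would bias range-level means and the Welch comparison between
ranges.  Note one consequence of the `1/n` correction worth knowing:
feeding the estimator two *copies of the same library* (identical count
columns) yields about `-1/(n-1)`, not 0, because a duplicated library is
not two independent samples of the population.  "No differentiation" means
two independently pooled, independently sequenced samples from the same
population — for which the estimator is centred on zero (this is what the
tests assert).

The simulator provides the calibration truth: a Beta island model in which
each deme's frequency has mean `p` and variance `F p (1-p)`.  Under that
model the parametric `F` is exactly the quantity the estimator targets, so
estimator validation is a direct truth comparison, not a
reference-implementation comparison.  We chose the Beta model over a
coalescent simulation for speed and because it makes `F` analytic; it has
no linkage, no mutation-model realism, and exchangeable demes — adequate
for calibrating a frequency-based estimator, inadequate for anything
sequence-level.

## SNP filtering

Two stock tiers mirror a tiered ddRAD workflow: a preliminary tier
(biallelic SNPs only, indels removed, locus missingness `< 66%`, minor
allele count ≥ 3, per-observation depth ≥ 20, pools dropped above 75%
missingness, one SNP per contig) used to design mixtures, and a final tier
(missingness `< 50%`, depth ≥ 40) for the statistics reported on the
finished experiment.  Interpretation choices, all recorded in the
`FilterReport`:

* *Minor allele count* is evaluated on read counts summed across pools —
  pool-seq has no genotype-level allele counts.
* *Depth below threshold* converts the observation to missing rather than
  dropping the locus, which is what makes the per-pool missingness rule
  meaningful.
* Thresholds are strict as phrased: "less than 66%" keeps
  `missing < 0.66`; "more than 75%" drops `missing > 0.75`.
* Of a multi-SNP contig the first SNP by position is kept (deterministic).
* Because dropping pools changes locus missing fractions and vice versa,
  the locus- and pool-level rules are iterated to a fixed point (and again
  after contig thinning).  A single linear pass is not idempotent — a
  second application could remove further loci — and idempotence
  (`filter(filter(x)) == filter(x)`) is a property we consider
  non-negotiable for a reported SNP panel.

## Designing the diversity gradient

All `C(n, 5)` candidate mixtures per origin are enumerated and scored by
the mean of their 10 pairwise FST values — the prediction of mixture
diversity available *before* any mixture is sequenced.  Selection divides
the observed score range into `m` equal-width bins and draws one candidate
uniformly per bin (seeded), sweeping bins from low to high, so the full
gradient is covered; empty bins are backfilled from the nearest occupied
bin, and a degenerate (constant-score) candidate set falls back to simple
random sampling with a warning.  The exact stratification protocol of the
original study is described only in its supplement, so this package's
default is our own minimal deterministic construction; the procedure is a
plain function and can be swapped.  Source populations may recur across
selected mixtures (observed He ranges imply they did); `max_reuse` caps
recurrence when desired.

Both the predicted score (mean pairwise FST) and the realized He (from
summed read counts) are kept on every mixture: selection operates on the
former, downstream inference on the latter, and conflating them would hide
the fact that they are different quantities on different scales.

Seed manifests allocate `k × seeds_per_population` seeds (default
5 × 20 = 100) equally across populations and, within a population, equally
across maternal plants, remainder to the lowest indices (deterministic).
`expandDesign()` crosses mixtures × microsite levels × replicates into the
unit table (15 × 2 × 3 × 3 = 270) with a seeded placement permutation.

## Monitoring statistics

Censuses assign every individual to one of ten classes: six vegetative
size classes (I cotyledons; II–VI by longest-leaf length with breaks at 1,
4, 8 and 12 cm) and four generative stages (VII bolting to X seed set).
Three log-ratio statistics summarise a census, all with +1 offsets so they
are finite for any record including the empty one:

* size-class ratio: `ln((N_II+…+N_VI+1)/(N_I+1))` — development beyond the
  cotyledon stage;
* rosette-size ratio: `ln((N_V+N_VI+1)/(N_I+…+N_IV+1))` — the 8 cm split;
  bolting classes are no longer rosettes and enter neither side;
* life-stage ratio: `ln((N_VII+…+N_X+1)/(N_I+…+N_VI+1))`.

Only the first formula is displayed in the source study; the other two
reuse its construction, which we flag as an interpretation.  Individuals
whose inflorescences were removed at seed set remain counted in class X.

## The statistical layer

Realized He is z-standardized *within origin* (sample SD, `n−1`) before
modelling, because the native and invasive mixtures span very different He
ranges; the standardized gradient is the `GD` covariate.  All models use
the fixed-effects structure `GD * MSA * Origin` (all interactions up to the
three-way term); a seed-size covariate (average projected seed area, a
maternal-effect proxy) is included for the establishment phase (weeks ≤ 4).
Replicates are treated as independent units — the source analysis names
"(generalized) linear effects models" but describes only fixed effects,
and we follow that, documented as a simplification.

* **Counts** (individuals per unit): quasi-Poisson GLM — log-link Poisson
  score equations with dispersion `φ = X²_Pearson/(n−p)` scaling the
  standard errors.  Point estimates equal Poisson estimates by
  construction.
* **Size statistics**: Gaussian LMs per monitoring date.
* **Zero-inflated Gamma** for responses that are zero when a unit failed
  to establish (harvest biomass; the non-negative mean rosette size in the
  mid-experiment weeks): with probability `π(z)` — logit-linear in the
  microsite treatment — the response is exactly zero, otherwise Gamma with
  log-link mean.  Because a Gamma variable cannot be zero, the likelihood
  factorises exactly, and the joint MLE is computed as a Bernoulli GLM on
  the zero indicator plus a Gamma GLM on the positives (shape by ML).  No
  iterative joint optimisation, no convergence tuning; with no zeros the
  fit *is* the Gamma GLM.  The tests cross-check the factorised fit
  against an independent joint-likelihood implementation (glmmTMB) to
  coefficient agreement of 1e-4.

A caveat follows from the factorised zi-Gamma: the log-ratio size
statistics can be negative and are therefore not Gamma material.  The
zero-inflated weeks model a *non-negative* size outcome (per-unit mean
rosette size, zero when the unit holds no plants); the log-ratio statistics
keep their Gaussian LMs throughout.

ANOVA tables are Type II — Wald chi-square for GLMs, F for LMs — the
common companion of this model family; the statistic type is recorded in
every table.  Subset trends (the GD slope within one origin or one
microsite level) refit on the subset with the separating factor removed
from the formula; zero-inflated subsets use an intercept-only
zero-inflation term, since the factor explaining the zeros may be the one
subset on.  Post hoc contrasts are studentized-range (Tukey) adjusted
pairwise comparisons of estimated marginal means.

## The synthetic garden

`simulateGarden()` emulates the experiment with known effects: germinant
counts are negative-binomial with log-mean linear in `GD`, microsite,
origin and their configured interactions; units fail outright with
microsite-dependent probability `π(MSA)` after week 4 (the structural-zero
process the zi-Gamma attributes to microsite); survivors thin weekly and
drift through the size classes; mean size and biomass are Gamma with
log-link GD effects.  Default conditions are the experiment's own: 270
units, realized-He ranges 0.2377–0.2795 (native) and 0.2593–0.2676
(invasive), a baseline of ~40 germinants per 100-seed sample, moderate
overdispersion (NB size 8).  The generator does **not** emulate spatial
placement effects, within-unit competition, seasonal covariates, or
maternal effects (the seed-size column is by construction a null
covariate), so passing recovery tests demonstrates estimator correctness
under the stated generative model — not robustness to the full messiness
of real garden data.

## Numerical choices and problem sizes

Permutation Mantel tests are one-sided (positive association), default 999
permutations, add-one p `(1+k)/(n_perm+1)`, seeded and deterministic;
exhaustive enumeration replaces sampling only in the tests (n ≤ 6 labels).
Geographic distances are haversine with mean Earth radius 6371 km.
Welch's t comparison of pairwise FST values between ranges treats the
pairwise values as independent observations — they are not (each pool
appears in many pairs), and we keep the convention only because it mirrors
the analysis this package reproduces; read its p value accordingly.

Validation problem sizes were chosen to make Monte-Carlo error small
relative to the tolerance being asserted: FST calibration uses 5 pools ×
5000 loci × 10 replicates per F value (estimator bias is ~1e-3, tolerance
±0.01); model calibration uses 500 null replicates of the 270-unit design
(binomial SE on a 5% rate ≈ 1%); coefficient-recovery checks use 10–40
replicated gardens so the 3-SE criterion is sharp.

## Known limitations

* The FST estimator assumes equal contribution of every individual to the
  pool; unequal DNA contributions inflate apparent drift and are not
  modelled.
* He uses read counts as the bias-correction sample size; at depths below
  ~20 this correction is noticeably larger than the pool-size correction,
  which is why the depth filters matter before He comparisons.
* No mixed-effects machinery: block or temporal random effects are out of
  scope.
* The zero-inflated Gamma is a two-part (hurdle-type) model; it cannot
  represent sampling zeros from the Gamma process itself, which is the
  correct reading of establishment failure here but not of, say,
  measurement rounding to zero.
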