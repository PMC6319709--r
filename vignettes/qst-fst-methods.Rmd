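---
title: "Detecting adaptive divergence with qstkit: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adaptive divergence with qstkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstkit)
```

## The scientific problem

Common-garden experiments on structured plant populations ask whether
among-population differences in quantitative traits exceed what genetic
drift alone would produce.  The benchmark is the comparison of

* **Q_ST**, the proportion of additive quantitative-trait variance that
  lies among populations, `Q_ST = V_AP / (V_AP + 2 V_WP)`, and
* **F_ST**, the analogous proportion for neutral molecular markers.

`Q_ST > F_ST` indicates directional (diversifying) selection,
`Q_ST < F_ST` stabilizing selection.  qstkit implements this comparison
for a seed-family design: offspring of open-pollinated (here largely
selfed) maternal plants from many populations, raised under several
nitrogen-addition treatments.  The motivating system is *Juncus effusus*,
a predominantly selfing wetland rush whose central-German populations
fall into three strongly differentiated genetic lineages; the package
bundles that 22-population reference panel (`reference_populations()`)
for worked examples and end-to-end tests.

## Variance components: the Gibbs sampler

`estimate_qst()` fits the Gaussian mixed model

```
y = X beta + u_pop + u_family (+ u_family:treatment) + e
```

by a blocked Gibbs sampler (`fit_lmm_gibbs()`).  Fixed effects get a
joint conjugate normal update; each random-effect block is updated
level-wise, which is exact because every observation belongs to exactly
one level per block; variances get scaled-inverse-chi-square updates.
Three analysis modes mirror the study design: across treatments
(treatment fixed), per treatment, and per lineage (lineages with fewer
than four populations are refused — a two- or three-population lineage
cannot support an among-population variance).

Decisions the data could not make for us, and how we made them:

* **Priors.**  Weakly-informative inverse-gamma (shape = scale = 0.001)
  on every variance, the conventional default of Bayesian mixed-model
  software for this tier of problem; fixed effects are flat.  With 22
  populations and ~100 families the likelihood dominates; with very few
  groups the prior matters and the sampler exposes `priors=` for
  sensitivity analyses.
* **Chain defaults.**  13,000 iterations, 3,000 burn-in, thinning 10 —
  exactly 1,000 retained draws, so that one retained draw maps to one
  neutral simulation draw downstream.  Reduced chains (e.g. 1,300/300/5
  for 200 draws) are used in the package's own simulation studies to
  keep hundreds of replicates tractable; the posterior-median summaries
  they feed are insensitive to this choice (doubling the burn-in moves
  medians by less than one Monte-Carlo SE).
* **V_WP definition.**  The within-population additive variance is the
  seed-family component only.  The family × treatment interaction, when
  modelled, is *not* counted in V_WP (toggle `count_fxt_in_vwp`),
  because the interaction variance reflects plasticity of family
  rankings, not standing additive variance within populations.
* **Every Q_ST draw lies in [0, 1] by construction** since both
  variance draws are positive; no clipping is ever needed on the
  Bayesian path.  On the REML path (pairwise matrices, below),
  boundary-zero components are used as estimated.

REML (`fit_lmm_reml()`, via lme4) serves the trait-response analyses
(treatment and lineage fixed effects with `posthoc_contrasts()`:
Holm-adjusted pairwise comparisons through emmeans) and cross-checks
the sampler: on balanced designs REML equals the closed-form ANOVA
components, and posterior medians agree with REML within sampling error.

## The neutral null and the difference test

`simulate_neutral_qst()` draws, for each posterior draw *i*,

```
Vnp_i = F_ST * (2 * V_A_i / (1 - F_ST)) * r_i / (n_pop - 1),   r_i ~ chi2(n_pop - 1)
Qnst_i = Vnp_i / (Vnp_i + 2 * V_WP_i)
```

The chi-square factor injects the sampling variance of an
among-population variance estimated from `n_pop` populations.  V_A is
taken equal to the seed-family variance draws (multiplier 1): under
random mating the family variance is a fraction of V_A, and under full
selfing it can exceed V_A/2, so the conventional equality is a
compromise the `v_a_multiplier` argument makes explicit.
`qst_fst_test()` forms index-paired differences `Qst_i - Qnst_i` (the
draws are independent, so the pairing is arbitrary but shares the V_WP
draw, which removes one common noise source) and applies the
CI-excludes-zero rule on the equal-tailed 95% interval (an HPD interval
would differ negligibly for these unimodal distributions).
`run_qstfst_suite()` recomputes F_ST on exactly the population subset
entering each mode — a treatment subset or a lineage has its own
differentiation level — and negative theta estimates are clipped to zero
before simulation, where the formula is otherwise undefined.

**Known property: the test is mildly conservative.**  The posterior
spread of V_AP and the chi-square factor of the neutral simulation both
contain the among-population sampling variance, so the difference
distribution is over-dispersed relative to the sampling distribution of
its median.  The package's closed-loop calibration (500 neutral
replicates at 10 populations × 4 families × 4 offspring, 200 draws)
measures a rejection rate of 0.03–0.04 at nominal 0.05; sensitivity runs
with longer chains give similar values.  Verdicts of "directional" or
"stabilizing" are therefore, if anything, understated.

## Molecular statistics

* `expected_heterozygosity()`: per-locus unbiased gene diversity
  `(2n/(2n-1)) (1 - sum p^2)`, averaged over the loci genotyped in the
  population.
* `fst()`: multilocus Weir–Cockerham theta as the ratio of summed
  variance components over alleles and loci — never a mean of per-locus
  ratios.  Theta is the estimator FSTAT-style software reports, hence
  the default; a classic Nei G_ST partition is available
  (`method = "gst"`) for sensitivity.  Loci monomorphic across the
  compared groups are dropped (they contribute 0/0 components); negative
  per-locus components stay in the sums; small negative multilocus
  estimates are reported as computed and only clipped when fed to the
  neutral simulator.  Between-lineage differentiation pools individuals
  per lineage (two-group theta); `hierarchical_fst()` offers the
  population-aware nested-ANOVA alternative (F_CT).
* `genotypic_distance()` and `pcoa()`: squared Smouse–Peakall codominant
  distances (`0.5 * ||y1 - y2||^2` on allele-count vectors, reproducing
  the 0/1/2/3/4 scheme) and Gower-centred principal coordinates, with
  negative eigenvalues reported rather than dropped.
* `assign_lineages()`: argmax cluster when max Q exceeds 0.7 (strict
  inequality), else "admixed"; population-level calls use the
  population's mean Q-vector.  Q-vectors are validated to sum to 1
  within ±0.05 to accommodate published rounded tables.

## Environment association

`soil_pca()` standardizes soil variables (constant columns are dropped —
they cannot be z-scored) and eigendecomposes the correlation matrix;
`trait_env_model()` regresses individual trait values on a population's
PC score with treatment fixed and lineage/population/family random
(per-treatment form: PC × lineage interaction fixed), optionally with
population mean seed mass as covariate; `pairwise_qst()` fits each
population pair by REML — tractable for the 231 pairs × traits of a full
panel, where per-pair MCMC would be prohibitive — flooring boundary
components at zero; `mmrr()` regresses the z-scored unfolded lower
triangle of the trait-differentiation matrix on environmental and
molecular distance matrices, with Mantel-style joint row/column
permutation of the dependent matrix (9,999 permutations by default) and
`p = (#{|t_perm| >= |t_obs|} + 1) / (n_perm + 1)`, the observed
statistic counting on both sides.  Off-diagonal z-scoring (not
whole-matrix) makes coefficients comparable across predictors.

Geography is spherical: haversine distances on the IUGG mean radius
6371.0088 km.  At the regional scale of the panel (≤ ~220 km) the
difference from ellipsoidal geodesics is far below 1%.  Soil survey
points are aggregated to populations by a closed 15 km ball (boundary
points included).  Root porosity's species-specific weight constant is
not published with the underlying method; it ships as `k_specific = 1`
(reporting the raw relative weight gain) and is documented as a
configuration parameter.  Seed volume treats the seed as a prolate
spheroid — length as major axis, width as both minor axes — the natural
reading of an "ellipsoid" from two measured dimensions.

## The synthetic-data generator

Because the raw genotypes and soil extracts behind the reference panel
are not distributable, every analysis stage is exercised on synthetic
data with the panel's statistical structure (`sim_design()` defaults):
22 populations in lineages 8/11/3, 4–6 families per population, three
treatments with the panel's unbalance (all populations at T0, 12 at
T70, 16 at T150), 4 offspring per family × treatment, 16 loci with up to
5 alleles (the panel carries 74 alleles over 16 loci), target F_ST 0.66,
selfing rate 0.95 (the species is predominantly selfing; the exact rate
is not critical — it enters only through within-individual
homozygosity).  Trait parameters default to grand mean 10, treatment
effects (0, 1, 2) residual-SD units, V_AP = V_WP = residual = 1 and
family × treatment 0.25 — a visible but not overwhelming nitrogen
response over a substantial nested genetic signal, the regime the
estimators must handle.

Genotypes follow a Dirichlet island model: population frequencies
`~ Dirichlet(p * (1 - F_ST)/F_ST)` have among-population variance
`p(1-p) F_ST`, giving an analytic link between the target and the
estimator — a coalescent simulator would model mutation and drift
history more faithfully but adds nothing for testing moment-based
estimators.  Selfing enters as the equilibrium inbreeding coefficient
`F_IS = s/(2-s)` (autozygous with probability F_IS), not as identity
disequilibrium across loci; that suffices for He, theta and distance
statistics, which are single-locus moments.  What the generator does
*not* emulate: stepwise mutation, linkage, demographic history,
non-Gaussian trait distributions, maternal effects, and
genotype-by-environment correlation beyond the optional linear cline —
so passing tests demonstrate estimator correctness under the model's
assumptions, not robustness to their violation.

The closed-loop calibration conditions each replicate's phenotypes on
that replicate's *estimated* theta, so the neutral relation the test
reconstructs is exactly the one that generated the data; conditioning on
the latent target instead would add theta estimation noise to both sides
and blur the calibration question.

## Numerical and degenerate-input choices

* Missing genotypes: both `0` (GenAlEx) and `-9` (STRUCTURE) normalise
  to `NA`; a half-missing diploid slot is treated as a missing locus
  call.
* Zero denominators in trait derivation warn and yield `NA`, never an
  error — a single empty pot must not kill a pipeline run.
* `pcoa()` refuses asymmetric input; eigenvalues within machine
  tolerance of zero get zero scores.
* Gibbs chains are bit-reproducible under a fixed seed; random-level
  updates consume RNG draws in sorted level order, so bit-identity under
  relabelling holds for order-preserving relabels (estimates are
  invariant in distribution generally, and exactly on the REML path).
* Problem sizes in the package's own simulation studies (500 calibration
  replicates at the reduced 10-population design; 200 recovery
  replicates at the full design with 1,300-iteration chains; 25-replicate
  REML/Gibbs agreement checks) were chosen once as the smallest designs
  that hold Monte-Carlo error comfortably below the asserted tolerances.

## Limitations

Gaussian responses only (no link functions, no pedigree/animal models);
Q_ST's factor 2 assumes the family variance represents within-population
additive variance on the conventional scale, which high selfing distorts
(see `v_a_multiplier`); the F_ST-based null inherits the marker's
properties — highly polymorphic microsatellites can understate
differentiation relative to SNPs, making the neutral bar easier to
clear; and the mild conservatism of the difference test noted above.
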