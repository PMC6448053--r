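---
title: "Heritability of value-added measures: models, simulator design and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability of value-added measures: models, simulator design and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Value-added (VA) measures of educational progress compare a pupil's
attainment at one key stage with their attainment at an earlier stage, and
are used to judge teachers and schools on the progress their pupils make
rather than on raw results. If a VA measure really controls for all
time-invariant differences between children, it should in particular be
robust to genetic differences: a child's genotype is fixed at birth, so none
of its influence on attainment can be credited to a school. SNP heritability
— the share of phenotypic variance attributable to measured common variants,
estimated by GREML on a genetic relatedness matrix (GRM) — is therefore a
direct audit statistic for VA measures: a heritable VA measure is, to that
extent, not measuring what schools add.

`vaherit` implements this audit end to end on synthetic cohorts: a
generator for genotyped school cohorts with configurable genetic
architecture, the three families of VA measures (raw, contextual, and
teacher-assessed), GREML with average-information REML, polygenic scoring,
and a measurement-error simulation study that reproduces the mechanism by
which *contextual* VA becomes more genetically loaded than raw VA when the
baseline score is measured with error.

## The estimation model

For a phenotype vector $y$ (always rank-based inverse-normal transformed
first, `int_transform()`), fixed covariates $X$ (an intercept plus the top
20 genotype principal components, the standard guard against population
stratification) and a GRM $A$ built from standardized dosages,

$$ y = X\beta + g + \varepsilon,\qquad
   g \sim N(0,\,\sigma_g^2 A),\quad \varepsilon \sim N(0,\,\sigma_e^2 I),
   \qquad h^2_{SNP} = \frac{\sigma_g^2}{\sigma_g^2+\sigma_e^2}. $$

The GRM entry for individuals $j,k$ averages
$(x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$ over SNPs non-missing in both,
with sample allele frequencies and pairwise missing-data exclusion; the
diagonal uses the usual within-individual estimator
$1+\tfrac1m\sum_i (x^2-(1+2p)x+2p^2)/(2p(1-p))$ (a plain
$(x-2p)^2$-based diagonal is available via `diagonal = "simple"`).

`fit_greml()` maximizes the restricted likelihood with an eigendecomposition
of $A$: since $V=\sigma_g^2A+\sigma_e^2I$ is diagonal in the eigenbasis of
$A$ for *every* parameter value, one $O(n^3)$ decomposition makes each
iteration — and each additional phenotype on the same cohort — cheap. The
optimizer runs two expectation-maximization warm-up steps, then
average-information (Newton-type) updates with step-halving whenever a step
would decrease the likelihood. Numerical choices:

* convergence: relative restricted log-likelihood change below `tol = 1e-8`,
  with `max_iter = 100`; non-convergence is flagged on the result, never
  silent;
* starting values $\sigma_g^2=\sigma_e^2=\mathrm{Var}(y)/2$ (scale-free
  after the rank transform);
* constrained mode (default): a component crossing zero is clamped to
  $10^{-6}\mathrm{Var}(y)$ and flagged. When a proposal crosses the floor,
  the offending component is fixed there and the *free* component takes a
  conditional Newton step; the joint step would otherwise keep dragging it
  through the information cross term and the iteration can cycle at the
  boundary;
* unconstrained mode is exposed because near-null heritabilities are
  censored by the constraint: the unconstrained estimate is unbiased around
  small truths (and can be negative, which is exactly how a null VA measure
  behaves in practice);
* standard errors by the delta method on $h^2$ from the inverse
  average-information matrix; intervals are $\pm 1.96\,SE$;
* the test of $\sigma_g^2=0$ is a boundary likelihood-ratio test against a
  50:50 mixture of a point mass at zero and $\chi^2_1$;
* a-priori power uses $SE(h^2)\approx\sqrt{2/(n^2\,\mathrm{var[offdiag]}(A))}$,
  with $\mathrm{var[offdiag]}\approx 1/m$ for $m$ independent SNPs.

## The value-added measures

* **Raw VA** (`raw_va()`): difference of cohort-standardized scores at the
  two occasions. Standardization is the same rank-based inverse normal
  transform used everywhere (the child's cohort rank is what matters); a
  mean/SD z-scoring variant is exposed via `method = "zscore"`.
* **Contextual VA** (`fit_cva()`): a two-level model with a school random
  intercept, fitted by REML (`lme4::lmer`),
  $y_{t_2}=\beta_0+\beta_1 y_{t_1}+\gamma'\mathrm{covariates}+u_{school}+e$,
  adjusting sex, free school meals, special educational needs, first
  language, mobility, in-care, ethnicity, month of birth (11 indicators) and
  area deprivation. The pupil's CVA is the deviation from the
  *fixed-effects* prediction, so it retains the school contribution plus the
  child residual — the quantity a school-effectiveness measure is meant to
  capture. A `mode = "residual"` alternative also subtracts the shrunken
  school effect. Because the fixed effects are generalized-least-squares
  estimates, exact orthogonality of the residual to the covariates holds
  only when the estimated school variance is zero (where GLS coincides with
  ordinary least squares); with school variance present it is approximate.
* **Teacher-assessed VA** (`tava()`): difference in the mean of the three
  integer subject levels (English, Mathematics, Science, scale 1-8) between
  occasions.

All analyses are complete-case per measure.

## What the synthetic cohorts emulate

`sim_config()` + `simulate_genotypes()` + `simulate_cohort()` generate, per
child: independent biallelic SNPs (ancestral frequencies uniform on the MAF
range; optional Balding-Nichols subpopulation structure with differentiation
$F_{st}$), a polygenic genetic value $G$ from `n_causal` SNPs with normal
effects, three key-stage scores, contextual covariates, school assignments,
and teacher subject levels. Each unit-variance score decomposes exactly into

$$ y_s=\sqrt{h^2_s}\,G+\sqrt{v_L-h^2_s}\,E_s+\sqrt{v_u}\,U+\sqrt{v_c}\,C^\perp $$

with $v_L=1-v_u-v_c$. Two constructions deserve explanation:

* **Confounded covariates, orthogonalized effects.** The observed
  covariates load on $G$ (free-school-meal, special-needs, in-care and
  mobility probabilities decrease in $G$ on the logistic scale; area
  deprivation is linearly $G$-correlated), scaled by
  `covariate_confounding`. Their *effect* on the score, however, enters
  through the $G$-orthogonalized composite $C^\perp$. This keeps the
  configured variance shares exact (so `h2_target = 0` is a genuine null)
  while preserving the mechanism under study: adjusting $G$-correlated
  covariates in a contextual model re-introduces genetic variance into the
  residual.
* **Persistence as a Markov environmental chain.** The environmental
  components follow $E_{s+1}=\kappa_s E_s+\sqrt{1-\kappa_s^2}\,\xi$, with
  $\kappa_s$ solved so that the *latent-ability* correlation between
  adjacent stages equals `persistence` exactly. Requiring the same
  correlation for all three pairs simultaneously is infeasible once the
  shared genetic covariance between the two later stages exceeds the
  persistence budget, which it does at the default heritability profile, so
  adjacent-pair correlations are the definition.

The observed KS2 score additionally receives independent Gaussian noise of
variance `baseline_error_var` — in phenotype-variance units, so `0.25` means
a quarter of the unit score variance. KS2 is the baseline of the age 11-14
progress measures, which are the canonical pair throughout.

**Teacher ratings.** Raters see the child's realized (error-free) score, not
just latent ability — that is what places the rating/score correlation in
the empirically reported 0.88-0.92 band — plus subject-specific noise
(`teacher_noise_var`) and a shared rater-bias term of variance
`teacher_bias_var`. The bias is *heritable but occasion-specific*: each
occasion's raters key on a different heritable "appeal" trait built from an
independent effect draw over the causal SNPs. This matters: a bias
proportional to the attainment genetic value itself would cancel when the
two occasions are differenced, and teacher-assessed VA would come out *less*
heritable than raw VA. Occasion-specific heritable bias — different teachers
at ages 11 and 14 responding to different heritable characteristics — is the
mechanism that makes teacher-assessed progress measures genetically loaded.
Ratings are binned into `n_levels` equal-probability (sample-quantile) bands
mapped to integers; with zero noise and bias the binning is a deterministic
monotone coarsening.

## Calibration of the generator defaults

The defaults are the package's operating point for the measurement-error
study, and were fixed once, before any acceptance testing, by a large-n
latent-variable Monte Carlo of exactly the generating equations above
(genotypes replaced by $G\sim N(0,1)$, which is all that matters at the
population level). The calibration searched a coarse grid over the stage
heritabilities, persistence, confounding and variance shares for the
configuration whose *implied population values* of raw-VA and contextual-VA
heritability at baseline error 0.25 best match the regime this package is
designed to exhibit — raw VA near 10% and contextual VA near 17%, with
contextual above raw. The result:

| parameter | default | note |
|---|---|---|
| `h2_target` | (0.35, 0.55, 0.60) | attainment heritability rising with age |
| `persistence` | 0.82 | latent-ability correlation, adjacent stages |
| `school_var_share` | 0.10 | school intercept share |
| `covariate_var_share` | 0.10 | contextual covariate share |
| `covariate_confounding` | 0.7 | strong gene-environment correlation |
| `baseline_error_var` | 0.25 | the headline error condition |
| `teacher_noise_var`, `teacher_bias_var` | 0.25, 0.10 | rating fidelity band + heritable bias |
| `n_individuals`, `n_snps`, `n_causal` | 5000, 5000, 1000 | desk-scale cohort |

Two analytic facts shaped this calibration and are worth recording. First,
raw VA subtracts the standardized noisy baseline with coefficient 1, so its
genetic loading is $\sqrt{h^2_2}-\lambda\sqrt{h^2_1}$ with
$\lambda=1/\sqrt{1+\mathrm{error}}$: with *equal* stage heritabilities the
error-0.25 signal is of order 1%, an order of magnitude below the regime of
interest — a rising heritability profile is required, and is also what real
attainment data show. Second, the contextual model estimates the baseline
coefficient by regression, and measurement error attenuates it below
$\lambda$, so contextual VA always retains more genetic variance than raw
VA; how much more is governed by persistence (which raises the regression
coefficient) and by confounding (the adjusted covariates absorb part of the
genetic variance back out of the residual).

## The measurement-error experiment

`run_measurement_error_experiment()` simulates cohorts, builds raw and
contextual VA on a baseline carrying each error variance in the grid, and
estimates GREML heritability for each measure with 20 PC covariates. By
default (`paired = TRUE`) one cohort, GRM and eigendecomposition per
replicate are shared across the error grid, and a single standard-normal
error draw is scaled by $\sqrt{v}$: common random numbers make differences
*between* grid points far more precise at a fixed replicate budget, which is
what a monotonicity-in-error claim needs. `paired = FALSE` gives fully
independent cohorts with replicate seeds `seed + 1000*grid_index +
replicate`. Non-converged fits are excluded from summaries and counted,
never imputed.

Near the null the constrained estimator censors at zero, which masks
sub-percentage-point trends in grid means; the experiment therefore exposes
`constrain = FALSE`, and the monotonicity property is assessed on
unconstrained estimates. Relatedly, the GREML sampling SD is approximately
$\sqrt{2m/n^2}$ for $m$ independent SNPs — *fewer* SNPs give a larger GRM
off-diagonal spread and a tighter estimator — so the trend analysis in the
test suite runs at $n=3000$, $m=500$ where the estimator SD is about 1%.

## Polygenic scoring

`align_weights()` harmonizes a per-allele weight table against the genotype
coding (swapped allele pairs become negated weights plus a $2w$ offset;
unresolvable variants are dropped with a warning), `compute_pgs()` sums
weighted dosages with mean imputation ($2p_iw_i$) for missing calls, and
`incremental_r2()` reports the OLS $R^2$ increment of the score over the
covariates on the transformed phenotype. Because the real discovery-GWAS
weight table is external to any simulation, `synthetic_gwas_weights()`
builds a synthetic stand-in: the 74 causal SNPs with the largest per-allele
effects, plus Gaussian estimation noise. At the default architecture of
1000 causal SNPs, those 74 carry a material fraction of the genetic
variance, so incremental $R^2$ values run percentage points rather than the
sub-1% magnitudes reported for real 74-variant scores — real architectures
spread heritability over orders of magnitude more variants than a
5000-SNP simulation can. The orderings (score $R^2$ far below GREML $h^2$;
raw VA below contextual VA below attainment) are the transferable
properties.

## Problem sizes and runtime posture

The package works at "desk scale". The test suite uses cohorts of 300-3000
children with 300-5000 SNPs and 8-30 replicates per Monte-Carlo claim; the
`scripts/acceptance.R` study runs the error-0.25 experiment at $n=4000$,
$m=4000$ with 20 replicates (mean standard errors near half a percentage
point), a full ten-measure analysis of one default cohort, null and
recovery calibrations, and the power approximation. One GRM
eigendecomposition per cohort is reused for principal components and for
every REML fit on that cohort.

## What passing tests do and do not show

The simulator reproduces the *statistical structure* the analyses assume:
independent SNPs (no linkage disequilibrium), exact variance shares,
Gaussian school and environment components, missingness only as an optional
missing-at-random mask, and no imputation uncertainty, dynastic effects,
assortative mating, sibling structure or selective participation. Passing
tests therefore validate the estimators and the measurement-error mechanism
on data satisfying the model's assumptions; they say nothing about
violations (uneven linkage disequilibrium, genetic nurture, residual
stratification) that complicate real-cohort heritability estimates. The
real-data point estimates quoted in the literature (attainment
heritabilities near one half, contextual VA near one fifth, teacher VA near
one third) come from restricted cohort linkages and are used here only as
qualitative regime bands for the simulator defaults, never as reproduction
targets.

## Known limitations

* The KS2 score is the only baseline that carries `baseline_error_var`;
  analyses of the KS3→KS4 pair use an error-free baseline by construction.
* The equal-pairwise persistence construction is infeasible at high
  heritability profiles (validated with a clear error); adjacent-pair
  persistence is the supported definition.
* CVA orthogonality to covariates is exact only under a zero school-variance
  fit (GLS = OLS).
* Greedy relatedness pruning matches the exhaustive optimum on the planted
  structures tested, but is a heuristic in general.
* With `n_subpops > 1`, drifted loci can be monomorphic in-sample; QC
  (`qc_filter()`) is the supported route before GRM or PCA construction,
  and the causal-effect generator draws only from polymorphic sites.
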