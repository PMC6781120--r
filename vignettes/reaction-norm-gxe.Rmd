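---
title: "Genotype-by-environment interaction with single-step genomic reaction norm models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-by-environment interaction with single-step genomic reaction norm models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrnm)
```

## The model

Dairy fertility traits are recorded across herds that differ strongly in
management, feeding and health care. When the ranking of sires depends on
the herd environment, selection decisions made in one environment do not
carry over to another: genotype-by-environment (G×E) interaction. `ssrnm`
implements a reaction norm analysis of this problem in which every
animal's breeding value is a linear function of a continuous environment
descriptor (the *environmental gradient*, EG):

$$ y = Xb + Ff + Z_0 a_0 + Z_1 a_1 + Ec + Wpe + e, $$

where $f$ are fixed herd effects, $a_0$ (intercept) and $a_1$ (slope) are
correlated additive-genetic effects with
$(a_0, a_1) \sim N\!\left(0,\; \Sigma \otimes K\right)$,
$\Sigma = \begin{pmatrix}\sigma^2_{a_0} & \sigma_{a_0a_1}\\
\sigma_{a_0a_1} & \sigma^2_{a_1}\end{pmatrix}$, $c$ are herd-year effects,
$pe$ permanent environmental effects, and $Z_1$ carries the estimated herd
effect of each record as a covariable. $K$ is either the pedigree
relationship matrix $A$ or the combined pedigree–genomic matrix $H$ of
single-step GBLUP, whose inverse is

$$ H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
\end{pmatrix}, $$

with $G = (1-\omega)G_0 + \omega A_{22}$ blended from the marker-based
(VanRaden) matrix $G_0 = ZDZ'/\sum_i 2p_i(1-p_i)$ and rescaled so that its
mean diagonal and overall mean match $A_{22}$ (two-moment compatibility
adjustment). The blending default $\omega = 0.2$ represents the fraction
of genetic variance not captured by markers and guarantees that $G$ is
invertible.

### The three-step procedure

Estimating the EG and the reaction norm simultaneously is expensive and
fragile, so the analysis is split into three steps:

1. **Step 1** fits the model without the slope term, with herds as fixed
   effects, by AI-REML. The estimated herd effects (estimable contrasts,
   centred to mean zero) become the EG.
2. **Step 2** ranks herds by their estimated effects, cuts them into five
   groups at the record-weighted 10/30/70/90% quantiles, and re-runs the
   step-1 model as a Gibbs sampler with a separate residual variance per
   group. Group weights
   $w_i = \sum_i n_i\sigma^2_{e_i} \big/ \big(\sigma^2_{e_i}\sum_i n_i\big)$
   turn the heterogeneous variances into per-record weights that preserve
   the record-weighted mean residual variance.
3. **Step 3** fits the reaction norm model with the step-1 herd effects as
   the covariable and residual covariance $\mathrm{diag}(1/w_i)\sigma^2_e$,
   together with the reduced model (RM, no slope) on identical data and
   weights, so that the likelihood-ratio statistic
   $D = 2(\ell_{RNM} - \ell_{RM})$ tests exactly the G×E term. Because the
   slope variance sits on a boundary under the null, the p-value uses the
   50:50 mixture $\tfrac12 P[\chi^2_1 \ge D] + \tfrac12 P[\chi^2_2 \ge D]$.

From a fitted model, the package reports the genetic variance
$\sigma^2_a(f) = \sigma^2_{a_0} + \sigma^2_{a_1}f^2 + 2\sigma_{a_0a_1}f$,
the heritability $h^2(f) = \sigma^2_a(f) / (\sigma^2_a(f) + \sigma^2_{pe} +
\sigma^2_e/w)$ (herd-year variance excluded from the denominator, and the
group weight $w$ making $h^2$ piecewise-continuous along the gradient),
genetic correlations between two gradient values
$r(f_1,f_2) = \mathrm{cov}(f_1,f_2)/\sqrt{\sigma^2_a(f_1)\sigma^2_a(f_2)}$
with $\mathrm{cov}(f_1,f_2) = \sigma^2_{a_0} + \sigma_{a_0a_1}(f_1+f_2) +
\sigma^2_{a_1}f_1f_2$ (the unique consequence of the linear reaction
norm), and the intercept–slope correlation
$\sigma_{a_0a_1}/\sqrt{\sigma^2_{a_0}\sigma^2_{a_1}}$.

### Prediction and the single-step GWAS

A bull's usable breeding value combines intercept and slope at the mean
EG of its daughters' herds, $\hat a = \hat a_0 + \bar f \hat a_1$ (record-
count weighted; $\bar f = 0$ for animals without daughters). Forward
prediction is validated against daughter yield deviations (DYD): the mean
daughter performance adjusted for all fixed effects, herd-year and
permanent environment, and half the dam's breeding value, over records
excluded from the training fit. Accuracy is the Pearson correlation
cor(DYD, prediction) over the held-out (youngest 20%) sires. DYD is kept
on the daughter-deviation scale rather than doubled to transmitting
ability; correlations are scale-free, so comparisons are unaffected.

The single-step GWAS back-solves marker effects from the genomic breeding
values of the genotyped animals, $\hat u = DZ'(ZDZ')^{-1}\hat a$,
re-weights markers by $D_{ii} = \hat u_i^2\, 2p_i(1-p_i)$ (normalised so
the implied genetic variance stays constant), rebuilds the weighted $G$,
and repeats for three iterations; in the last iteration intercept and
slope effects are back-solved separately from $\hat a_0$ and $\hat a_1$
and aggregated into non-overlapping 20-SNP windows per chromosome
(leftover markers merge into the last window), each reported as the
percentage of the REML intercept or slope variance its genetic values
explain.

## Numerical design

*Mixed-model machinery.* All models are solved through sparse Henderson
mixed-model equations (`Matrix`). Fixed effects use drop-first treatment
coding; cross-factor aliasing (e.g. a year level implied by parity in a
single-generation design) is removed by pivoted QR. The intercept+slope
term is stored component-major as $\Sigma^{-1} \otimes K^{-1}$. The slope
covariable is standardized internally for conditioning — an exact
reparameterisation; components, standard errors and solutions are
transformed back to the raw covariable scale on output.

*REML.* Variance components are estimated by average-information (AI)
REML. The AI matrix comes from working vectors (one mixed-model solve per
parameter); exact first derivatives and EM updates use a sparse selected
inverse of the coefficient matrix computed by the Takahashi equations
over the simplicial Cholesky factor (a compiled kernel). AI proposals are
kept inside a trust region, fall back to step-halving and then to EM
(monotone in exact arithmetic; a part-way step guards against numerical
degradation), and the trajectory of the restricted likelihood is
non-decreasing up to a 1e-6 tolerance. Variances drifting to zero — an
already-small variance whose AI proposal turns negative while its
gradient points outward — are pinned at $10^{-8}$ times the phenotypic
variance and flagged as boundary estimates; a pinned slope variance also
zeroes and freezes its covariance, keeping $\Sigma$ positive definite.
Convergence requires a relative parameter change below `1e-8` and a
(projected) gradient norm below `1e-6`. Because the reduced model is
nested in the reaction norm model, step 3 refits the latter from the
reduced-model optimum with the slope variance at the boundary whenever
its likelihood lands below the reduced model's, which preserves the
nested-likelihood ordering that the LRT needs.

*Gibbs sampler.* Step 2 uses a compiled single-site sampler: every
location effect is updated from its scalar full conditional, then each
random-term variance and each group residual variance is drawn from its
scaled-inverse-chi-square full conditional under flat priors (all
components are re-sampled, not only the residual groups). Defaults are
20,000 rounds, 5,000 burn-in, thinning 10; the bundled studies use
6,000/1,500/5, which at their data sizes gives Monte-Carlo errors well
below the posterior spread. Groups with fewer than 50 records are
flagged; posterior means of single-herd groups are noticeably inflated
under flat priors, one reason the quantile grouping uses record-weighted
cuts.

*Back-solving marker effects.* Because $Z$ is centred at allele
frequencies computed from the genotyped animals themselves, $ZDZ'$ always
carries the ones-vector in its null space (rank $n-1$): the inverse is an
eigenvalue-truncated pseudo-inverse, exact on the range space, and the
projection identity $Z\hat u = \hat a$ holds for mean-centred breeding
values — the overall mean is not attributable to centred marker
covariates.

## The synthetic-data generator

Real fertility data of this kind are proprietary, so the package ships a
generator with known truth (`sim_config()`, `simulate_gxe_data()`). It
emulates: a multi-generation paternal half-sib pedigree with exactly
balanced sexes; gene dropping of unlinked biallelic markers from
Hardy-Weinberg founders (allele frequencies Uniform(0.05, 0.95)); true
intercept/slope breeding values built from per-marker bivariate effects
and rescaled so the founder (co)variances match the configuration
exactly; normally distributed herd effects acting as the EG (the model
itself assumes nothing about their distribution); herd-year and permanent
environmental effects; group-wise heteroskedastic residuals with groups
cut at the record-weighted quantiles of the true herd effects; records in
up to three parities for every non-founder female; and right-censoring
flags (the censoring penalty is applied by `edit_records()`, mirroring
the editing order of routine evaluation). Slope QTL receive large effects
that jointly account for half the slope variance, and each also carries
the intercept effect implied by regressing intercept on slope
($\sigma_{a_0a_1}/\sigma^2_{a_1}$ times its slope effect): fertility
reaction norms show strongly negative intercept-slope correlations, so
top slope regions are expected to be pleiotropic, with shared windows
acting in opposite directions.

What the generator does *not* emulate: linkage disequilibrium beyond
cosegregation on the pedigree, selection, multiple correlated traits, or
the scale of routine evaluations (hundreds of thousands of records,
progeny groups of hundreds of daughters). Passing tests therefore
demonstrate correctness of the machinery and qualitative behaviour of the
procedure, not real-data effect sizes.

One consequence of scale is the herd-year editing rule: routine editing
merges and discards herd-year classes with fewer than 20 records, which
presumes several hundred records per herd. The generator produces about
25, so the bundled studies use `edit_rules(herd_year_min = 5)`; with the
routine minimum, merging collapses herd-year to one level per herd,
confounds it with the fixed herd effect and corrupts every variance
component. The default rules keep the routine thresholds, which the unit
tests exercise on constructed records. Likewise, the synthetic trait
`"SIM"` is unit-scale with censoring flags but a zero penalty and
unbounded values, so that the generated variance structure stays exactly
at the configured truth; the penalty and bound mechanics are tested on
the real traits' rules.

## The bundled studies

Four replicate studies (in `R/experiments.R`) fix the problem sizes used
by the test suite and the acceptance script:

* **Recovery** (`gxe_recovery_replicate`): the default population — 2,000
  animals in a three-generation half-sib design, ~1,200 records, 50
  herds, $\Sigma = (1.0, -0.3, 0.2)$, pe 0.3, herd-year 0.2, residual
  groups 0.8–1.2. Each REML component is compared with truth on the scale
  of its AI standard error. Two behaviours of the procedure itself are
  visible here: the step-2 group variances of extreme-EG groups absorb
  the G×E variance the step-1 model ignores, and regressing on estimated
  (rather than true) herd effects attenuates the slope variance somewhat;
  both are properties of the three-step design, and the estimates stay
  within their standard errors at this scale. In a minority of replicates
  the weighted reaction norm collapses onto the reduced model (slope
  variance pinned at zero): near the positive-semi-definite edge of the
  2x2 block the restricted likelihood is extremely flat, and the
  estimator then conservatively reports no G-by-E; a restart from a
  G-by-E-present configuration is attempted automatically whenever the
  slope variance lands on the boundary.
* **LRT calibration** (`lrt_replicate`): ~930 animals, 25 herds,
  homoskedastic residuals; with the slope variance at zero the mixture
  test keeps its size, with 0.2 it rejects in most replicates (the study
  seeds give 8/10; power at this scale is near that edge).
* **ssGWAS power** (`ssgwas_replicate`): 2,000 SNPs, 300 genotyped sires
  (three generations of 100, six matings each), one major pleiotropic
  slope QTL carrying half the slope variance. The QTL's 20-SNP window is
  expected in the top 10 slope windows; at this family size the sire
  slope EBVs have accuracy ≈ 0.45, and QTL below roughly 20% of the slope
  variance are beneath detection — a scale limitation, not a property of
  the method.
* **Forward prediction** (`accuracy_replicate`): ~1,200 animals with the 50
  sires genotyped, youngest 20% of sires held out; accuracies
  cor(DYD, prediction) for the pedigree and single-step reaction norm are
  compared. The genomic margin at this scale is small and noisy (ten
  validation sires); it is directional, not a quantitative reproduction
  of real-data accuracies.

## Worked example

```{r example, eval = FALSE}
set.seed(21)
cfg <- sim_config(seed = 21)
sim <- simulate_gxe_data(cfg)
data <- edit_records(sim$phenotypes, edit_rules(herd_year_min = 5))

res <- run_gxe_pipeline(sim$pedigree, sim$phenotypes, kinship = "A",
                        rules = edit_rules(herd_year_min = 5))
res$rnm
gxe_summary(res$rnm, res$data)
```

## Known limitations

Beyond the generator's simplifications listed above: no higher-order
(quadratic) reaction norms; no heteroskedastic-residual model beyond the
five-group weighting; no Taylor-series standard errors for heritabilities
and genetic correlations along the gradient (significance flags for
between-environment correlations are omitted rather than approximated);
no multi-trait REML; single-chain Gibbs only; and no large-scale
approximations of the H inverse, so the genotyped block is handled
densely.
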