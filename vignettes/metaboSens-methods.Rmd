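---
title: "Predicting sire-family heat-stress sensitivity from thermoneutral plasma metabolomes: models and methods"
author: "metaboSens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaboSens methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboSens)
```

## The problem

Chronic heat stress depresses feed intake and growth in pigs and raises
body temperature, and the severity of the response differs between sire
families — a genotype-by-environment interaction that matters wherever
breeding stock raised in temperate nucleus herds is exported to hot
climates. Measuring that sensitivity directly requires phenotyping each
family's offspring in both a temperate (TEMP) and a tropical (TROP)
environment, which is slow and expensive. metaboSens implements a
two-part alternative: (i) quantify each family's realized sensitivity
from two-climate phenotypes with a composite index, and (ii) learn to
predict that sensitivity from plasma ^1^H-NMR metabolome profiles
collected *in the thermoneutral environment only*, so that future
candidates can be screened from a single blood sample.

The data model is a `HeatStudy`, a `SummarizedExperiment` whose assay is
the bucket table (0.01-ppm integrated spectral regions, one column per
animal, each spectrum normalized to unit total area) and whose `colData`
carries the design (sire family, climate, batch, sex) and seven traits:
average daily feed intake (ADFI, kg/d), body weight (BW, kg), rectal
temperature (RT, degC), average daily gain (ADG, g/d), feed conversion
ratio (FCR, kg/kg), average backfat thickness (ABFT, mm) and skin
temperature (ST, degC).

## Nuisance adjustment and its audit

Both data blocks are first adjusted for batch (contemporary group) and
sex with a parametric empirical-Bayes location/scale model
(`ebAdjust()`): per feature, the data are standardized by a linear model
containing the batch and the preserved covariates (climate, family, and
the not-yet-removed nuisance factor); per-batch locations
$\hat\gamma_{gk}$ and scales $\hat\delta^2_{gk}$ are shrunk toward
pooled priors — normal for locations, inverse-gamma for scales, with
hyper-parameters estimated from across-feature moments — by the usual
iterative conditional updates; the shrunken effects are subtracted and
rescaled and the covariate fit restored. The two nuisance factors are
removed sequentially (batch first, then sex; the order is an argument)
because the location/scale model takes a single batch factor.

Two implementation points deserve note:

* **Nested batches.** Contemporary groups are nested within climate, so
  the joint [batch | covariates] design is singular. `ebAdjust()` then
  estimates the covariate fit first and applies the batch model to its
  residuals; preserved effects can never leak into the batch estimates.
  On full-rank designs the standard joint fit is used.
* **Approximate idempotence.** Because the *shrunken* batch effect is
  removed, a residual of order (1 − shrinkage weight) remains; a second
  pass removes a further shrunken fraction of that residual. Re-running
  the adjustment therefore changes the matrix by far less than the
  first pass (typically an order of magnitude), but not by zero — this
  is a property of empirical-Bayes batch correction itself, not of this
  implementation.

The removal is audited with principal variance component analysis
(`pvca()`): features are standardized (essential for the trait block,
whose units are incommensurable), the fewest principal components
reaching 60 % of the variance (tunable) are retained, each PC score is
decomposed by a REML random-intercept model over climate, family, batch
and sex (lme4; negative components truncated at zero), and the per-PC
fractions are eigenvalue-weighted into the WAPV, in percent. A
successful adjustment leaves batch and sex below 1 % while the climate
fraction moves only by the renormalization that removing variance mass
implies.

## The composite sensitivity index

For every family $f$ and each of ADFI, BW and RT, the TEMP and TROP
offspring are compared with a Welch $t$ statistic (unequal variances,
Satterthwaite degrees of freedom), oriented TEMP − TROP:

$$ t = \frac{\bar x_{TEMP} - \bar x_{TROP}}
           {\sqrt{s^2_{TEMP}/n_{TEMP} + s^2_{TROP}/n_{TROP}}} $$

so a family whose intake or weight drops more in the hot climate has
larger $t_{ADFI}$, $t_{BW}$, and a family whose rectal temperature
rises more has a more negative $t_{RT}$. The families × 3 matrix of
these statistics is submitted to a centered PCA and each family's score
on the first component is its sensitivity index $I_{sens}$
(`computeIsens()`).

Two conventions are deliberate. The $t$ columns are **not** scaled to
unit variance by default: the statistics are already unit-free, and
scaling would force near-equal variable contributions; a `scale` flag
exposes the other convention. And the component is oriented so the
$t_{BW}$ loading is positive, making "larger index = more sensitive"
reproducible across runs; per-variable contributions to PC1 are the
squared loadings in percent. The `k = 2` lowest-index families form the
robust reference group and the two highest the sensitive one
(`selectExtremes()`, ties broken by family label).

## Sparse PLS-DA

The classifier (`splsda()`) is a from-scratch two-class sparse PLS-DA in
regression mode. X is centered/scaled, the class factor dummy-coded and
centered. Per component $h$, the weight vector is the dominant singular
direction of $X_d^\top Y_d$, soft-thresholded so that exactly
`keepX[h]` entries survive — the retained magnitudes are shrunk by the
(keepX+1)-th largest magnitude, a Lasso-like soft threshold with an
exact-cardinality parameterization — then renormalized; scores are
$t_h = X_d w_h$ and both blocks are deflated by regression on $t_h$.
With `keepX = ncol(X)` the fit is dense PLS-DA (the test suite verifies
equality with an independent NIPALS reference to 1e-8, and the
one-component closed form $w \propto X^\top y$).

Prediction standardizes new samples by the training statistics, runs
them through the deflation sequence, and classifies by the nearest
training-class centroid in score space (default); the
maximum-dummy-response rule is available via `rule = "response"`. The
continuous score for ROC analysis is the predicted-response margin of
the sensitive class.

Model quality is summarized by the balanced error rate
$BER = 1 - \tfrac12(\text{sensitivity} + \text{specificity})$, suited
to the imbalanced reference groups, with the ROC built from pooled
cross-validation scores and the AUC by the trapezoid rule.
`tuneKeepX()` chooses per-component selection sizes sequentially
(components 1..h−1 frozen) as the *smallest* grid size whose mean CV
BER is within 1e-3 of the minimum — parsimony on plateaus.
`crossValidate()` uses stratified folds throughout (each training part
must contain both classes) and reports, besides BER/AUC, each bucket's
selection-stability frequency over the folds × repeats (default
10 × 10 = 100) resample fits. Variable importance uses the standard
PLS VIP,

$$ VIP_j = \sqrt{ p \cdot \sum_h SS_h\, w_{jh}^2 \big/ \sum_h SS_h },$$

with $SS_h$ the Y sum of squares explained by component $h$; by
construction $\overline{VIP^2} = 1$, and buckets with VIP > 1 are
flagged as important.

## Validation

Every thermoneutral animal of every family is classified, and each
family's membership rate (MR, the percentage of its animals predicted
sensitive) is correlated with $I_{sens}$ (Pearson, two-sided t-based
p). By default the correlation uses all families; a flag restricts it
to the non-reference (validation) families. Differential abundance
between the reference groups is screened per bucket with a two-sided
Wilcoxon rank-sum test (normal approximation) and Benjamini–Hochberg
adjustment across *all* buckets; all-tied buckets get p = 1 with a tie
flag. The correlation panel relates each VIP > 1 bucket's per-family
median (TEMP animals) to per-family trait means in both climates and to
MR and $I_{sens}$. A type-III ANOVA utility (`groupComparisonTable()`,
sum-to-zero contrasts, families recoded within group so the nested
SF(G) term has no structurally empty cells) reproduces the usual
group-comparison reporting with `***`/`*`/`#` significance codes.

## The synthetic study generator

`generateStudy()` emulates the design the pipeline targets so every
stage is testable without animal data: 10 sire families × 2 climates,
offspring counts drawn as round(N(56, 5)) clipped at 10, 11 TEMP and
12 TROP contemporary batches assigned round-robin, alternating sexes,
and 445 buckets of which 30 carry signal. Traits are Gaussian around
TEMP means typical of growing pigs (e.g. ADFI 2.25 kg/d, BW 101.5 kg,
RT 39.25 degC) with residual standard deviations at the residual scale
of performance-test models (ADFI 0.42, BW 9, RT 0.3, ADG 136, FCR
0.54, ABFT 2.7, ST 0.7); the TROP shift is
`climateEffect + sensitivityScaling * s_f`, where the latent family
sensitivity $s_f$ defaults to an even gradient over [−1.5, 1.5] and the
scaling signs make sensitive families lose more intake/weight and heat
up more. Bucket abundances are exponentiated Gaussians (log-normal:
nonnegative, realistically skewed) with per-bucket climate, batch and
sex coefficients whose magnitudes (0.15, 0.09, 0.07 log units against a
0.4 residual) were chosen so the pre-adjustment PVCA fractions resemble
a realistically batch-affected metabolome (batch ≈ 5–10 %, sex ≈ 1 %);
informative buckets are *depleted* proportionally to $s_f$ in TEMP
animals (robust families richer), then every spectrum is normalized to
unit sum. The latent truth (s_f and the informative bucket labels) is
returned beside the study, never through it.

What the generator does **not** emulate: within-family genetic
variation in sensitivity (s_f is a family constant; real half-sib
groups segregate), litter/dam structure, peak-shape or chemical-shift
artefacts of real spectra, correlated metabolite networks (buckets are
conditionally independent given the design), and missing phenotypes.
Passing recovery tests on these data therefore shows the pipeline's
statistical machinery is sound at realistic effect sizes — not that
real metabolomes carry this much signal.

## Numerical choices and problem sizes

* EB iteration converges at 1e-4 relative change; features constant
  within all batches, or containing missing values, bypass the EB path
  (pass-through and complete-case location adjustment respectively).
* Soft-threshold ties at the cardinality boundary keep their stable
  order, and shrunken magnitudes are floored at the smallest positive
  double so the nonzero count is exact.
* Component signs (PCA and PLS are sign-ambiguous) are fixed: positive
  $t_{BW}$ loading for the index, dominant-entry-positive weights for
  PLS components.
* All randomness (generator, fold draws) flows from explicit integer
  seeds through an internal sub-seed stream; the caller's RNG state is
  restored afterwards.
* The test suite runs the full chain at the target design size (10
  families, ~1120 animals, 445 buckets) for the adjustment audit and
  the multi-seed recovery check, and scales everything else down (6
  families, 40–100 buckets) to keep a complete run in minutes; the
  acceptance script runs one full-size workflow.

## Known limitations

The index is a *relative* measure: it ranks the families of one
experiment and does not transfer across designs or trait sets. The
MR–index correlation across 10 families has wide confidence bands.
Unit-sum normalization makes buckets compositional, so strong shifts in
a few buckets induce small opposite shifts everywhere — the generator
reproduces this, and it slightly blurs planted-support recovery at
extreme effect sizes. Multiclass discrimination, orthogonal-PLS
variants and non-parametric EB priors are out of scope.
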