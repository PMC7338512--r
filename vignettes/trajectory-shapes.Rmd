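---
title: "Trajectory-shape analysis of cortical thickness development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-shape analysis of cortical thickness development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cross-sectional studies of autism spectrum disorder (ASD) often find no
stable difference in cortical thickness (CT) between ASD and typically
developing (TD) cohorts when thickness is compared directly. A more
sensitive question is whether the *shape* of the developmental trajectory —
how CT changes between childhood and early adulthood — differs between
groups. `ctshapes` implements that analysis as a reusable pipeline: regional
CT tables from a multi-center cohort (ages 6–30) are harmonized across
acquisition centers, per-group polynomial age models are fitted per region
of interest (ROI), and the highest-order coefficients of those models — the
**slope** (linear model, mm/yr), **curvature** (quadratic, mm/yr²), and
**aberrancy** (cubic, mm/yr³) — are treated as the trajectory-shape
parameters. Group differences and symptom associations are then tested with
partial least squares (PLS), and the shapes are used to classify ASD versus
TD development with a linear support vector machine (SVM).

Because real multi-center MRI repositories cannot be shipped with a package,
`ctshapes` includes a first-class synthetic-data module that generates
cohorts with the statistical structure the analysis assumes. Every stage of
the pipeline is exercised and tested end-to-end on generated data.

## The model

For each ROI, center harmonization fits (ordinary least squares, both groups
pooled, degree $d \in \{1,2,3\}$):

$$\mathrm{CT} \sim \beta_{\mathrm{int}} + \boldsymbol{\beta}_0\,
\mathrm{Center} + \sum_{j=1}^{d} \beta_j\, \mathrm{Age}^j + \gamma_0\,
\mathrm{Group} + \sum_{j=1}^{d} \gamma_j\, (\mathrm{Age}^j \times
\mathrm{Group})$$

with centers dummy-coded against a reference (all but one, because the
intercept is present) and the group coded ±1. Only the variance carried by
the center dummies is subtracted; age, group, and age-by-group variance is
preserved. The subtracted center effects are re-centered to a size-weighted
zero mean so each ROI's grand mean is unchanged and the adjusted values stay
in physiological range regardless of the reference choice. The adjustment is
a projection (applying it twice equals once), and refitting the model on
adjusted data returns center coefficients of numerically zero. Each
degree-$d$ downstream analysis consumes the degree-$d$ adjustment, keeping
every analysis internally consistent; with a single center the data pass
through untouched.

Trajectories are then fitted per group, parcellation, and ROI with the
center and group terms removed. Goodness of fit uses a deviance test: the
Gaussian likelihood-ratio statistic $n \log(\mathrm{RSS}_0 /
\mathrm{RSS}_d)$ against the intercept-only model, referred to
$\chi^2_d$. ROIs whose fit fails a Benjamini–Hochberg correction at $q =
0.05$ (per group × degree family) are masked from later stages. Two masking
rules exist because the source analysis is ambiguous about whether an ROI
must fit in *both* groups or in *any* group; `both_groups` is the default
and the rule is a configuration switch.

The **turning point** of a negative-curvature quadratic trajectory is the
age at which the fitted curve is furthest, in vertical distance, from the
chord connecting its values at ages 6 and 30 — the transition from
decreased to increased cortical thinning. We use vertical rather than
perpendicular distance because "distance at a time point" is the natural
reading; for any quadratic the maximizer is then analytically the interval
midpoint, 18 years, which the implementation derives from the stationarity
condition of the fitted coefficients rather than asserting.

## Subsampling and inference

A shape coefficient is a constant of the sample used to estimate it. To
obtain a sampling distribution the pipeline draws many subject subsamples
per group (70 subjects, 100,000 candidate draws at full scale), keeps the
80 whose age histograms have the highest Shannon entropy (one-year bins on
6–30; entropy ranks are invariant to the logarithm base, so only the
binning matters), and fits the three models to each retained subsample.
One-year bins are the finest resolution consistent with 70-subject samples.
The candidate count is configurable with a fast default (2,000) for
interactive use and tests.

**Mean-centered PLS** stacks the two groups' subsample-by-feature shape
matrices, forms the group-means matrix, subtracts the grand mean (unweighted
mean of group means; the groups are balanced by construction), and takes the
SVD. For two groups this is a rank-1 contrast, oriented ASD > TD.
**Behavioral PLS** takes the SVD of the correlation matrix between subgroup
mean ADOS subscores (communication, social, stereotyped behavior) and
subgroup shape coefficients. Feature reliability is assessed with bootstrap
ratios: resamples of observations (within group for the mean-centered
variant, paired rows for the behavioral one), sign-aligned to the original
saliences by dot product — the alignment rule is undocumented in the
original tooling, and dot-product alignment is the standard choice — with
the ratio defined as original salience over bootstrap standard error.
Permutation p-values use the add-one estimator $(1 + \#\{\sigma_{perm} \ge
\sigma_{obs}\})/(1 + n_{perm})$, so they are never exactly zero.

### Why permutation is at the subject level

Subsamples of one group share a subject pool, so their shape estimates are
strongly dependent: the pool-level sampling deviation is common to all of a
group's rows. Shuffling *row* labels between groups cannot reproduce that
pool-level variance under the null and is badly anti-conservative —
simulations with the null generator reject essentially always. The
orchestrating functions therefore permute at the level the data are actually
exchangeable: `run_group_pls()` reassigns *subjects* across groups and, for
every permutation, re-runs the entropy-guided subsample selection and the
shape fitting on the permuted pools, so the permuted statistic is produced
by the identical procedure as the observed one. `run_behavioral_pls()`
likewise permutes the assignment of ADOS records to subjects while keeping
subgroup memberships fixed, because both the coefficient rows and the
mean-ADOS rows inherit dependence from shared members, and only the
subject-level shuffle preserves that structure on both sides. The generic
`mean_centered_pls()`/`behavioral_pls()` functions keep plain row-level
shuffling for independent-row inputs. Under the null generator the
subject-level test is calibrated (type-I error within Monte-Carlo limits of
the nominal 5%), which the acceptance suite verifies with 200 replicate
datasets.

Sign conventions: mean-centered LVs are oriented so the first group (ASD)
loads positively — positive bootstrap ratios mean "higher in ASD".
Behavioral LVs are oriented so the brain saliences sum non-negatively; the
reported per-subscore correlations then carry the direction of the raw
brain–behavior association (negative when higher symptom scores accompany
more negative curvature).

## Classification

`cross_validate()` repeats (500 times at full scale): split each group in
half within two-year age bins (an odd subject goes to either half with
probability ½), subsample and fit shapes independently in each half, train a
linear-kernel SVM (cost 1, no feature standardization — the stated defaults
of the original tooling) on one half's subgroup rows of a chosen
coefficient, and evaluate on the other half's rows. Sensitivity is ASD
recall, specificity TD recall, and with balanced test classes accuracy is
their mean. The subsample selection is re-run in every repeat. Pairwise
model comparisons use equal-variance two-sample t-tests with
Benjamini–Hochberg correction.

A caveat this package makes explicit: with a *finite* cohort, the two halves
share the cohort's sampling deviation — the half-specific group differences
both center on the full-cohort difference — so subsample-level
classification is structurally above chance whenever the feature count is
large relative to the cohort, *even under a null generating process*.
Simulations show this clearly (for example, ~73% null accuracy with 20 ROIs
and 160 subjects per group). Reported accuracies from this design should
therefore be read as evidence about this cohort's group separation, not as
unbiased subject-level generalization estimates. The chance-level
calibration in the acceptance suite is accordingly run where pool-level
noise is negligible (600 subjects per group, 6 ROIs).

## The synthetic generator

`ct_preset()` defines the study conditions:

* TD baseline: per-ROI intercepts spread over 2.9–3.5 mm, slope −0.045
  mm/yr, curvature +0.001 mm/yr² — a gently U-shaped thinning trajectory
  with realistic thickness values; no cubic component.
* `"paper-like"`: in a contiguous block of 20% of the ROIs, the ASD group
  receives a contrast decomposed into $s\,(a-18)$ with $s = +0.010$ mm/yr
  (reduced thinning rate; shifts only the linear-fit slope) and
  $c\,((a-18)^2 - 48)$ with $c = -0.0015$ mm/yr² (negative curvature;
  shifts only the quadratic-fit curvature). Both parts integrate to zero
  over ages uniform on [6, 30], so the groups have equal mean CT — matching
  the empirical observation that overall CT does not differ. ASD planted
  curvature becomes −0.0005 mm/yr² against the TD +0.001.
* `"strong"`: both components doubled.
* `"null"`: identical trajectories, used for all calibration checks.

Noise is 0.1 mm per subject and ROI (a typical ROI-level CT residual SD);
centers carry additive offsets spread over ±0.2 mm. Ages are continuous
uniform on [6, 30]: the cohort age density is otherwise unconstrained and
the entropy-based subsampling itself rewards uniformity. ADOS subscores are
rounded, range-clamped integers (0–8 communication and social, 0–4
stereotyped) built from a base level, noise, and a latent standard-normal
severity trait; the same trait scales a mean-zero per-subject quadratic
deviation ($-\mathrm{het}\cdot s_i\,((a-18)^2-48)$) in planted ROIs, so a
positive coupling plants the "more severe symptoms — more negative
curvature" association at the population level without moving the group
trajectory. Group sizes, center counts, and ADOS completeness are arguments,
with the published design sizes (674/686, 24 centers, 404 ADOS-complete) as
reference points.

What the generator does **not** emulate: spatial covariance between ROIs
(noise is independent across ROIs), scanner-specific age interactions,
non-uniform age densities, IQ structure, or vertex-level data. Passing tests
therefore show that the pipeline recovers planted effects of realistic size
under clean model assumptions — not that real data satisfy those
assumptions.

## Numerical choices

* Polynomial fits are computed on mean-centered ages (QR decomposition) and
  mapped back to raw-age coefficients exactly; the highest-order coefficient
  is shift-invariant, so shape estimates never depend on the centering.
* The subsample fitting engine shares cross-products across the three
  degrees (the degree-$d$ normal equations are the leading blocks of the
  cubic ones).
* Rank-deficient harmonization designs (for example a center perfectly
  confounded with group) raise an error naming the collinear columns.
* Zero within-center variance in the outlier screen yields z = 0 for that
  ROI (logged), so identical values never trigger removal.
* Deviance tests on data equal to their own mean return statistic 0 and
  p = 1; zero-residual fits of non-constant data return p = 0 with a
  degeneracy flag.
* Entropy ties during subsample selection break by candidate draw order;
  duplicate candidate subject sets are allowed (no deduplication).
* Adjusted CT values that become non-positive are logged, never clipped.
* Permutation p-values use the add-one estimator; bootstrap standard errors
  of exactly zero yield `NA` ratios rather than infinities.
* One master seed spawns per-stage child seeds through a fixed
  multiplicative-congruential scheme (`child_seed()`), so any stage can be
  reproduced in isolation and reruns are bit-identical.

## Problem sizes used by the test suite

The packaged tests run the full-scale *algorithms* at reduced problem sizes
chosen so planted effects remain comfortably recoverable: cohorts of
120–600 subjects per group, 6–40 ROIs, 20–100 subsamples of 20–35 subjects
from 50–300 candidate draws, 200–500 permutations, and 50–200 replicate
datasets for the calibration checks. The full-scale settings (100,000
candidates, 10,000 permutations and bootstraps, 500 cross-validation
repeats) remain the defaults of `default_config()` for real runs.

## Known limitations

* The deviance test assumes Gaussian residuals; heavy-tailed CT noise would
  make the $\chi^2$ reference approximate.
* Harmonization is plain regression, not empirical-Bayes shrinkage; very
  small centers are handled by exclusion (the 10-per-group filter), not by
  pooling.
* The subsample-level classifier inherits the optimism discussed above; a
  subject-level classifier is out of scope.
* Behavioral PLS requires at least three ADOS-complete subjects per
  subgroup; subgroups below that are dropped with a warning.
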