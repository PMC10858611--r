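---
title: "Heterogeneous causal effects in Mendelian randomization with random forests of Q trees"
author: "rfqt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous causal effects in Mendelian randomization with random forests of Q trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A standard Mendelian randomization (MR) analysis uses a genetic
instrument $Z$ — a variant dosage or a weighted allele score — to
estimate the population-averaged causal effect of an exposure $X$ on an
outcome $Y$. The effect need not be the same for everyone: covariates
$M_1, \dots, M_p$ may modify it, and identifying in whom an intervention
on $X$ would matter most requires stratum-specific estimates.

The obstacle is that in MR the "randomization" happens at conception, so
essentially every covariate is post-randomization. A covariate that is
causally downstream of the exposure is a *collider*: a common effect of
the exposure and of unmeasured confounders $U$. Stratifying on a
collider induces a correlation between the instrument and the
confounders inside each stratum, so the instrumental-variable
assumptions fail there even though they hold in the whole population —
naive stratum-specific estimates are biased, sometimes drastically (see
the package's simulation benchmark, where naive stratification on a
collider moves the estimate from the true 0.5 to roughly 0).

`rfqt` implements a collider-robust, data-adaptive answer in four layers:
collider-robust stratification on one covariate; a heterogeneity
statistic over stratum estimates; a tree/forest machine that searches a
high-dimensional covariate set for effect modification; and inference
tools (variable importance, permutation tests, pooled stratum estimates
with trend tests).

## Collider-robust stratification

Two methods are provided alongside naive rank stratification:

* **Residual method** (`residual_strata()`): regress $M$ on $Z$, stratify
  on the residuals. The residual estimates the covariate value the
  individual would have at $Z = 0$, which is not a function of the
  instrument. Valid when the instrument acts on the covariate linearly
  and homogeneously.
* **Doubly-ranked method** (`doubly_ranked_strata()`): rank on $Z$, form
  consecutive pre-strata of 10 individuals, rank on $M$ within each
  pre-stratum, and build strata by collecting equal covariate-rank slices
  from every pre-stratum. Only a *rank-preserving* assumption is needed:
  changing an individual's instrument value would not change their
  covariate rank within their pre-stratum. Each stratum draws identically
  from every instrument pre-stratum, so the instrument distribution is
  balanced across strata by construction.

The pre-stratum size of 10 is the conventional choice and gives integer
slices for the 3:7 / 5:5 / 7:3 splitting proportions used in trees; it is
exposed as `prestratum_size`. When $n$ is not a multiple of 10, the final
(smaller) pre-stratum is sliced by the same proportions applied to its
own size with largest-remainder rounding, so every individual is kept.
All tie-breaking is random and driven by one seeded stream per call;
heavy-tied (effectively discrete) covariates trigger a warning, because
their stratum membership is then largely arbitrary.

## Stratum estimates and the Q statistic

Within stratum $k$, `stratum_associations()` fits ordinary least-squares
regressions of $X$ on $Z$ and of $Y$ on $Z$, giving
$\hat\beta_{Xk}(\sigma_{Xk})$ and $\hat\beta_{Yk}(\sigma_{Yk})$, and the
ratio (Wald) estimate $\hat\theta_k = \hat\beta_{Yk}/\hat\beta_{Xk}$ with
first-order standard error $\sigma_{Yk}/|\hat\beta_{Xk}|$. Heterogeneity
across strata is measured by a Cochran-type statistic
$$
Q = \sum_{k=1}^K
  \frac{(\hat\beta_{Yk} - \hat\theta\,\hat\beta_{Xk})^2}
       {\widehat{\operatorname{var}}(\hat\beta_{Yk} - \hat\theta\,\hat\beta_{Xk})},
$$
which under homogeneity is $\chi^2_{K-1}$.

Two numerical choices matter here and are deliberate:

1. **One-sample covariance.** Both associations are estimated on the
   same individuals, so $\hat\beta_{Xk}$ and $\hat\beta_{Yk}$ co-vary
   (strongly, under shared confounding). The denominator therefore uses
   the exact profile-likelihood variance
   $\sigma_{Yk}^2 + \hat\theta^2\sigma_{Xk}^2 -
   2\hat\theta\,\sigma_{XYk}$, where $\sigma_{XYk}$ is the sampling
   covariance of the two slopes, recorded by `stratum_associations()`.
   Dropping the covariance term (the familiar two-sample summary-data
   form, recovered automatically when no covariance is available) makes
   Q severely conservative on individual-level data: in the package's
   null calibration experiment the mean of a 9-df Q drops from ~9 to
   ~3.5.
2. **Profile-likelihood reference effect.** By default $\hat\theta$
   minimises Q (`iterate = TRUE`), rather than plugging in the
   closed-form inverse-variance weighted average of the
   $\hat\theta_k$. With the plug-in value the statistic over-rejects
   when per-stratum instruments are weak (null rejection ~0.10 at
   per-stratum F around 4 in the calibration experiment, against ~0.05
   for the profile version). The plug-in variant remains available via
   `iterate = FALSE`, and `ivw_average()` keeps the weighted mean as the
   point estimator.

With these defaults the null calibration experiment (scenario A below,
no modification, deciles of a non-modifier covariate) reproduces a mean
Q of ≈9 on 9 df with ≈5% rejection — the property the tests assert.

## Q trees and forests

`grow_qtree()` recursively partitions the sample. At each node, for every
candidate covariate and each splitting proportion in {3:7, 5:5, 7:3},
two strata are formed with the configured stratifier (doubly-ranked by
default) and the two-stratum Q is computed; the split with the greatest
Q is taken. A node is not split when the best Q is below
`q_threshold = 3.84` (the $\chi^2_1$ 95th percentile), when a child
would fall below `min_node_size`, or beyond `max_depth = 5`. The small
proportion menu is intentional: leaf estimates reuse the fitting data,
so a richer menu would overfit. `min_node_size = 1000` targets
biobank-scale data — stratum-specific ratio estimates need sizeable
strata because within-stratum instruments are weak; for simulation-scale
fits a few hundred is appropriate and all values are configurable.

Child membership at fit time **is** the stratum assignment, not a
covariate threshold — this is what keeps the leaf estimates
collider-robust, and it is why honest sample-splitting estimation is not
used here (re-deriving node membership in an estimation subsample by
thresholding would reintroduce collider bias). For routing *new*
individuals, each internal node stores the boundary value
$(n_1\bar M^*_1 + n_2\bar M^*_2)/(n_1+n_2)$; an individual goes to the
lower child iff their covariate value is at or below the boundary (ties
to the lower child). Leaves carry the ratio estimate of their members.

`fit_rfqt()` aggregates `n_trees` Q trees over bootstrap resamples with
per-node covariate subsampling (`mtry_fraction = 0.4`, i.e. 8 of 20
candidates in the simulator, 11 of 28 covariates in a typical applied
set). Predictions are unweighted means over trees. Out-of-bag
predictions average only trees whose resample excluded the individual.

Per-tree seeds are derived from the master seed by index, so results are
independent of evaluation order and fully reproducible.

## Variable importance and permutation tests

`variable_importance()` permutes one covariate within each tree's
out-of-bag rows and records the mean squared shift of the OOB predicted
effects; importances are averaged over trees and ranked. A covariate
never used for splitting shifts nothing and scores exactly zero.

`permutation_test()` addresses the global null that no candidate
covariate modifies the effect. Two statistics summarise a fitted forest:
$S_1$, the mean over trees of the size-weighted variance of leaf
estimates (leaf sizes count bootstrap multiplicity, so they sum to the
training size), and $S_2$, the mean over trees of the tree-level leaf Q
— more robust to weak instruments, since it standardises by the
association variances. The null distribution is built by refitting the
forest after applying one random row permutation jointly to the whole
covariate block — this preserves the covariate-covariate correlation
structure while severing all covariate links to $(Z, X, Y)$ — and the
p-value is the proportion of permuted refits with a statistic at least
the observed one (a $(r+1)/(n+1)$ correction is available by flag).
Permutation refits default to the same forest size as the observed fit;
a smaller `perm_n_trees` is possible but changes the observed and null
statistics' distributions asymmetrically, so it is off by default.

## Pooled stratum estimates and trend tests

A single doubly-ranked stratification is rank-sensitive: small
perturbations of the sample reshuffle strata. `pooled_stratum_estimates()`
repeats the stratification `S = 100` times (the default; the number of
resamples is a stability/compute trade-off), each time dropping
`n_drop = 10` individuals at random, and pools per Rubin's rules: the
pooled association is the plain mean across resamples; its total
variance combines the mean within-resample variance $U$ and the
between-resample variance $B$ (computed with the $S-1$ denominator) as
$U + (1 + 1/S)B$; the 95% CI uses a $t$ quantile with
$\nu = (S-1)\,(1 + U/((1+1/S)B))^2$ degrees of freedom, degenerating to
the normal quantile when $B = 0$. Pooled ratio estimates divide the
outcome-association interval by the pooled instrument-exposure
association (endpoints re-ordered if that association is negative). A
pooled Q (`pooled_q()`) uses the total variances — including the pooled
covariance term — in the denominator. Because overlapping resamples make
$B$ partially double-count sampling noise, the pooled intervals are
mildly conservative (measured coverage ~97–98% at nominal 95%) and the
pooled Q under-rejects; this is a property of the resampling design, not
a defect of the pooling arithmetic, and the tests assert the measured
behaviour.

`trend_test()` regresses the pooled stratum ratio estimates on the
pooled stratum covariate means with a random-effects meta-regression
(`metafor::rma`, REML heterogeneity variance by default) and reports the
Wald test of the moderator slope.

## The simulator

`simulate_dataset()` generates
$$
X = 0.5Z + 0.5\textstyle\sum_{j=1}^{20} U_j + \epsilon_X,\qquad
M_j = b_j X + U_j,\qquad
Y = \big(0.5 + \textstyle\sum_{j\le 5}\gamma_j M_j\big) X
    + 0.5\textstyle\sum_j U_j + \epsilon_Y,
$$
with all of $Z, U_j, \epsilon_X, \epsilon_Y$ standard normal,
$\gamma_j \sim N(\gamma, 0.1^2)$ for the five modifiers (drawn once per
dataset — modifier effects are population-level quantities) and zero
otherwise. Scenario A sets $b_j = 0$ (no colliders); scenario B sets
$b_j = 0.5$ for even $j$ (half the covariates are colliders); scenario C
sets $b_j = 0.1 + 0.5U_j$ evaluated at each individual's confounder
value, so the exposure's effect on the covariates is itself modified by
the confounders and both the residual method's linearity assumption and
the rank-preserving assumption fail. The recorded per-individual truth is
the controlled direct effect $0.5 + \sum_{j\le5}\gamma_j M_j$ — a close,
cheaper stand-in for the total effect that MR targets. Because the
$\gamma_j$ are random, $\gamma = 0$ still leaves weak modification; the
`pure_null` flag forces all $\gamma_j = 0$ exactly, which exact-null
calibration experiments need.

What the generator does **not** emulate: non-Gaussian traits, weak or
pleiotropic instruments at the variant level, measurement error, discrete
covariates, or selection effects. Green tests therefore certify the
machinery under the stated structural model, not performance on any
particular cohort.

## Problem sizes used by the test-suite experiments

The packaged experiments run at desk scale, chosen so each property is
measurable with useful Monte-Carlo precision: Q calibration at
$n = 2{,}000$ with 500 replicates; collider-bias contrast at
$n = 5{,}000$ with 100 replicates; the benchmark grid at $n = 10{,}000$
training / 2,000 held-out individuals, 20-tree forests, 20 replicates;
variable importance at $n = 10{,}000$ with 50-tree forests over 10
replicates; permutation calibration at $n = 2{,}000$, 10-tree forests,
99 permutations, 50 replicates; pooled coverage at $n = 2{,}000$,
$K = 5$, $S = 50$, 200 replicates. The benchmark and permutation
experiments use the default stopping rules; the only scaled-down
hyperparameter anywhere is the forest size.

## Known limitations

* Ratio estimates assume linearity and homogeneity (or monotonicity)
  within strata; stratum estimands may differ in interpretation across
  strata.
* The doubly-ranked method's rank-preserving assumption is untestable;
  discrete covariates sit uneasily with rank-based slicing.
* No confidence intervals accompany individual forest predictions.
* The per-stratum "Monte-Carlo" contrast in the collider benchmark is a
  power statement about a fixed $n$; at $n = 5{,}000$ the naive bias is
  about 2.9 standard errors, so a 3-SE detection rule identifies it in
  roughly 60% of replicates (rising quickly with $n$).
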