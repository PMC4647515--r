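---
title: "Odds-ratio effect sizes for QLQ-C30 scores: models and design notes"
author: "qlor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Odds-ratio effect sizes for QLQ-C30 scores: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlor)
```

## The problem

EORTC QLQ-C30 domain scores live on a bounded 0-100 scale, are usually
heavily skewed with mass piled at 0 and/or 100, and are observed repeatedly
per patient until dropout. Treatment benefit is conventionally reported as a
between-arm mean difference (MD) from a repeated-measures linear model, but
for boundary-piled distributions the mean is a poor location summary and
small MDs can hide effects that are large on a relative scale. This package
implements the alternative: report the treatment effect as an odds ratio
(OR) from a Beta-Binomial (BB) mixed-effects regression of the
unit-interval-transformed score, classify effects on both scales, and
compare both against time-to-deterioration (TD) analysis.

## Score representations

A domain built from $m$ items answered on $(r+1)$-point scales can only take
the $n+1 = m\,r + 1$ equally spaced values $0, 100/n, \dots, 100$. Three
representations are used:

* the 0-100 score itself (`score_domain()`, standard scoring arithmetic with
  the half rule for missing items: the score is the mean of answered items
  provided at least half were answered);
* the unit-interval transform $u = (Y - a)/(b - a)$ with $a=0$, $b=100$
  (`unit_transform()`);
* the count pair $(k, n)$ with $k = \mathrm{round}(u\,n)$ (`to_counts()`),
  exact on the achievable grid and the form the BB likelihood consumes.

The instrument's missing-item policy is our design choice (the standard
half rule); pre-computed scores are accepted directly and only warned about
when off-grid by more than 0.05, since 1-dp rounding in source files is
common.

## The Beta-Binomial mixed model

For patient $i$, visit $j$: conditional on a random intercept
$b_i \sim N(0, \sigma_b^2)$,

$$k_{ij} \sim \mathrm{BetaBinomial}(n,\ \mu_{ij},\ \rho), \qquad
  \mathrm{logit}(\mu_{ij}) = \mathbf{x}_{ij}'\boldsymbol\beta + b_i,$$

in the mean/correlation parameterization $\alpha = \mu(1-\rho)/\rho$,
$\beta = (1-\mu)(1-\rho)/\rho$, so $\mu$ is the mean proportion of the scale
achieved and $\rho \in [0,1)$ the overdispersion correlation
(`bb_pmf()`; $\rho \to 0$ recovers the Binomial, and $\rho$ below $10^{-8}$
is evaluated in that limit for numerical stability). This parameterization
is chosen so that $e^{\beta_{\mathrm{trt}}}$ is directly the treatment odds
ratio of scoring higher on the scale. Counts $k = 0$ and $k = n$ are
ordinary likelihood contributions — no dichotomization and no boundary
inflation are needed on the grid.

The marginal likelihood integrates each patient's product of BB terms over
$b_i$ by Gauss-Hermite quadrature (`bb_marginal_loglik()`, default 15
nodes). With $\sigma_b = 0$ it equals the fixed-effects likelihood exactly
because the quadrature weights sum to $\sqrt\pi$. The core is compiled
(Rcpp) with an equivalent pure-R path retained; tests compare the two and a
brute-force trapezoid integral.

`fit_bb()` maximizes this likelihood by BFGS from up to three starts
(method-of-moments, null, and a jittered moment start drawn from the
caller's RNG stream), takes Wald standard errors from the numerical
Hessian, and reports $\mathrm{OR} = e^{\beta_{\mathrm{trt}}}$ with a 95% CI
and two-sided p-value. Defaults that matter:

* **Fixed effects**: intercept + treatment + visit time (categorical) +
  baseline score, with each patient's earliest visit used as the baseline
  covariate and removed from the response. Baseline HRQoL precedes
  treatment, so adjusting for it sharpens the contrast without absorbing it.
* **Conditional OR**: because $b_i$ enters the linear predictor, the
  reported OR is subject-specific, *given* the patient's latent level — the
  natural scale for "this patient's odds of a better score". It is larger
  in magnitude than the population-averaged OR when $\sigma_b > 0$; the two
  are not interchangeable and we document ours prominently.
* **Separation**: an arm sitting entirely at one boundary cannot identify
  its odds; the fit aborts with a pointer to the inflated model.
* **Convergence**: tight relative tolerance ($10^{-12}$) so that exact
  symmetries (arm relabelling maps the optimum to its mirror image) hold to
  $10^{-6}$ on the OR.

### Zero-one inflated beta variant

For continuous-valued bounded responses (where the grid argument does not
apply) `fit_zoib()` fits a three-part mixture: multinomial-logit point
masses at 0 and 1 (intercept + treatment) and a beta density with
logit-linear mean on the interior, constant precision. The treatment OR is
taken from the interior mean, mirroring the BB report. With no boundary
observations the model collapses to plain beta regression; with no interior
observations it refuses to fit.

## The mean-difference comparator

`fit_md()` fits the repeated-measures linear mixed model on the raw 0-100
score with the same fixed effects and a patient random intercept
(`lme4::lmer`), so MD and OR contrasts are like-for-like. P-values use the
normal approximation, consistent with trial-sized samples. Degenerate
designs the mixed model cannot identify — a single visit per patient, or
zero residual variance — fall back to OLS on the same fixed effects, which
yields the identical treatment contrast in exactly those cases. The MD is
experimental minus control on the score scale, so its sign reads through
the domain orientation (function up = better, symptom up = worse).

## Effect-size taxonomies and their comparison

MD bands (on $|\mathrm{MD}|$): trivial 0-3, small 3-10, medium 10-15, large
> 15 points, boundaries closed below. OR bands are additive around 1:
trivial $[0.95, 1.05]$, small $1 \pm 0.10$, medium $1 \pm 0.20$, large
beyond 0.80/1.20 (strict). This boundary convention is the unique simple
one consistent with every published band count reproduced by the packaged
fixture (e.g. an OR of 1.10396 counts as medium, so the small band is
closed at 1.10). Additivity means reciprocal ORs need not share a band —
documented, not "fixed", because the bands are defined additively.

`crosstab()` tabulates bands against two-sided significance at
$\alpha = 0.05$. `detection_odds()` compares the odds of landing in the
medium-or-large bands between two classifications; its `digits` argument
reproduces arithmetic quoted from proportions rounded to two decimals
(22/90 vs 4/90 quoted as 0.24 vs 0.04 gives 7.58 rather than the exact
6.96), which is how the packaged summary is reported.

The published fixture's "significant OR" column sums to 21; the total
printed alongside it in the source is 31, which is inconsistent with its
own column. We reproduce the column.

### MD-to-OR equivalence

`md_or_equivalence()` matches the two scales through cumulative frequency:
the empirical CDF of $|\mathrm{MD}|$ at a grid value is inverted on the
empirical CDF of the OR magnitude $e^{|\log \mathrm{OR}|}$, with linear
interpolation between knots and duplicate values collapsed to their largest
plotting position on both curves (this consistency makes the mapping exact
when the two samples are rank-matched, and monotone always). The exact
procedure behind the published equivalence figures is not stated in enough
detail to reproduce: on the packaged estimates the naive empirical median of
$|\mathrm{MD}|$ is about 2.2 rather than the quoted 2.5, so the published
grid values (about 1.02-1.37) are treated as reference points and the
package asserts only the structural properties (identity on matched
samples, monotonicity).

## Time to deterioration

`derive_td()` defines deterioration as the first post-baseline visit whose
score has worsened from baseline by at least the threshold (default 5
points): a decrease for function/global domains, an increase for
symptom/FI domains — the only clinically coherent reading of
"reduced/increased". First crossing, not confirmed deterioration; patients
who never cross are censored at their last assessment. On a grid with step
16.7, thresholds 5 and 16 define identical event sets, which is why
threshold choice interacts with the instrument's granularity.
Kaplan-Meier medians use the first time the product-limit curve reaches
0.5 or below (undefined when it never does — common with few events);
`cox_hr()` uses Efron ties, and `ph_diagnostic()` is the scaled
Schoenfeld-residual trend test, withheld below 3 events. Death is not
treated as deterioration; competing risks are out of scope.

## The synthetic generator

`generate_trial()` emulates what the analysis assumes: per-patient logit
intercepts (within-visit correlation), a constant subject-specific
treatment OR applied only post-baseline (baseline is assessed
pre-treatment), BB draws on the achievable grid — or boundary masses plus
interior beta draws in inflated mode — and discrete-time dropout,
optionally arm-dependent or tied to the latent intercept (informative
dropout switch; default is missing at random given arm and time, since the
source analyses did not model dropout). Defaults are the conditions the
package's recovery studies use throughout: 150 patients per arm, five
visits (days 0-120), a symptom-type domain on the 6-step grid with baseline
mean proportion 0.25, true OR 1.2, $\rho = 0.1$, $\sigma_b = 0.5$, 5%
per-visit dropout. What the generator does *not* emulate: item-level
missingness, treatment-by-time interactions, informative visit timing, and
calibration to any real trial's parameters — so passing recovery tests
demonstrate internal consistency of the machinery, not agreement with any
specific published estimate (the underlying six-trial patient data are not
public, and the published model estimates are not exactly recoverable even
in principle because the covariate and random-effects structures are not
fully specified in the source).

`generate_crossing_hazards()` exists to exercise the PH diagnostic: latent
deterioration times follow a discrete piecewise hazard whose arm ratio
flips from `hr_early` to `1/hr_early` at a configurable changepoint, and
scores drop two grid steps at deterioration. Defaults (150/arm, monthly
visits for 24 months, control hazard 0.03/visit, early HR 3, changepoint at
50% of follow-up) were designed so both phases carry information: the low
base hazard keeps risk sets populated after the reversal, which is what
makes the violation detectable rather than merely present. With the
changepoint at the end (no reversal) the same generator produces
proportional hazards and is used to check the diagnostic's size.

## Numerical choices and problem sizes

Quadrature: 15 Gauss-Hermite nodes (61-node refinement changes the
log-likelihood by well under $10^{-4}$ on trial-sized data). Optimizer
restarts: 3 by default; the simulation studies use the moment start alone,
which reaches the same optimum on this generator two orders of magnitude
faster. The packaged studies use 200 replicates for OR recovery/CI coverage
at 300 patients x 5 visits, and 100 replicates for the PH diagnostic's
power and size; these sizes give Monte-Carlo standard errors comfortably
inside the acceptance margins (about 0.007 on a 0.95 coverage estimate).
Ties in the equivalence mapping and in Cox fits are handled as described
above; `bb_pmf` switches to the Binomial limit below $\rho = 10^{-8}$.

## Known limitations

* The reported BB OR is conditional (subject-specific); marginal ORs would
  require an extra integration step and are not provided.
* Treatment-by-time interaction is not modelled by default: the OR (like
  the single-number MD and the Cox HR) presumes a constant effect over the
  assessment window.
* No multiple imputation for dropout; the likelihood is valid under
  missingness at random given the modelled covariates.
* The OR bands are additive around 1 by definition, hence not reciprocal-
  symmetric at every boundary.
* Real QLQ-C30 datasets at scale may need more quadrature nodes or
  covariates than the defaults; both are exposed.
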