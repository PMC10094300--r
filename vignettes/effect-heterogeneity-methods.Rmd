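---
title: "Weighted model-based recursive partitioning for green-space effect heterogeneity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted model-based recursive partitioning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenmob)
```

# The estimation problem

The package targets a common situation in environmental epidemiology: a
cross-sectional cohort with a binary health outcome (self-rated health,
dichotomized good vs bad), one green-space exposure per analysis (binary
self-rated measures, or a continuous NDVI-like greenness index), a short
list of confounders, and a long list (~40) of mixed-type candidate
moderators. The scientific question is not only whether exposure and outcome
are associated after confounding adjustment, but *for whom*: which subgroups,
defined by interactions of the moderators, show a different exposure effect.

The analysis proceeds in two stages that are deliberately separated:

1. **Weighting** makes the exposure approximately independent of the
   confounders (a pseudo-randomized sample).
2. **Model-based recursive partitioning (MOB)** searches the moderator space
   for parameter instability of the weighted exposure–outcome model.

Keeping confounders and moderators in separate roles mirrors applied
practice: confounders are adjusted by design (weighting), while moderators
are allowed to define subgroups.

# Stage 1: stabilized inverse-probability weights

For a binary exposure the propensity score $e(X_i) = P(E_i = 1 \mid X_i)$ is
estimated by maximum-likelihood logistic regression. The stabilized weight is

$$ sw_i = \frac{P(E = e_i)}{P(E = e_i \mid X_i)}, $$

with the marginal probability taken from the raw sample. For a continuous
exposure the conditional probability is replaced by a conditional density
(the generalized propensity score): the exposure is regressed linearly on
the confounders, and both the conditional density (Gaussian kernel density
estimate of the residuals, evaluated at each record's own residual) and the
marginal density (kernel density estimate of the exposure itself) are
estimated with Silverman's rule-of-thumb bandwidth. Both bandwidths can be
overridden.

Assumptions: no unmeasured confounding given the confounder list; positivity
(no covariate pattern with probability 0 or 1 of exposure); correct
specification of the exposure model (logistic / homoscedastic linear). The
diagnostics are the standard ones — absolute standardized mean differences
(binary exposure) or absolute weighted exposure–covariate correlations
(continuous) with the conventional 0.1 threshold, and weight summaries
(mean far from 1, or extreme maxima, indicate positivity problems).

Two choices the literature leaves open:

* **SMD denominator.** The pooled unweighted standard deviation is computed
  once from the raw sample and reused for the weighted contrast, so the
  before/after columns share a scale. Categorical confounders are expanded
  to one indicator per level, reference level included, giving one balance
  row per level.
* **Numerator sample.** The marginal (numerator) probabilities and densities
  are estimated on the raw sample, not the weighted one.

Weights enter all downstream likelihoods as frequency-style weights, and all
confidence intervals use sandwich (HC0 by default, HC1 optional) covariance,
because the weighted score is no longer an ordinary maximum-likelihood
score. The sandwich treats the weights as fixed; the extra variability from
estimating the propensity model is ignored, which in the package's own
simulations leaves the weighted null coverage close to (slightly below)
nominal.

# Stage 2: the partitioning algorithm

Each node fits the two-parameter weighted logistic model
$\mathrm{logit}\, P(Y_i = 1) = \beta_0 + \beta_1 E_i$ by IRLS, keeping the
per-record score contributions $\psi_i = w_i (y_i - p_i) (1, E_i)^\top$.

**Instability testing.** For each candidate moderator $Z$ the node asks
whether $(\beta_0, \beta_1)$ is constant across $Z$, using the M-fluctuation
framework: under the null the decorrelated cumulative score process behaves
like a bivariate Brownian bridge.

* *Numeric moderators* use the supLM statistic — the supremum of the
  normalized squared process over the trimmed interval (default trimming
  fraction 0.1), evaluated at boundaries between distinct values. P-values
  come from a Monte-Carlo tabulation of the asymptotic distribution
  (200,000 simulated bridges on a 2,000-point grid for the two-parameter
  case; quantile interpolation with a log-linear tail beyond the table). A
  seeded Monte-Carlo fallback covers non-default trimming fractions.
* *Categorical moderators* — nominal **and** ordinal — use the within-level
  aggregated score statistic, asymptotically $\chi^2$ with $(C-1)\cdot 2$
  degrees of freedom. Treating ordinal questionnaire items through the
  categorical statistic rather than supLM is a deliberate choice: with only
  3–5 levels the supremum runs over at most four cut points, and the
  continuous supLM approximation is then conservative enough to distort the
  type-I error of the stopping rule; the categorical statistic is
  asymptotically exact. Order still matters where it should — in the split
  search (below), ordinal moderators admit only threshold splits.

The moderator with the smallest Bonferroni-adjusted p-value wins if it is
below $\alpha$; otherwise the node is terminal. Bonferroni adjustment
(multiplying by the number of testable candidates, capped at 1) defaults to
on — with ~40 candidates, familywise error control is what makes the
stopping rule interpretable — and is configurable.

**Split search.** Ordered moderators are cut at every observed distinct
value; nominal moderators are searched exhaustively over all
$2^{C-1} - 1$ binary level partitions (capped at 10 levels). A candidate is
admissible if both children keep at least `minsize` records (unweighted
counts, default 100) and both child fits converge; among admissible
candidates the summed child log-likelihood is maximized. Ties break toward
the smaller threshold / the earlier enumerated partition, making the tree
deterministic given the input ordering. Because the parent's parameters are
feasible in both children, every executed split weakly increases the summed
log-likelihood — an invariant the test suite checks on every tree it grows.

**Stopping rules.** $\alpha = 0.05$, `minsize = 100`, `maxdepth = 3` (the
root has depth 0, so subgroups are defined by at most three consecutive
conditions). Non-convergent or separated child fits invalidate the candidate
split rather than aborting the tree; a non-convergent node is closed as
terminal and flagged.

# Per-subgroup inference

For every terminal node: the odds ratio $\exp(\beta_1)$ with a robust Wald
interval; for continuous exposures the OR is rescaled to a 0.1-unit
increment ($\exp(0.1\,\beta_1)$), the conventional NDVI reporting scale.
For binary exposures the risk difference
$P[Y{=}1 \mid E{=}1] - P[Y{=}1 \mid E{=}0]$ is computed from weighted arm
proportions with a percentile bootstrap interval over 2,000 seeded resamples
of the node's records (weights carried along; resamples that lose an arm are
redrawn up to a cap and counted). The percentile method was chosen over BCa
for transparency; the replicate count and method are configurable. The
bootstrap resamples within the node with the tree held fixed — it quantifies
sampling noise of the node estimate, not the uncertainty of the tree search
itself.

**Heterogeneity vs prevalence.** Two sibling subgroups may differ in the
exposure slope (true effect heterogeneity of the odds ratio), only in the
intercept (different prevalence of the good outcome), in both or in
neither. The package formalizes the distinction with per-parameter robust
Wald contrasts $(\beta_a - \beta_b)/\sqrt{se_a^2 + se_b^2}$ at the 0.05
level, and also reports the informal CI-overlap comparison used in applied
papers. No multiplicity or post-selection correction is applied to these
contrasts (see Limitations).

# The synthetic cohort generator

The motivating cohort is not publicly available, so the generator is a
first-class module: every covariate is described by a marginal distribution,
a centred contribution to the exposure-assignment model (confounding
strength) and a centred contribution to the outcome log-odds. The
`kora_like_config()` defaults encode the published study conditions:

* n = 2534 complete cases; good-outcome prevalence 1926/2534 ≈ 0.76;
* binary exposure prevalences 774/2534 ≈ 0.305 (high-quality access) and
  2008/2534 ≈ 0.792 (very green neighbourhood); continuous exposure mean
  0.47, SD 0.09, truncated to the observed range [0.16, 0.73] (values
  outside the clamp are truncated, not resampled, preserving the monotone
  confounder–exposure association);
* four confounders (age 62.7 ± 9, home ownership 83.8%, urbanisation
  35.6/43.1/21.3, self-rated financial situation) driving both exposure and
  outcome;
* a 40-covariate moderator battery (binary, 3–5-level ordinal, 3–4-level
  nominal) including a binary sex-at-birth covariate;
* a planted depth-2 truth mirroring the published tree: ~30% reporting any
  disability discrimination form a leaf with lower baseline health and a
  near-null slope; among the rest, basic education (45%) marks a leaf with
  slope $\log 2.66$ and lower intercept, higher education a high-prevalence
  leaf with slope $\log 0.91$. Intercepts (0.49, 0.847, 1.735 before
  calibration) were set analytically, before any recovery test existed, to
  reproduce the published description (the higher-educated leaf healthy
  regardless of exposure) and the ~0.76 marginal prevalence.

Two scalar calibrations — the binary exposure-model intercept and a common
shift of all subgroup intercepts — are solved by a fixed-seed Monte-Carlo
root search at config-construction time so the simulated marginals hit the
printed targets exactly in expectation; the calibration is deterministic and
leaves all planted contrasts untouched. Each column draws from its own RNG
stream (a hash of the master seed and the column name), so adding a
covariate never perturbs the others' draws.

Switches used by the property tests: `null_moderators = TRUE` removes all
parameter instability (one subgroup) for stopping-rule calibration;
`null_effect = TRUE` zeroes all slopes and equalizes intercepts, making the
conditional null the unambiguous causal target for the weighting-debias
check (with a logistic link, marginal and conditional effects differ by
non-collapsibility except under the null, which is why the debias test uses
the null). The `confounding` multiplier scales the confounder–exposure
strengths; the debias scenario uses 3, the level at which the unweighted
estimate is reliably biased while weighting still balances every confounder
below 0.1 at $n = 10^4$.

What the generator does **not** emulate: covariate correlation structure
(the published marginals come without one; pairwise independence is the
default), item-level questionnaire responses, spatial structure of the NDVI
measures, and informative missingness (`inject_missing()` is independent
per cell). Passing recovery tests therefore show that the algorithmic
machinery works under the study's marginal and effect structure — not that
the pipeline is robust to correlated moderators or non-ignorable
missingness in real data.

# Simulation sizes and numerical choices

The package's own calibration checks run at the study's scale: n = 2534
cohorts with the full 40-moderator battery, 200 replicates for stopping-rule
calibration and IPW debiasing, 100 for split recovery, 500 n = 2000
replicates for supLM calibration, and n = 10^4 for balance checks —
together about a minute of compute, chosen to keep Monte-Carlo bands tight
(99% binomial band ±4 points at 200 replicates) while remaining quick to
rerun.

Degenerate inputs are handled explicitly: single-class outcomes and constant
exposures are errors at the root and inadmissible for children; perfect
separation in the propensity model is an error pointing at positivity;
separated node fits are flagged non-converged (coefficients beyond ±15 on
the logit scale or fitted probabilities at machine bounds); zero-variance
balance covariates report 0 with a warning; singular score covariance skips
the covariate with a warning. Kernel density estimates are computed in
chunks to avoid $n^2$ memory.

# Known limitations

* Inference in terminal nodes is conditional on the discovered tree; no
  honest sample-splitting or selective-inference correction is applied, so
  subgroup confidence intervals are optimistic to a degree that grows with
  the strength of the search.
* The weighted likelihood-ratio interaction test treats weights as
  frequencies, so its $\chi^2$ calibration is approximate; a robust Wald
  interaction test is reported alongside.
* The sandwich intervals ignore the estimation of the weights themselves.
* Missing data are handled only by complete-case filtering (imputation and
  surrogate splits are out of scope by design).
* The categorical instability statistic ignores the ordering of ordinal
  moderators at the testing step (power is spread over all level contrasts);
  ordering is honoured at the split step.
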