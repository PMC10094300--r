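# greenmob

Subgroup discovery for green-space epidemiology: **stabilized
inverse-probability weighting** plus **model-based recursive partitioning
(MOB)** of weighted binary logistic exposure–outcome models, with per-subgroup
effect inference.

## The problem

Observational cohort studies of residential green space and self-rated health
ask two questions at once:

1. *Confounding* — exposure to green space is not randomized; age, home
   ownership, urbanisation and financial situation all push both exposure and
   health. The package answers this with propensity-score weighting:
   stabilized weights `sw_i = P(E = e_i) / P(E = e_i | X_i)` for a binary
   exposure (propensity via logistic regression) and
   `sw_i = f(E_i) / f(E_i | X_i)` for a continuous NDVI-like exposure
   (generalized propensity via a linear exposure model with kernel density
   estimation of the residuals). Balance is diagnosed by absolute
   standardized mean differences (binary exposure) or weighted
   exposure–covariate correlations (continuous), with the conventional 0.1
   threshold, plus weight-based positivity checks.

2. *Effect heterogeneity* — does the exposure effect differ across subgroups
   defined by many candidate moderators (discrimination experience,
   education, income, sex/gender-related covariates, ...)? In every node the
   package fits the weighted logistic model

   `logit P(Y = 1) = β0 + β1 · E`

   and tests *parameter instability* of `(β0, β1)` against each candidate
   moderator using score-based fluctuation tests (supLM along numeric
   moderators; a `(C−1)·2`-df chi-square statistic for categorical ones).
   If the smallest Bonferroni-adjusted p-value is below α = 0.05 the node is
   split at the cut maximizing the summed child log-likelihoods; otherwise
   the node is terminal. Additional stopping rules: ≥ 100 records per node
   and maximum depth 3. Terminal subgroups are summarised by odds ratios
   `exp(β1)` with robust (sandwich) confidence intervals, bootstrap risk
   differences, and each split is classified as *slope heterogeneity* (the
   odds ratios differ) versus a mere *prevalence difference* (only the
   intercepts differ) via robust Wald contrasts.

Because the motivating cohort data are not publicly available, the package
ships a seeded synthetic-cohort generator that emulates the study's
structure — the printed marginals (76% good self-rated health, exposure
prevalences 30.5% / 79.2%, NDVI mean 0.47 SD 0.09 on [0.16, 0.73]),
confounded exposure assignment, a 40-covariate mixed-type moderator battery,
and a planted depth-2 partition whose leaves carry the published odds-ratio
contrast 2.66 vs 0.91 — so that calibration, recovery and debiasing
properties are all testable.

## Worked example

```r
library(greenmob)

cfg  <- kora_like_config("binary_quality")      # n = 2534, planted truth
tab  <- generate_cohort(cfg, seed = 42)
ws   <- stabilized_weights(fit_propensity_binary(
          tab, "green_quality",
          c("age", "home_owner", "urbanisation", "financial_situation")))
ws
#> stabilized weights, n = 2534
#>   mean    min    max
#> 1.0000 0.4938 3.2868

tree <- grow_tree(tab, "srh", "green_quality", ws,
                  cohort_columns(tab, "moderator"))
tree
#> Model-based recursive partition (weighted logistic: srh ~ green_quality)
#> [1] n = 2534, b0 = 1.145, b1 = 0.439 (OR = 1.552)
#>   [2] discrimination_disability <= rather_disagree: n = 746, b0 = 0.641, b1 = 0.312 (OR = 1.366)
#>   [3] discrimination_disability > rather_disagree: n = 1788, b0 = 1.405, b1 = 0.493 (OR = 1.637)
#>     [4] school_education <= basic: n = 799, b0 = 1.006, b1 = 1.186 (OR = 3.275)
#>     [5] school_education > basic: n = 989, b0 = 1.806, b1 = -0.108 (OR = 0.898)

node_effects(tree)
#>   node   n prevalence beta0  beta1    or or_lo or_hi converged
#> 1    2 746      0.674 0.641  0.312 1.366 0.953  1.96      TRUE
#> 2    4 799      0.786 1.006  1.186 3.275 2.036  5.27      TRUE
#> 3    5 989      0.855 1.806 -0.108 0.898 0.598  1.35      TRUE

classify_splits(tree)
#>   node                 covariate                 label z_beta0 z_beta1
#> 1    1 discrimination_disability prevalence difference   -6.57  -0.752
#> 2    3          school_education                  both   -5.48   4.055
```

The tree recovers the planted structure: the root split separates
participants reporting disability discrimination (a lower-prevalence
subgroup, same exposure effect — a *prevalence difference*), and within the
non-discriminated branch the education split uncovers genuine *slope
heterogeneity*: a strong positive green-space association for participants
with basic education (OR 3.3, planted 2.66) and none for the
higher-educated, high-prevalence leaf (OR 0.90, planted 0.91).

Contingency-table odds ratios work directly from printed counts:

```r
res <- or_from_2x2(641, 133, 1285, 475)
sprintf("OR %.2f [%.2f, %.2f]", res$or, res$ci[1], res$ci[2])
#> "OR 1.78 [1.44, 2.21]"
```

`run_pipeline(run_config(...))` chains everything — generation or CSV input,
complete-case filtering, weighting, balance/positivity diagnostics, tree,
effects with bootstrap risk differences, split classification — and writes a
manifest with content hashes for reproducibility. A thin CLI wrapper lives at
`inst/cli/greenmob.R` (subcommands `simulate`, `weight`, `tree`, `effects`,
`run`, `or2x2`).

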