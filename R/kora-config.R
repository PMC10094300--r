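#' Default cohort configuration matching the study's printed marginals
#'
#' Builds a ready-to-use [generator_config()] emulating the complete-case
#' cohort the analysis targets: n = 2534 participants; a binary self-rated
#' health outcome with ~76% in the good category; one of three exposures
#' (high-quality green-space access, prevalence 774/2534 = 0.305; very-green
#' neighbourhood, prevalence 2008/2534 = 0.792; or an NDVI-like continuous
#' greenness with mean 0.47, SD 0.09, truncated to the observed range
#' [0.16, 0.73]); four confounders (age, home ownership, urbanisation degree,
#' self-rated financial situation) that drive both exposure and outcome; and
#' 40 mixed-type moderator covariates, of which two (a disability
#' discrimination item and school education) carry the planted subgroup
#' structure.
#'
#' The planted partition mirrors the published quality-exposure tree: the
#' ~30% who report any disability discrimination form a low-prevalence leaf;
#' among the rest, participants with basic education form a leaf with a
#' strong positive exposure effect (OR 2.66) while the higher-educated leaf
#' has a high good-health prevalence and essentially no exposure effect
#' (OR 0.91).
#'
#' The exposure-model intercept (binary exposures) and a common shift of the
#' subgroup intercepts are calibrated by a fixed-seed Monte-Carlo root search
#' so the generated marginals hit the targets above; the calibration is
#' deterministic and leaves the planted contrasts untouched.
#'
#' @param exposure_kind `"binary_quality"`, `"binary_greenness"` or
#'   `"continuous"` (300 m NDVI-like).
#' @param n cohort size; default 2534.
#' @param null_effect if `TRUE`, all planted slopes are set to zero and
#'   subgroup intercepts are equalised (used for weighting-debias checks
#'   where the conditional null makes the causal target unambiguous).
#' @param null_moderators if `TRUE`, the planted partition is replaced by a
#'   single subgroup (no parameter instability anywhere), for stopping-rule
#'   calibration.
#' @param confounding multiplier on all confounder strengths (0 removes
#'   confounding, values > 1 strengthen it).
#' @param seed default master seed stored in the config.
#' @return a [generator_config()].
#' @examples
#' cfg <- kora_like_config("binary_quality", n = 500)
#' tab <- generate_cohort(cfg, seed = 7)
#' mean(tab$green_quality == "high_quality")
#' @export
kora_like_config <- function(exposure_kind = c("binary_quality",
                                               "binary_greenness",
                                               "continuous"),
                             n = 2534,
                             null_effect = FALSE,
                             null_moderators = FALSE,
                             confounding = 1,
                             seed = 1L) {
  exposure_kind <- match.arg(exposure_kind)
  cs <- confounding

  confounders <- list(
    covariate_spec("age", "continuous", mean = 62.7, sd = 9,
                   confounder_strength = -0.25 * cs,
                   outcome_strength = -0.35),
    covariate_spec("home_owner", "binary", levels = c("rent", "own"),
                   probs = c(0.162, 0.838),
                   confounder_strength = 0.5 * cs, outcome_strength = 0.4),
    covariate_spec("urbanisation", "nominal",
                   levels = c("city", "suburb", "rural"),
                   probs = c(0.356, 0.431, 0.213),
                   confounder_strength = c(0.4, 0, -0.2) * cs,
                   outcome_strength = c(-0.2, 0, 0.1)),
    covariate_spec("financial_situation", "ordinal",
                   levels = c("bad", "moderate", "good", "very_good"),
                   probs = c(0.05, 0.25, 0.50, 0.20),
                   confounder_strength = 0.3 * cs, outcome_strength = 0.35)
  )

  planted <- list(
    covariate_spec("discrimination_disability", "ordinal",
                   levels = c("strongly_agree", "rather_agree",
                              "neither", "rather_disagree",
                              "strongly_disagree"),
                   probs = c(0.06, 0.06, 0.08, 0.10, 0.70)),
    covariate_spec("school_education", "ordinal",
                   levels = c("basic", "o_level", "a_level"),
                   probs = c(0.45, 0.33, 0.22))
  )

  moderators <- c(planted, list(
    covariate_spec("sex_at_birth", "binary", levels = c("male", "female"),
                   probs = c(0.48, 0.52))
  ))
  # generic null moderators filling the 40-covariate battery
  filler_specs <- function(prefix, kinds) {
    out <- list()
    for (i in seq_along(kinds)) {
      nm <- sprintf("%s%02d", prefix, i)
      out[[i]] <- switch(kinds[i],
        b = covariate_spec(nm, "binary", levels = c("no", "yes"),
                           probs = c(0.3 + 0.01 * i, 0.7 - 0.01 * i)),
        o4 = covariate_spec(nm, "ordinal",
                            levels = c("l1", "l2", "l3", "l4"),
                            probs = c(0.15, 0.35, 0.30, 0.20)),
        o5 = covariate_spec(nm, "ordinal",
                            levels = c("l1", "l2", "l3", "l4", "l5"),
                            probs = c(0.10, 0.20, 0.30, 0.25, 0.15)),
        n3 = covariate_spec(nm, "nominal", levels = c("a", "b", "c"),
                            probs = c(0.4, 0.35, 0.25)),
        n4 = covariate_spec(nm, "nominal", levels = c("a", "b", "c", "d"),
                            probs = c(0.3, 0.3, 0.25, 0.15)))
    }
    out
  }
  moderators <- c(moderators,
                  filler_specs("mod_", rep(c("b", "o4", "o5", "n3", "n4"),
                                           length.out = 37)))

  if (null_moderators) {
    truth <- planted_truth(list(
      truth_subgroup("all", list(), beta0 = 1.2,
                     beta1 = if (exposure_kind == "continuous") 0.6 else 0.3)
    ))
  } else {
    b1 <- if (exposure_kind == "continuous") {
      # per NDVI unit; ORs per 0.1 increment: 1.05, 1.49, 0.96
      c(0.5, 4.0, -0.4)
    } else {
      c(0.10, log(2.66), log(0.91))
    }
    b0 <- c(0.49, 0.847, 1.735)
    if (null_effect) {
      b1 <- c(0, 0, 0)
      b0 <- c(1.2, 1.2, 1.2)
    }
    truth <- planted_truth(list(
      truth_subgroup("discriminated",
                     list(list(covariate = "discrimination_disability",
                               op = "<=", value = "rather_disagree")),
                     beta0 = b0[1], beta1 = b1[1]),
      truth_subgroup("no_discrimination_basic_edu",
                     list(list(covariate = "discrimination_disability",
                               op = ">", value = "rather_disagree"),
                          list(covariate = "school_education",
                               op = "<=", value = "basic")),
                     beta0 = b0[2], beta1 = b1[2]),
      truth_subgroup("no_discrimination_higher_edu",
                     list(list(covariate = "discrimination_disability",
                               op = ">", value = "rather_disagree"),
                          list(covariate = "school_education",
                               op = ">", value = "basic")),
                     beta0 = b0[3], beta1 = b1[3])
    ))
  }

  covariates <- c(confounders, moderators)

  if (exposure_kind == "continuous") {
    exposure_model <- list(
      name = "ndvi_300m", intercept = 0.47,
      noise_sd = 0.0835, clamp = c(0.16, 0.73))
    # confounder strengths on the NDVI scale
    scale_map <- c(age = -0.015 / -0.25, home_owner = 0.02 / 0.5,
                   financial_situation = 0.015 / 0.3)
    for (i in seq_along(covariates)) {
      nm <- covariates[[i]]$name
      if (nm %in% names(scale_map)) {
        covariates[[i]]$confounder_strength <-
          covariates[[i]]$confounder_strength * scale_map[[nm]]
      } else if (nm == "urbanisation") {
        covariates[[i]]$confounder_strength <- c(-0.03, 0, 0.04) * cs
      }
    }
  } else {
    target_prev <- if (exposure_kind == "binary_quality") 774 / 2534
                   else 2008 / 2534
    lev <- if (exposure_kind == "binary_quality") {
      c("lower_or_no", "high_quality")
    } else {
      c("less_green", "very_green")
    }
    exposure_model <- list(name = if (exposure_kind == "binary_quality")
                                    "green_quality" else "green_neighbourhood",
                           intercept = 0, levels = lev)
  }

  cfg <- generator_config(
    n = n, covariates = covariates, exposure_kind =
      if (exposure_kind == "continuous") "continuous" else "binary",
    exposure_model = exposure_model, truth = truth,
    outcome = list(name = "srh", levels = c("bad", "good")), seed = seed)

  calibrate_config(cfg,
                   exposure_target = if (exposure_kind == "continuous") NULL
                                     else target_prev,
                   outcome_target = 1926 / 2534)
}

# Fixed-seed Monte-Carlo calibration: solves for the binary-exposure
# intercept and a common outcome-intercept shift so simulated marginals hit
# their targets. Deterministic (internal seed), preserves planted contrasts.
calibrate_config <- function(cfg, exposure_target = NULL,
                             outcome_target = NULL, n_mc = 1e5) {
  specs <- cfg$covariates
  names(specs) <- vapply(specs, `[[`, "", "name")
  draws <- with_seed(880731L, {
    d <- lapply(specs, function(s) draw_covariate(s, n_mc, sample.int(1e8, 1)))
    as.data.frame(d, stringsAsFactors = FALSE)
  })
  lp_e <- rep(0, n_mc)
  for (s in specs) {
    lp_e <- lp_e + spec_contrib(s, draws[[s$name]], s$confounder_strength)
  }
  if (!is.null(exposure_target) && cfg$exposure_kind == "binary") {
    f <- function(b0) mean(stats::plogis(b0 + lp_e)) - exposure_target
    cfg$exposure_model$intercept <-
      stats::uniroot(f, c(-10, 10), tol = 1e-8)$root
  }
  if (!is.null(outcome_target)) {
    if (cfg$exposure_kind == "binary") {
      e_num <- with_seed(880732L,
                         stats::rbinom(n_mc, 1L,
                                       stats::plogis(cfg$exposure_model$intercept + lp_e)))
    } else {
      em <- cfg$exposure_model
      e_num <- with_seed(880732L,
                         em$intercept + lp_e + stats::rnorm(n_mc, 0, em$noise_sd))
      e_num <- pmin(pmax(e_num, em$clamp[1]), em$clamp[2])
    }
    g <- assign_subgroups(cfg$truth, draws, specs)
    beta0 <- vapply(cfg$truth$subgroups, `[[`, 0, "beta0")
    beta1 <- vapply(cfg$truth$subgroups, `[[`, 0, "beta1")
    lp_y <- beta0[g] + beta1[g] * e_num
    for (s in specs) {
      lp_y <- lp_y + spec_contrib(s, draws[[s$name]], s$outcome_strength)
    }
    f <- function(d) mean(stats::plogis(lp_y + d)) - outcome_target
    shift <- stats::uniroot(f, c(-5, 5), tol = 1e-8)$root
    for (j in seq_along(cfg$truth$subgroups)) {
      cfg$truth$subgroups[[j]]$beta0 <- cfg$truth$subgroups[[j]]$beta0 + shift
    }
  }
  cfg
}

#' Serialize and restore generator configurations
#'
#' Configurations round-trip through JSON or YAML (chosen by file
#' extension) unchanged, so simulation settings can live beside results.
#'
#' @param config a [generator_config()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_generator_config()` returns the restored config.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$covariates <- lapply(x$covariates, unclass)
  x$truth <- unclass(x$truth)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 17)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  }
  covs <- lapply(x$covariates, function(s) {
    do.call(covariate_spec, s[!vapply(s, is.null, TRUE)])
  })
  subgroups <- lapply(x$truth$subgroups, function(g) {
    conds <- lapply(g$conditions, function(cd) {
      cd$value <- unlist(cd$value)
      cd
    })
    truth_subgroup(g$name, conds, g$beta0, g$beta1)
  })
  em <- x$exposure_model
  if (!is.null(em$clamp)) em$clamp <- unlist(em$clamp)
  if (!is.null(em$levels)) em$levels <- unlist(em$levels)
  out <- x$outcome
  out$levels <- unlist(out$levels)
  mr <- x$missing_rates
  if (!is.null(mr)) mr <- unlist(mr)
  generator_config(n = x$n, covariates = covs, exposure_kind = x$exposure_kind,
                   exposure_model = em, truth = planted_truth(subgroups),
                   outcome = out, missing_rates = mr, seed = x$seed)
}
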