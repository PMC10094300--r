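#' Specify a synthetic covariate
#'
#' Describes one covariate of the synthetic cohort: its marginal distribution,
#' how strongly it pushes participants toward exposure (confounding) and how
#' strongly it shifts the baseline log-odds of a good outcome.
#'
#' Categorical contributions are centred at the marginal mean so that
#' confounder and outcome strengths do not move the cohort-level exposure
#' prevalence or outcome prevalence; a scalar `confounder_strength` acts
#' linearly on the 0-based level code, a length-`k` vector gives one
#' contribution per level. Continuous covariates contribute
#' `strength * (x - mean) / sd`.
#'
#' @param name column name.
#' @param kind one of `"binary"`, `"ordinal"`, `"nominal"`, `"continuous"`.
#' @param levels level labels (categorical kinds), in order for ordinal.
#' @param probs marginal probability vector over `levels` (must sum to 1).
#' @param mean,sd marginal mean and SD (continuous kind).
#' @param confounder_strength log-odds (binary exposure) or linear (continuous
#'   exposure) contribution to exposure assignment; scalar or per-level vector.
#' @param outcome_strength log-odds contribution to the outcome; same
#'   convention.
#' @param role optional explicit schema role (`"confounder"` or
#'   `"moderator"`); by default covariates with non-zero
#'   `confounder_strength` are tagged confounders, all others moderators.
#' @return a `covariate_spec` list.
#' @export
covariate_spec <- function(name, kind,
                           levels = NULL, probs = NULL,
                           mean = 0, sd = 1,
                           confounder_strength = 0, outcome_strength = 0,
                           role = NULL) {
  kind <- match.arg(kind, c("binary", "ordinal", "nominal", "continuous"))
  if (kind == "continuous") {
    if (!is.numeric(sd) || sd <= 0) stop("covariate ", name, ": sd must be > 0",
                                         call. = FALSE)
  } else {
    if (kind == "binary" && is.null(levels)) levels <- c("no", "yes")
    if (is.null(levels) || length(levels) < 2) {
      stop("covariate ", name, ": categorical kinds need >= 2 levels",
           call. = FALSE)
    }
    if (kind == "binary" && length(levels) != 2) {
      stop("covariate ", name, ": binary kind needs exactly 2 levels",
           call. = FALSE)
    }
    if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
    if (length(probs) != length(levels)) {
      stop("covariate ", name, ": probs must match levels", call. = FALSE)
    }
    if (abs(sum(probs) - 1) > 1e-12 || any(probs < 0)) {
      stop("covariate ", name, ": probs must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  for (s in list(confounder_strength, outcome_strength)) {
    if (!length(s) %in% c(1L, length(levels %||% 1))) {
      stop("covariate ", name,
           ": strength must be scalar or one value per level", call. = FALSE)
    }
  }
  structure(list(name = name, kind = kind, levels = levels, probs = probs,
                 mean = mean, sd = sd,
                 confounder_strength = confounder_strength,
                 outcome_strength = outcome_strength, role = role),
            class = "covariate_spec")
}

#' Planted subgroup truth
#'
#' Defines the true partition of the covariate space and the per-subgroup
#' logistic parameters `(beta0, beta1)` driving the outcome. Subgroups are
#' conjunctions of at most three covariate conditions and must be mutually
#' exclusive and exhaustive (validated record-wise at generation time).
#'
#' @param subgroups a list of subgroups built with [truth_subgroup()].
#' @return a `planted_truth` object.
#' @export
planted_truth <- function(subgroups) {
  stopifnot(length(subgroups) >= 1)
  for (g in subgroups) {
    if (length(g$conditions) > 3) {
      stop("subgroup ", g$name, ": conjunction depth must be <= 3",
           call. = FALSE)
    }
  }
  structure(list(subgroups = subgroups), class = "planted_truth")
}

#' @rdname planted_truth
#' @param name subgroup label.
#' @param conditions list of conditions, each
#'   `list(covariate =, op = "<="|">"|"in", value =)`; for ordinal covariates
#'   `value` is a level label and comparison is by level order, for `"in"` a
#'   vector of level labels, for continuous a numeric threshold.
#' @param beta0,beta1 subgroup log-odds intercept and exposure slope.
#' @export
truth_subgroup <- function(name, conditions, beta0, beta1) {
  list(name = name, conditions = conditions, beta0 = beta0, beta1 = beta1)
}

#' Synthetic cohort generator configuration
#'
#' @param n number of records.
#' @param covariates list of [covariate_spec()] objects.
#' @param exposure_kind `"binary"` or `"continuous"`.
#' @param exposure_model list with `name` (column name), `intercept`, and for
#'   continuous exposure `noise_sd` and `clamp = c(lo, hi)`; confounder
#'   contributions come from the covariates' `confounder_strength`. For binary
#'   exposure `levels = c(negative, positive)`.
#' @param truth a [planted_truth()].
#' @param outcome list with `name` and `levels = c(negative, positive)`;
#'   defaults to self-rated health coding `c("bad", "good")`.
#' @param missing_rates named numeric vector of per-column missingness
#'   probabilities in `[0, 1]` (applied only by [inject_missing()]).
#' @param seed default master seed used by [generate_cohort()].
#' @return a validated `generator_config`.
#' @export
generator_config <- function(n, covariates, exposure_kind, exposure_model,
                             truth,
                             outcome = list(name = "srh",
                                            levels = c("bad", "good")),
                             missing_rates = NULL, seed = 1L) {
  cfg <- structure(list(n = n, covariates = covariates,
                        exposure_kind = exposure_kind,
                        exposure_model = exposure_model, truth = truth,
                        outcome = outcome, missing_rates = missing_rates,
                        seed = seed),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || cfg$n < 1 ||
      cfg$n != round(cfg$n)) {
    stop("invalid generator config field 'n': must be a positive integer",
         call. = FALSE)
  }
  if (!cfg$exposure_kind %in% c("binary", "continuous")) {
    stop("invalid generator config field 'exposure_kind': ",
         cfg$exposure_kind, call. = FALSE)
  }
  if (!length(cfg$covariates)) {
    stop("invalid generator config field 'covariates': empty", call. = FALSE)
  }
  nms <- vapply(cfg$covariates, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("invalid generator config field 'covariates': duplicate names",
         call. = FALSE)
  }
  em <- cfg$exposure_model
  if (is.null(em$name)) {
    stop("invalid generator config field 'exposure_model': missing name",
         call. = FALSE)
  }
  if (cfg$exposure_kind == "continuous") {
    cl <- em$clamp
    if (is.null(cl) || length(cl) != 2 || cl[1] >= cl[2]) {
      stop("invalid generator config field 'exposure_model$clamp': ",
           "bounds must be ordered", call. = FALSE)
    }
    if (is.null(em$noise_sd) || em$noise_sd <= 0) {
      stop("invalid generator config field 'exposure_model$noise_sd'",
           call. = FALSE)
    }
  }
  if (!inherits(cfg$truth, "planted_truth")) {
    stop("invalid generator config field 'truth'", call. = FALSE)
  }
  if (!is.null(cfg$missing_rates)) {
    mr <- cfg$missing_rates
    if (any(mr < 0 | mr > 1)) {
      stop("invalid generator config field 'missing_rates': must be in [0, 1]",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# centred contribution of one covariate to a linear predictor
spec_contrib <- function(spec, values, strength) {
  if (all(strength == 0)) return(numeric(length(values)))
  if (spec$kind == "continuous") {
    return(strength * (values - spec$mean) / spec$sd)
  }
  code0 <- as.integer(values) - 1L
  if (length(strength) == 1L) {
    strength * (code0 - sum(spec$probs * (seq_along(spec$levels) - 1L)))
  } else {
    strength[code0 + 1L] - sum(spec$probs * strength)
  }
}

draw_covariate <- function(spec, n, seed) {
  with_seed(seed, {
    if (spec$kind == "continuous") {
      stats::rnorm(n, spec$mean, spec$sd)
    } else {
      codes <- sample.int(length(spec$levels), n, replace = TRUE,
                          prob = spec$probs)
      factor(spec$levels[codes], levels = spec$levels,
             ordered = spec$kind == "ordinal")
    }
  })
}

condition_holds <- function(cond, column, spec) {
  if (!is.null(spec) && spec$kind %in% c("binary", "ordinal", "nominal")) {
    if (cond$op == "in") {
      idx <- match_levels(cond$value, spec$levels, "truth level")
      return(as.integer(column) %in% idx)
    }
    thr <- match_levels(cond$value, spec$levels, "truth level")
    code <- as.integer(column)
    if (cond$op == "<=") return(code <= thr)
    if (cond$op == ">") return(code > thr)
  } else {
    if (cond$op == "<=") return(column <= cond$value)
    if (cond$op == ">") return(column > cond$value)
    if (cond$op == "in") return(column %in% cond$value)
  }
  stop("unsupported truth condition op: ", cond$op, call. = FALSE)
}

assign_subgroups <- function(truth, data, specs) {
  n <- nrow(data)
  hit <- matrix(FALSE, n, length(truth$subgroups))
  for (j in seq_along(truth$subgroups)) {
    g <- truth$subgroups[[j]]
    ok <- rep(TRUE, n)
    for (cond in g$conditions) {
      spec <- specs[[cond$covariate]]
      ok <- ok & condition_holds(cond, data[[cond$covariate]], spec)
    }
    hit[, j] <- ok
  }
  nhit <- rowSums(hit)
  if (any(nhit != 1)) {
    stop("planted truth is not a partition: ", sum(nhit == 0),
         " records match no subgroup, ", sum(nhit > 1),
         " match several", call. = FALSE)
  }
  max.col(hit, ties.method = "first")
}

#' Generate a synthetic cohort with planted subgroup structure
#'
#' Draws covariates from their marginals (one RNG stream per column, split
#' from the master seed), assigns exposure from the confounded exposure model
#' (logistic for binary, linear-plus-Gaussian-noise with truncation to the
#' clamp interval for continuous), maps each record to its true subgroup and
#' draws the binary outcome with log-odds
#' `beta0(g) + beta1(g) * E + sum(outcome contributions)`.
#'
#' @param config a [generator_config()].
#' @param seed master seed; defaults to `config$seed`. Identical
#'   `(config, seed)` pairs yield identical tables.
#' @return a [cohort_table()] with roles attached; the `true_subgroup` column
#'   (role `"truth"`) records the planted subgroup of each record and the
#'   `planted_truth` is attached as attribute `"truth"`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_generator_config(config)
  n <- as.integer(config$n)
  specs <- config$covariates
  names(specs) <- vapply(specs, `[[`, "", "name")

  data <- list()
  for (spec in specs) {
    data[[spec$name]] <- draw_covariate(spec, n, str_seed(seed, spec$name))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  # exposure
  em <- config$exposure_model
  lp_e <- rep(0, n)
  for (spec in specs) {
    lp_e <- lp_e + spec_contrib(spec, data[[spec$name]],
                                spec$confounder_strength)
  }
  if (config$exposure_kind == "binary") {
    p_e <- stats::plogis(em$intercept + lp_e)
    e01 <- with_seed(str_seed(seed, paste0("exposure:", em$name)),
                     stats::rbinom(n, 1L, p_e))
    lev <- em$levels %||% c("unexposed", "exposed")
    data[[em$name]] <- factor(lev[e01 + 1L], levels = lev)
    e_num <- e01
  } else {
    raw <- with_seed(str_seed(seed, paste0("exposure:", em$name)),
                     em$intercept + lp_e + stats::rnorm(n, 0, em$noise_sd))
    e_num <- pmin(pmax(raw, em$clamp[1]), em$clamp[2])
    data[[em$name]] <- e_num
  }

  # outcome
  g <- assign_subgroups(config$truth, data, specs)
  beta0 <- vapply(config$truth$subgroups, `[[`, 0, "beta0")
  beta1 <- vapply(config$truth$subgroups, `[[`, 0, "beta1")
  lp_y <- beta0[g] + beta1[g] * e_num
  for (spec in specs) {
    lp_y <- lp_y + spec_contrib(spec, data[[spec$name]], spec$outcome_strength)
  }
  y01 <- with_seed(str_seed(seed, paste0("outcome:", config$outcome$name)),
                   stats::rbinom(n, 1L, stats::plogis(lp_y)))
  ylev <- config$outcome$levels
  data[[config$outcome$name]] <- factor(ylev[y01 + 1L], levels = ylev)
  gnames <- vapply(config$truth$subgroups, `[[`, "", "name")
  data$true_subgroup <- factor(gnames[g], levels = gnames)

  schema <- lapply(specs, function(s) {
    list(role = if (any(s$confounder_strength != 0)) "confounder" else "moderator",
         kind = s$kind, levels = s$levels)
  })
  # a covariate may both confound and moderate; an explicit role wins
  for (nm in names(specs)) {
    if (!is.null(specs[[nm]]$role)) schema[[nm]]$role <- specs[[nm]]$role
  }
  schema[[em$name]] <- list(
    role = "exposure",
    kind = if (config$exposure_kind == "binary") "binary" else "continuous",
    levels = if (config$exposure_kind == "binary")
      em$levels %||% c("unexposed", "exposed"))
  schema[[config$outcome$name]] <- list(role = "outcome", kind = "binary",
                                        levels = ylev)
  schema$true_subgroup <- list(role = "truth", kind = "nominal",
                               levels = gnames)
  out <- cohort_table(data, schema)
  attr(out, "truth") <- config$truth
  out
}

#' Inject independent missingness into a cohort
#'
#' Each cell of a listed column is independently set to `NA` with that
#' column's rate; seeded per column so results are reproducible and unaffected
#' by other columns' rates.
#'
#' @param table a [cohort_table()].
#' @param missing_rates named vector of probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return the table with missing values injected.
#' @export
inject_missing <- function(table, missing_rates, seed = 1L) {
  if (any(missing_rates < 0 | missing_rates > 1)) {
    stop("missing rates must be in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(names(missing_rates), names(table))
  if (length(bad)) stop("unknown columns: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(missing_rates)) {
    r <- missing_rates[[nm]]
    if (r == 0) next
    hit <- with_seed(str_seed(seed, paste0("miss:", nm)),
                     stats::runif(nrow(table)) < r)
    table[[nm]][hit] <- NA
  }
  table
}
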