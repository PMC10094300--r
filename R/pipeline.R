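#' Odds ratio from a 2x2 contingency table
#'
#' Cross-product odds ratio `(a d) / (b c)` with the Woolf log-scale
#' confidence interval `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' No continuity correction: a zero cell is an error.
#'
#' @param a,b,c,d counts: exposed-good, exposed-bad, unexposed-good,
#'   unexposed-bad.
#' @param level confidence level (default 0.95).
#' @return a list: `or`, `log_or`, `se_log_or`, `ci`.
#' @examples
#' or_from_2x2(641, 133, 1285, 475)$or   # 1.78 to 2 d.p.
#' @export
or_from_2x2 <- function(a, b, c, d, level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(counts == 0)) {
    stop("zero cell: odds ratio undefined without continuity correction",
         call. = FALSE)
  }
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(log_or), log_or = log_or, se_log_or = se,
       ci = exp(log_or + c(-1, 1) * z * se))
}

#' Weighted likelihood-ratio test for an exposure-by-group interaction
#'
#' Compares weighted logistic models of the outcome with and without an
#' `exposure x group` interaction term, reporting twice the difference in
#' maximized weighted log-likelihood against a chi-square with 1 degree of
#' freedom, plus stratified exposure odds ratios with robust confidence
#' intervals per group. Because the likelihood is weighted, the chi-square
#' calibration is approximate; a robust Wald test of the interaction
#' coefficient is reported alongside.
#'
#' @param outcome binary outcome (0/1 or two-level factor).
#' @param exposure binary or numeric exposure.
#' @param group binary grouping variable (e.g. sex assigned at birth).
#' @param weights positive weights, a `weight_set`, or `NULL`.
#' @param level confidence level of the stratified ORs.
#' @return a list: `statistic`, `df`, `p_value`, `wald_z`, `wald_p`,
#'   `group_effects` (per-group OR with robust CI).
#' @export
weighted_interaction_lrt <- function(outcome, exposure, group,
                                     weights = NULL, level = 0.95) {
  y <- outcome_numeric(outcome)
  e <- exposure_numeric(exposure)
  if (is.numeric(group) && !is_binary01(group)) {
    stop("group must be binary", call. = FALSE)
  }
  g <- exposure_numeric(group)
  w <- if (inherits(weights, "weight_set")) weights$w
       else weights %||% rep(1, length(y))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (length(unique(g)) < 2) stop("degenerate strata: group is constant",
                                  call. = FALSE)
  for (gv in c(0, 1)) {
    if (length(unique(y[g == gv])) < 2 || length(unique(e[g == gv])) < 2) {
      stop("degenerate strata: outcome or exposure constant within a group",
           call. = FALSE)
    }
  }
  X0 <- cbind(1, e, g)
  X1 <- cbind(X0, e * g)
  f0 <- weighted_logistic(X0, y, w,
                          c("(Intercept)", "exposure", "group"))
  f1 <- weighted_logistic(X1, y, w,
                          c("(Intercept)", "exposure", "group",
                            "exposure:group"))
  stat <- 2 * (f1$loglik - f0$loglik)
  wald_z <- f1$coef[4] / sqrt(f1$vcov_sandwich[4, 4])
  z <- stats::qnorm(1 - (1 - level) / 2)
  strata <- lapply(c(0, 1), function(gv) {
    fit <- fit_weighted_logistic(y[g == gv], e[g == gv], w[g == gv])
    se <- sqrt(fit$vcov_sandwich[2, 2])
    data.frame(group = gv, or = exp(fit$coef[2]),
               or_lo = exp(fit$coef[2] - z * se),
               or_hi = exp(fit$coef[2] + z * se), n = fit$n)
  })
  list(statistic = stat, df = 1,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       wald_z = unname(wald_z),
       wald_p = unname(2 * stats::pnorm(-abs(wald_z))),
       group_effects = do.call(rbind, strata))
}

#' Configure an end-to-end analysis run
#'
#' @param input either a [generator_config()] (the cohort is simulated) or a
#'   path to a cohort CSV with its schema sidecar.
#' @param exposure,outcome column names; when `NULL` they are read from the
#'   schema roles.
#' @param confounders,moderators column names; when `NULL`, schema roles
#'   decide. The exposure may appear in neither list.
#' @param control a [mob_control()].
#' @param bootstrap list with `B` and logical `enabled`.
#' @param ci_level confidence level for reported intervals.
#' @param seed master seed for the run (generator and bootstrap).
#' @param out_dir output directory; created if needed.
#' @return a validated `run_config`.
#' @export
run_config <- function(input, exposure = NULL, outcome = NULL,
                       confounders = NULL, moderators = NULL,
                       control = mob_control(),
                       bootstrap = list(enabled = TRUE, B = 2000),
                       ci_level = 0.95, seed = 1L, out_dir = tempfile("run")) {
  cfg <- structure(list(input = input, exposure = exposure,
                        outcome = outcome, confounders = confounders,
                        moderators = moderators, control = control,
                        bootstrap = bootstrap, ci_level = ci_level,
                        seed = seed, out_dir = out_dir),
                   class = "run_config")
  if (!is.null(exposure)) {
    if (exposure %in% c(confounders, moderators)) {
      stop("exposure must not appear among confounders or moderators",
           call. = FALSE)
    }
  }
  cfg
}

resolve_columns <- function(cfg, table) {
  sch_cols <- function(role) cohort_columns(table, role)
  cfg$outcome <- cfg$outcome %||% sch_cols("outcome")[1]
  cfg$exposure <- cfg$exposure %||% sch_cols("exposure")[1]
  cfg$confounders <- cfg$confounders %||% sch_cols("confounder")
  cfg$moderators <- cfg$moderators %||% sch_cols("moderator")
  for (cl in c(cfg$outcome, cfg$exposure, cfg$confounders, cfg$moderators)) {
    if (is.na(cl) || !cl %in% names(table)) {
      stop("run config refers to a missing column: ", cl, call. = FALSE)
    }
  }
  if (cfg$exposure %in% c(cfg$confounders, cfg$moderators)) {
    stop("exposure must not appear among confounders or moderators",
         call. = FALSE)
  }
  cfg
}

#' Execute the full analysis pipeline
#'
#' Stages: obtain the cohort (simulate from a generator config, or read a
#' CSV + schema sidecar), complete-case filter, fit the propensity /
#' generalized propensity model, form stabilized weights, balance and
#' positivity diagnostics, grow the model-based tree, per-node effects
#' (with bootstrap risk differences for binary exposures) and split
#' classification. All artifacts are written to `out_dir` together with a
#' manifest (config hash, seed, file content hashes, package and R
#' versions). Reruns with the same config and seed reproduce every output.
#'
#' @param cfg a [run_config()].
#' @return the run report (invisibly): list with `table`, `weights`,
#'   `balance`, `positivity`, `tree`, `effects`, `classification`,
#'   `exclusion`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth_path <- NULL
  tab <- step("input", {
    if (inherits(cfg$input, "generator_config")) {
      t <- generate_cohort(cfg$input, seed = cfg$seed)
      truth_path <- file.path(cfg$out_dir, "truth.json")
      jsonlite::write_json(unclass(attr(t, "truth")), truth_path,
                           auto_unbox = TRUE, digits = NA, null = "null")
      t
    } else {
      read_cohort(cfg$input)
    }
  })
  cfg <- step("input", resolve_columns(cfg, tab))

  filt <- step("complete_cases", complete_case_filter(
    tab, c(cfg$outcome, cfg$exposure, cfg$confounders, cfg$moderators)))
  tab <- filt$table
  jsonlite::write_json(filt$report, file.path(cfg$out_dir, "exclusion.json"),
                       auto_unbox = TRUE, digits = NA)

  binary <- !is.numeric(tab[[cfg$exposure]])
  pfit <- step("propensity", {
    if (binary) fit_propensity_binary(tab, cfg$exposure, cfg$confounders)
    else fit_gps_continuous(tab, cfg$exposure, cfg$confounders)
  })
  ws <- step("weights", stabilized_weights(pfit))
  bal <- step("balance", balance_report(tab, ws, cfg$exposure,
                                        cfg$confounders))
  pos <- step("positivity", positivity_diagnostics(pfit, ws))
  utils::write.csv(bal, file.path(cfg$out_dir, "balance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(pos[c("weight_summary", "flag", "reasons")],
                       file.path(cfg$out_dir, "positivity.json"),
                       auto_unbox = TRUE, digits = NA)
  snap <- as.data.frame(tab)
  snap$.weight <- ws$w
  utils::write.csv(snap, file.path(cfg$out_dir, "cohort.csv"),
                   row.names = FALSE)

  tree <- step("tree", grow_tree(tab, cfg$outcome, cfg$exposure, ws,
                                 cfg$moderators, cfg$control))
  tree_to_json(tree, file.path(cfg$out_dir, "tree.json"))
  utils::write.csv(node_membership(tree),
                   file.path(cfg$out_dir, "node_membership.csv"),
                   row.names = FALSE)

  eff <- step("effects", node_effects(tree, level = cfg$ci_level))
  if (binary && isTRUE(cfg$bootstrap$enabled)) {
    rd <- lapply(seq_len(nrow(eff)), function(i) {
      nd <- tree$nodes[[eff$node[i]]]
      res <- tryCatch(
        bootstrap_rd(tab[[cfg$outcome]][nd$idx], tab[[cfg$exposure]][nd$idx],
                     ws$w[nd$idx], B = cfg$bootstrap$B %||% 2000,
                     seed = str_seed(cfg$seed, paste0("boot:", eff$node[i])),
                     level = cfg$ci_level),
        error = function(e) list(rd = NA_real_, ci = c(NA_real_, NA_real_)))
      c(res$rd, res$ci)
    })
    rd <- do.call(rbind, rd)
    eff$rd <- rd[, 1]; eff$rd_lo <- rd[, 2]; eff$rd_hi <- rd[, 3]
  }
  utils::write.csv(eff, file.path(cfg$out_dir, "effects.csv"),
                   row.names = FALSE)
  cls <- step("classification", classify_splits(tree))
  utils::write.csv(cls, file.path(cfg$out_dir, "classification.csv"),
                   row.names = FALSE)

  files <- list.files(cfg$out_dir, full.names = TRUE)
  manifest <- list(
    seed = cfg$seed,
    exposure = cfg$exposure, outcome = cfg$outcome,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("greenmob")),
    truth_file = if (!is.null(truth_path)) basename(truth_path),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(table = tab, weights = ws, balance = bal, positivity = pos,
                 tree = tree, effects = eff, classification = cls,
                 exclusion = filt$report, manifest = manifest,
                 out_dir = cfg$out_dir))
}
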