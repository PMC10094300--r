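#' Control parameters for model-based recursive partitioning
#'
#' @param alpha significance level of the parameter-instability stopping
#'   rule.
#' @param minsize minimum unweighted number of records per node.
#' @param maxdepth maximum tree depth (root has depth 0; `maxdepth = 3`
#'   allows subgroups defined by up to three consecutive splits).
#' @param bonferroni adjust instability p-values for the number of tested
#'   moderators.
#' @param trim trimming fraction of the supLM statistic.
#' @param nominal_level_cap maximum number of nominal levels for which the
#'   exhaustive binary-partition search is attempted.
#' @return a `mob_control` list.
#' @export
mob_control <- function(alpha = 0.05, minsize = 100, maxdepth = 3,
                        bonferroni = TRUE, trim = 0.1,
                        nominal_level_cap = 10) {
  stopifnot(alpha > 0, alpha < 1, minsize >= 2, maxdepth >= 1,
            trim > 0, trim < 0.5)
  structure(list(alpha = alpha, minsize = minsize, maxdepth = maxdepth,
                 bonferroni = bonferroni, trim = trim,
                 nominal_level_cap = nominal_level_cap),
            class = "mob_control")
}

#' Score-based parameter-instability test for one candidate moderator
#'
#' Tests whether the node model's parameters are stable across the values of
#' a candidate splitting covariate, using the fitted node's per-record score
#' contributions. For a numeric moderator, records are ordered by the
#' moderator, the decorrelated cumulative score process is formed and the
#' supLM statistic (supremum of the normalized squared process over the
#' trimmed interval, evaluated at distinct-value boundaries) is compared with
#' the asymptotic distribution of the trimmed squared Brownian bridge. For a
#' categorical moderator (nominal *or* ordinal), scores are aggregated within
#' levels and the statistic is asymptotically chi-square with
#' `(C - 1) * k` degrees of freedom; this categorical route is exact for the
#' few-level covariates typical of questionnaire data, where the continuous
#' supLM approximation would be conservative.
#'
#' @param fit a converged [fit_weighted_logistic()] result.
#' @param z the candidate moderator, aligned with the fit's records.
#' @param control a [mob_control()].
#' @param name covariate label carried into the result.
#' @return a one-row data frame: `covariate`, `type`, `statistic`, `df`,
#'   `p_value` (`NA` with a warning when the score covariance is singular or
#'   the covariate is constant in the node).
#' @export
instability_test <- function(fit, z, control = mob_control(),
                             name = deparse(substitute(z))) {
  stopifnot(inherits(fit, "node_fit"))
  if (!fit$converged) stop("node fit did not converge", call. = FALSE)
  psi <- fit$scores
  n <- nrow(psi)
  k <- ncol(psi)
  na_row <- function(type) data.frame(covariate = name, type = type,
                                      statistic = NA_real_, df = NA_real_,
                                      p_value = NA_real_)
  if (length(unique(z[!is.na(z)])) < 2) return(na_row("constant"))
  J <- crossprod(psi) / n
  Jinv <- tryCatch(solve(J), error = function(e) NULL)
  if (is.null(Jinv) || !all(is.finite(Jinv))) {
    warning("singular score covariance for covariate ", name,
            "; skipped", call. = FALSE)
    return(na_row("singular"))
  }
  if (is.factor(z) || is.character(z) || is.logical(z)) {
    zf <- droplevels(as.factor(z))
    C <- nlevels(zf)
    S <- rowsum(psi, zf)
    p_c <- as.numeric(table(zf)) / n
    stat <- sum(vapply(seq_len(C), function(c) {
      drop(S[c, ] %*% Jinv %*% S[c, ]) / (n * p_c[c])
    }, 0))
    df <- (C - 1) * k
    data.frame(covariate = name, type = "chisq", statistic = stat,
               df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  } else {
    ord <- order(z)
    zo <- z[ord]
    cs <- apply(psi[ord, , drop = FALSE], 2, cumsum)
    lo <- ceiling(n * control$trim)
    hi <- floor(n * (1 - control$trim))
    cand <- which(zo[-n] != zo[-1])
    cand <- cand[cand >= lo & cand <= hi]
    if (!length(cand)) return(na_row("suplm"))
    tt <- cand / n
    lm_t <- vapply(seq_along(cand), function(j) {
      s <- cs[cand[j], ]
      drop(s %*% Jinv %*% s) / (n * tt[j] * (1 - tt[j]))
    }, 0)
    stat <- max(lm_t)
    data.frame(covariate = name, type = "suplm", statistic = stat,
               df = NA_real_,
               p_value = suplm_pvalue(stat, k, control$trim))
  }
}

#' Choose the splitting covariate from instability results
#'
#' Applies the Bonferroni adjustment (multiplying each raw p-value by the
#' number of testable covariates, capped at 1) and returns the covariate with
#' the smallest adjusted p-value provided it is below `alpha`; otherwise no
#' split. Ties break toward the earlier covariate in the input order.
#'
#' @param results data frame of stacked [instability_test()] rows.
#' @param control a [mob_control()].
#' @return a list: `covariate` (or `NA` for no split) and `results` with an
#'   added `p_adjusted` column.
#' @export
select_split_variable <- function(results, control = mob_control()) {
  stopifnot(nrow(results) >= 1)
  m <- sum(!is.na(results$p_value))
  results$p_adjusted <- if (control$bonferroni) {
    pmin(1, results$p_value * m)
  } else {
    results$p_value
  }
  if (m == 0 || min(results$p_adjusted, na.rm = TRUE) >= control$alpha) {
    return(list(covariate = NA_character_, results = results))
  }
  list(covariate = results$covariate[which.min(results$p_adjusted)],
       results = results)
}

split_goes_left <- function(rule, z) {
  if (rule$type == "nominal") {
    as.character(z) %in% rule$left_levels
  } else if (is.factor(z)) {
    as.integer(z) <= match(rule$threshold, levels(z))
  } else {
    z <= rule$threshold
  }
}

#' Exhaustive search for the best binary split on a selected moderator
#'
#' Ordered moderators (ordinal factors, numeric) are cut at each observed
#' distinct value; nominal moderators are searched over all binary partitions
#' of their observed levels. A candidate is admissible when both children
#' contain at least `minsize` records and both child models converge; among
#' admissible candidates the one maximizing the summed maximized child
#' log-likelihoods wins (equivalently, minimizing the summed negative
#' log-likelihood). Ties break toward the smaller threshold / the partition
#' enumerated first.
#'
#' @param outcome,exposure,weights node data as in
#'   [fit_weighted_logistic()].
#' @param z the selected splitting covariate.
#' @param minsize minimum child size (unweighted records).
#' @param name covariate label stored in the rule.
#' @param nominal_level_cap see [mob_control()].
#' @return `NULL` when no admissible split exists, else a list with `rule`
#'   (`covariate`, `type`, `threshold` or `left_levels`), `objective` (summed
#'   child log-likelihood) and `left` (logical membership vector).
#' @export
search_split <- function(outcome, exposure, weights, z, minsize = 100,
                         name = deparse(substitute(z)),
                         nominal_level_cap = 10) {
  y <- outcome_numeric(outcome)
  e <- exposure_numeric(exposure)
  w <- weights %||% rep(1, length(y))

  child_ll <- function(left) {
    if (sum(left) < minsize || sum(!left) < minsize) return(NULL)
    lf <- tryCatch(fit_weighted_logistic(y[left], e[left], w[left]),
                   error = function(err) NULL)
    rf <- tryCatch(fit_weighted_logistic(y[!left], e[!left], w[!left]),
                   error = function(err) NULL)
    if (is.null(lf) || is.null(rf) || !lf$converged || !rf$converged) {
      return(NULL)
    }
    lf$loglik + rf$loglik
  }

  best <- NULL
  nominal <- (is.factor(z) && !is.ordered(z)) || is.character(z)
  if (nominal) {
    zf <- droplevels(as.factor(z))
    lev <- levels(zf)
    C <- length(lev)
    if (C > nominal_level_cap) {
      stop("nominal covariate ", name, " has ", C,
           " levels, exceeding the exhaustive-search cap", call. = FALSE)
    }
    for (mask in 0:(2^(C - 1) - 2)) {
      left_levels <- c(lev[1], lev[-1][bitwAnd(mask, 2^(0:(C - 2))) > 0])
      left <- as.character(zf) %in% left_levels
      ll <- child_ll(left)
      if (!is.null(ll) && (is.null(best) || ll > best$objective)) {
        best <- list(rule = list(covariate = name, type = "nominal",
                                 left_levels = left_levels),
                     objective = ll, left = left)
      }
    }
  } else {
    vals <- sort(unique(z))
    for (v in utils::head(vals, -1)) {
      left <- if (is.factor(z)) as.integer(z) <= match(v, levels(z)) else z <= v
      ll <- child_ll(left)
      if (!is.null(ll) && (is.null(best) || ll > best$objective)) {
        thr <- if (is.factor(z)) as.character(v) else v
        best <- list(rule = list(covariate = name, type = if (is.factor(z))
                                   "ordered" else "numeric",
                                 threshold = thr),
                     objective = ll, left = left)
      }
    }
  }
  best
}

#' Grow a model-based recursive partition of a weighted logistic model
#'
#' Starting from all records, repeatedly: fit the weighted logistic
#' exposure-outcome model, run the parameter-instability test for every
#' candidate moderator, stop if no Bonferroni-adjusted p-value is below
#' `alpha`, otherwise split on the most unstable moderator at the
#' likelihood-optimal cut, and recurse into both children. Additional
#' stopping rules: children must keep at least `minsize` records, and depth
#' may not exceed `maxdepth`. Deterministic given the input table ordering.
#'
#' @param table a data frame or [cohort_table()], complete cases only.
#' @param outcome,exposure column names; outcome a two-level factor or 0/1,
#'   exposure binary or numeric.
#' @param weights numeric vector, a `weight_set`, or `NULL` for unit weights.
#' @param moderators character vector of candidate moderator columns.
#' @param control a [mob_control()].
#' @return a `mob_tree`: list of nodes (preorder ids) each carrying its
#'   depth, record indices, `node_fit`, instability table and split rule.
#' @examples
#' cfg <- kora_like_config("binary_quality", n = 800)
#' tab <- generate_cohort(cfg, seed = 3)
#' tree <- grow_tree(tab, "srh", "green_quality",
#'                   moderators = c("discrimination_disability",
#'                                  "school_education"),
#'                   control = mob_control(minsize = 50))
#' print(tree)
#' @export
grow_tree <- function(table, outcome, exposure, weights = NULL, moderators,
                      control = mob_control()) {
  stopifnot(length(moderators) >= 1)
  df <- as.data.frame(table)
  y <- df[[outcome]]
  e <- df[[exposure]]
  w <- if (inherits(weights, "weight_set")) weights$w
       else weights %||% rep(1, nrow(df))
  n <- nrow(df)
  nodes <- list()
  next_id <- 1L

  build <- function(idx, depth) {
    id <- next_id
    next_id <<- next_id + 1L
    fit <- tryCatch(fit_weighted_logistic(y[idx], e[idx], w[idx]),
                    error = function(err) {
      if (id == 1L) stop("root fit degenerate: ", conditionMessage(err),
                         call. = FALSE)
      NULL
    })
    node <- list(id = id, depth = depth, idx = idx, fit = fit,
                 instability = NULL, split = NULL, kids = NULL,
                 terminal = TRUE)
    if (is.null(fit) || !fit$converged || depth >= control$maxdepth ||
        length(idx) < 2 * control$minsize) {
      nodes[[id]] <<- node
      return(id)
    }
    res <- do.call(rbind, lapply(moderators, function(mz) {
      suppressWarnings(instability_test(fit, df[[mz]][idx], control,
                                        name = mz))
    }))
    sel <- select_split_variable(res, control)
    node$instability <- sel$results
    if (is.na(sel$covariate)) {
      nodes[[id]] <<- node
      return(id)
    }
    sp <- search_split(y[idx], e[idx], w[idx], df[[sel$covariate]][idx],
                       minsize = control$minsize, name = sel$covariate,
                       nominal_level_cap = control$nominal_level_cap)
    if (is.null(sp)) {
      nodes[[id]] <<- node
      return(id)
    }
    node$split <- sp$rule
    node$terminal <- FALSE
    nodes[[id]] <<- node  # reserve slot before children renumber
    left_id <- build(idx[sp$left], depth + 1L)
    right_id <- build(idx[!sp$left], depth + 1L)
    node$kids <- c(left_id, right_id)
    nodes[[id]] <<- node
    id
  }

  build(seq_len(n), 0L)
  structure(list(nodes = nodes, outcome = outcome, exposure = exposure,
                 moderators = moderators, control = control, n = n,
                 weights = w,
                 exposure_binary = !is.numeric(e)),
            class = "mob_tree")
}

#' @rdname grow_tree
#' @param tree a `mob_tree`.
#' @return `terminal_ids()` returns the ids of terminal nodes.
#' @export
terminal_ids <- function(tree) {
  ids <- vapply(tree$nodes, `[[`, 0L, "id")
  ids[vapply(tree$nodes, `[[`, TRUE, "terminal")]
}

#' @rdname grow_tree
#' @return `node_membership()` returns a data frame mapping each record to
#'   its terminal node id.
#' @export
node_membership <- function(tree) {
  out <- integer(tree$n)
  for (nd in tree$nodes) if (nd$terminal) out[nd$idx] <- nd$id
  data.frame(record = seq_len(tree$n), node = out)
}

rule_label <- function(rule, right = FALSE) {
  if (is.null(rule)) return("")
  if (rule$type == "nominal") {
    lv <- if (right) paste0("not in {", paste(rule$left_levels, collapse = ","), "}")
          else paste0("in {", paste(rule$left_levels, collapse = ","), "}")
    paste(rule$covariate, lv)
  } else {
    paste(rule$covariate, if (right) ">" else "<=", rule$threshold)
  }
}

#' @export
print.mob_tree <- function(x, digits = 3, ...) {
  cat("Model-based recursive partition (weighted logistic: ",
      x$outcome, " ~ ", x$exposure, ")\n", sep = "")
  rec <- function(id, prefix, lab) {
    nd <- x$nodes[[id]]
    est <- if (!is.null(nd$fit)) {
      paste0("b0 = ", round(nd$fit$coef[1], digits),
             ", b1 = ", round(nd$fit$coef[2], digits),
             " (OR = ", round(exp(nd$fit$coef[2]), digits), ")")
    } else "fit failed"
    cat(prefix, "[", nd$id, "] ", lab, if (nzchar(lab)) ": " else "",
        "n = ", length(nd$idx), ", ", est, "\n", sep = "")
    if (!nd$terminal) {
      rec(nd$kids[1], paste0(prefix, "  "), rule_label(nd$split, FALSE))
      rec(nd$kids[2], paste0(prefix, "  "), rule_label(nd$split, TRUE))
    }
  }
  rec(1L, "", "")
  invisible(x)
}

#' Serialize a fitted tree to JSON
#'
#' Nodes are emitted with their ids, split rules, coefficient estimates,
#' robust standard errors and record counts, suitable for archiving a run.
#'
#' @param tree a `mob_tree`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- lapply(tree$nodes, function(nd) {
    fit <- nd$fit
    list(id = nd$id, depth = nd$depth, n = length(nd$idx),
         terminal = nd$terminal,
         coef = if (!is.null(fit)) as.list(fit$coef),
         se_robust = if (!is.null(fit) && !is.null(fit$vcov_sandwich))
           as.list(stats::setNames(sqrt(diag(fit$vcov_sandwich)),
                                   names(fit$coef))),
         loglik = if (!is.null(fit)) fit$loglik,
         split = nd$split, kids = nd$kids)
  })
  obj <- list(outcome = tree$outcome, exposure = tree$exposure,
              n = tree$n, nodes = nodes)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
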