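#' Per-terminal-node effect estimates
#'
#' For every terminal node: the exposure odds ratio `exp(beta1)` with a
#' robust (sandwich) Wald confidence interval, and the weighted prevalence of
#' the good outcome. For continuous exposures the OR and CI are rescaled to
#' an increment of `delta` exposure units (e.g. 0.1 NDVI) via
#' `exp(delta * beta1)`.
#'
#' @param tree a [grow_tree()] result.
#' @param level confidence level (default 0.95).
#' @param delta exposure increment for continuous exposures; `NULL` keeps the
#'   per-unit OR, the default 0.1 matches the conventional NDVI reporting
#'   increment when the tree's exposure is numeric.
#' @return a data frame with one row per terminal node: `node`, `n`,
#'   `prevalence`, `beta0`, `beta1`, `or`, `or_lo`, `or_hi`, `converged`.
#'   Non-converged nodes keep their point estimates but have `NA` intervals.
#' @export
node_effects <- function(tree, level = 0.95,
                         delta = if (tree$exposure_binary) NULL else 0.1) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  d <- delta %||% 1
  rows <- lapply(tree$nodes[terminal_ids(tree)], function(nd) {
    fit <- nd$fit
    w <- tree$weights[nd$idx]
    prev <- if (!is.null(fit)) wmean(fit$y, w) else NA_real_
    if (is.null(fit)) {
      return(data.frame(node = nd$id, n = length(nd$idx), prevalence = prev,
                        beta0 = NA, beta1 = NA, or = NA, or_lo = NA,
                        or_hi = NA, converged = FALSE))
    }
    b1 <- fit$coef[[2]]
    if (fit$converged && !is.null(fit$vcov_sandwich)) {
      se <- sqrt(fit$vcov_sandwich[2, 2])
      lo <- exp(d * (b1 - z * se))
      hi <- exp(d * (b1 + z * se))
    } else {
      lo <- hi <- NA_real_
    }
    data.frame(node = nd$id, n = length(nd$idx), prevalence = prev,
               beta0 = fit$coef[[1]], beta1 = b1, or = exp(d * b1),
               or_lo = lo, or_hi = hi, converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Rescale a log-odds slope to a smaller exposure increment
#'
#' `exp(delta * beta1)` turns a per-unit odds ratio into the odds ratio for a
#' `delta`-unit increase (0.1 by default, the conventional NDVI reporting
#' increment); confidence bounds rescale identically. Monotone in `beta1`.
#'
#' @param beta1 log-odds slope(s) per exposure unit.
#' @param delta exposure increment.
#' @export
rescale_or <- function(beta1, delta = 0.1) exp(delta * beta1)

#' Weighted risk difference with a percentile bootstrap interval
#'
#' The point estimate is the difference of weighted good-outcome proportions
#' between the exposed and unexposed arms of a node,
#' `P[Y=1|E=1] - P[Y=1|E=0]`. The interval is the 2.5/97.5 percentile range
#' over `B` seeded resamples of the node's records (drawn with replacement,
#' weights carried along); resamples that lose an arm are redrawn up to a cap
#' and counted.
#'
#' @param outcome,exposure,weights node data; exposure must be binary with
#'   both arms present.
#' @param B bootstrap replicates (default 2000).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param level confidence level.
#' @param max_redraw redraw attempts per replicate before giving up on it.
#' @return a list: `rd`, `ci` (length 2), `B`, `n_redrawn`, `n_failed`.
#' @export
bootstrap_rd <- function(outcome, exposure, weights = NULL, B = 2000,
                         seed = 1L, level = 0.95, max_redraw = 10L) {
  y <- outcome_numeric(outcome)
  e <- exposure_numeric(exposure)
  w <- weights %||% rep(1, length(y))
  if (!all(c(0, 1) %in% e)) {
    stop("both exposure arms must be present in the node", call. = FALSE)
  }
  rd_of <- function(idx) {
    ei <- e[idx]
    if (!all(c(0, 1) %in% ei)) return(NA_real_)
    wmean(y[idx][ei == 1], w[idx][ei == 1]) -
      wmean(y[idx][ei == 0], w[idx][ei == 0])
  }
  n <- length(y)
  point <- rd_of(seq_len(n))
  n_redrawn <- 0L
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in seq_len(max_redraw)) {
        r <- rd_of(sample.int(n, n, replace = TRUE))
        if (!is.na(r)) return(r)
        n_redrawn <<- n_redrawn + 1L
      }
      NA_real_
    }, 0)
  })
  alpha <- 1 - level
  ci <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  list(rd = point, ci = ci, B = B, n_redrawn = n_redrawn,
       n_failed = sum(is.na(reps)))
}

#' Classify a split as effect heterogeneity or a prevalence difference
#'
#' Sibling subgroups produced by a split can differ in the exposure slope
#' (genuine effect heterogeneity of the odds ratio), only in the intercept
#' (different prevalence of the good outcome, same exposure effect), in
#' both, or in neither. The formal classification uses per-parameter Wald
#' contrasts `(beta_a - beta_b) / sqrt(se_a^2 + se_b^2)` with robust
#' standard errors; the informal confidence-interval-overlap reading used in
#' applied reports is returned alongside.
#'
#' @param fit_a,fit_b the two sibling `node_fit`s.
#' @param level significance level of the contrasts (default 0.05).
#' @param ci_level level of the informal CI-overlap comparison.
#' @return a `split_classification` list: `label` (one of
#'   `"slope heterogeneity"`, `"prevalence difference"`, `"both"`,
#'   `"neither"`), `z` (per-parameter contrast statistics), `p` and
#'   `or_ci_overlap`.
#' @export
classify_split <- function(fit_a, fit_b, level = 0.05, ci_level = 0.95) {
  for (f in list(fit_a, fit_b)) {
    if (is.null(f$vcov_sandwich)) {
      return(structure(list(label = "unclassified", z = c(NA, NA),
                            p = c(NA, NA), or_ci_overlap = NA),
                       class = "split_classification"))
    }
  }
  se_a <- sqrt(diag(fit_a$vcov_sandwich))
  se_b <- sqrt(diag(fit_b$vcov_sandwich))
  z <- (fit_a$coef - fit_b$coef) / sqrt(se_a^2 + se_b^2)
  p <- 2 * stats::pnorm(-abs(z))
  slope <- p[2] < level
  intercept <- p[1] < level
  label <- if (slope && intercept) "both"
           else if (slope) "slope heterogeneity"
           else if (intercept) "prevalence difference"
           else "neither"
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci_a <- fit_a$coef[2] + c(-1, 1) * zq * se_a[2]
  ci_b <- fit_b$coef[2] + c(-1, 1) * zq * se_b[2]
  overlap <- ci_a[1] <= ci_b[2] && ci_b[1] <= ci_a[2]
  structure(list(label = label, z = stats::setNames(z, c("beta0", "beta1")),
                 p = stats::setNames(p, c("beta0", "beta1")),
                 or_ci_overlap = overlap),
            class = "split_classification")
}

#' @export
print.split_classification <- function(x, ...) {
  cat("split classification:", x$label, "\n")
  cat("contrast z: beta0 =", round(x$z[1], 3),
      ", beta1 =", round(x$z[2], 3), "\n")
  cat("slope CI overlap:", x$or_ci_overlap, "\n")
  invisible(x)
}

#' Classify every split of a fitted tree
#'
#' Applies [classify_split()] to the two children of each internal node.
#'
#' @param tree a `mob_tree`.
#' @param level contrast significance level.
#' @return a data frame: `node`, `covariate`, `label`, `z_beta0`, `z_beta1`.
#' @export
classify_splits <- function(tree, level = 0.05) {
  rows <- list()
  for (nd in tree$nodes) {
    if (nd$terminal) next
    cl <- classify_split(tree$nodes[[nd$kids[1]]]$fit,
                         tree$nodes[[nd$kids[2]]]$fit, level = level)
    rows[[length(rows) + 1L]] <-
      data.frame(node = nd$id, covariate = nd$split$covariate,
                 label = cl$label, z_beta0 = cl$z[1], z_beta1 = cl$z[2],
                 row.names = NULL)
  }
  if (!length(rows)) {
    return(data.frame(node = integer(), covariate = character(),
                      label = character(), z_beta0 = numeric(),
                      z_beta1 = numeric()))
  }
  do.call(rbind, rows)
}
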