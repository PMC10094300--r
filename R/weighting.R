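# exposure columns can be factors (binary) or numeric (continuous); all
# weighting code works on the numeric coding below.
exposure_numeric <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.factor(x) && nlevels(x) == 2) return(as.integer(x) - 1L)
  if (is.logical(x)) return(as.integer(x))
  stop("exposure must be numeric or a two-level factor", call. = FALSE)
}

#' Fit a propensity-score model for a binary exposure
#'
#' Maximum-likelihood logistic regression of the exposure on the confounders;
#' the fitted conditional probabilities of the *observed* exposure status and
#' the marginal probabilities of that status (from the raw sample) are
#' attached per record, ready for [stabilized_weights()].
#'
#' @param table a data frame or [cohort_table()], complete in the columns
#'   used.
#' @param exposure name of the binary exposure column (second factor level =
#'   exposed).
#' @param confounders character vector of confounder column names.
#' @return a `propensity_fit` with elements `type = "binary"`, `p_exposed`
#'   (fitted P(E=1|X)), `cond` (probability of the observed status given X),
#'   `marg` (marginal probability of the observed status), `coef`, `model`.
#' @export
fit_propensity_binary <- function(table, exposure, confounders) {
  e <- exposure_numeric(table[[exposure]])
  if (anyNA(e)) stop("exposure contains missing values", call. = FALSE)
  f <- stats::as.formula(paste("..e ~", paste(confounders, collapse = " + ")))
  df <- as.data.frame(table)[, confounders, drop = FALSE]
  df$..e <- e
  fit <- suppressWarnings(stats::glm(f, data = df, family = stats::binomial()))
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (any(p < eps | p > 1 - eps) || any(abs(stats::coef(fit)) > 15)) {
    stop("perfect or quasi-perfect separation in the propensity model; ",
         "review the confounder set (positivity violation)", call. = FALSE)
  }
  p_marg <- mean(e)
  structure(list(type = "binary",
                 p_exposed = p,
                 cond = ifelse(e == 1, p, 1 - p),
                 marg = ifelse(e == 1, p_marg, 1 - p_marg),
                 exposure = e,
                 coef = stats::coef(fit),
                 model = fit),
            class = "propensity_fit")
}

#' Fit a generalized propensity score for a continuous exposure
#'
#' The conditional density of the exposure given the confounders is modelled
#' as a homoscedastic linear regression whose residual density is estimated
#' by Gaussian kernel density estimation (Silverman's rule bandwidth) and
#' evaluated at each record's own residual; the marginal density is a kernel
#' density estimate of the exposure itself, evaluated at each record's
#' exposure value.
#'
#' @inheritParams fit_propensity_binary
#' @param bw_cond,bw_marg optional kernel bandwidth overrides.
#' @return a `propensity_fit` with `type = "continuous"`, per-record `cond`
#'   and `marg` densities, coefficients and bandwidths.
#' @export
fit_gps_continuous <- function(table, exposure, confounders,
                               bw_cond = NULL, bw_marg = NULL) {
  e <- table[[exposure]]
  if (!is.numeric(e)) stop("continuous exposure must be numeric", call. = FALSE)
  if (stats::sd(e) == 0) stop("degenerate exposure: zero variance", call. = FALSE)
  f <- stats::as.formula(paste("..e ~", paste(confounders, collapse = " + ")))
  df <- as.data.frame(table)[, confounders, drop = FALSE]
  df$..e <- e
  fit <- stats::lm(f, data = df)
  r <- stats::residuals(fit)
  if (stats::sd(r) < 1e-12) stop("zero residual variance in the exposure model",
                                 call. = FALSE)
  bw_cond <- bw_cond %||% stats::bw.nrd0(r)
  bw_marg <- bw_marg %||% stats::bw.nrd0(e)
  cond <- gaussian_kde_at(r, r, bw_cond)
  marg <- gaussian_kde_at(e, e, bw_marg)
  if (any(cond <= 0) || any(marg <= 0)) {
    stop("non-positive density estimate", call. = FALSE)
  }
  structure(list(type = "continuous", cond = cond, marg = marg,
                 exposure = e, coef = stats::coef(fit), model = fit,
                 bw = c(cond = bw_cond, marg = bw_marg)),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("propensity_fit (", x$type, " exposure), n = ", length(x$cond),
      "\n", sep = "")
  cat("conditional ", if (x$type == "binary") "probability" else "density",
      " range: [", format(min(x$cond), digits = 4), ", ",
      format(max(x$cond), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Stabilized inverse-probability weights
#'
#' For each record the weight is the marginal probability (binary exposure)
#' or marginal density (continuous exposure) of its observed exposure divided
#' by the conditional one given the confounders. Under a correctly specified
#' model the weights have mean near 1; a mean far from 1 or extreme values
#' indicate positivity problems.
#'
#' @param fit a `propensity_fit`.
#' @return a `weight_set`: `w` (per-record weights), `summary`
#'   (mean/min/max).
#' @export
stabilized_weights <- function(fit) {
  stopifnot(inherits(fit, "propensity_fit"))
  w <- fit$marg / fit$cond
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad)) {
    stop("non-finite or non-positive stabilized weights for records: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  structure(list(w = w,
                 summary = c(mean = mean(w), min = min(w), max = max(w))),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("stabilized weights, n =", length(x$w), "\n")
  print(round(x$summary, 4))
  invisible(x)
}

# expand confounders to numeric columns: continuous stay as-is, categorical
# become one indicator per level (reference included)
expand_confounders <- function(table, confounders) {
  out <- list()
  for (nm in confounders) {
    x <- table[[nm]]
    if (is.numeric(x)) {
      out[[nm]] <- x
    } else {
      x <- as.factor(x)
      for (lv in levels(x)) {
        out[[paste0(nm, ":", lv)]] <- as.numeric(x == lv)
      }
    }
  }
  out
}

#' Covariate balance before and after weighting
#'
#' For a binary exposure, the absolute standardized mean difference (SMD) of
#' each confounder between exposed and unexposed, before and after applying
#' the weights; the denominator is the unweighted pooled standard deviation
#' in both cases so the two columns share a scale. For a continuous exposure,
#' the absolute (weighted) Pearson exposure-covariate correlation.
#' Categorical confounders are expanded to one indicator per level, reference
#' level included. Statistics below 0.1 are flagged as balanced.
#'
#' @param table a data frame or [cohort_table()].
#' @param weights a `weight_set` or numeric vector of positive weights.
#' @param exposure exposure column name.
#' @param confounders confounder column names.
#' @param threshold balance threshold (default 0.1).
#' @return a `balance_report` data frame with columns `covariate`, `before`,
#'   `after`, `balanced_before`, `balanced_after`, `zero_variance`.
#' @export
balance_report <- function(table, weights, exposure, confounders,
                           threshold = 0.1) {
  w <- if (inherits(weights, "weight_set")) weights$w else weights
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  e <- table[[exposure]]
  binary <- !is.numeric(e)
  e_num <- exposure_numeric(e)
  cols <- expand_confounders(as.data.frame(table), confounders)
  res <- lapply(names(cols), function(nm) {
    x <- cols[[nm]]
    zv <- stats::sd(x) == 0
    if (zv) {
      warning("zero-variance covariate: ", nm, call. = FALSE)
      before <- after <- 0
    } else if (binary) {
      s_pool <- sqrt((stats::var(x[e_num == 1]) + stats::var(x[e_num == 0])) / 2)
      if (!is.finite(s_pool) || s_pool == 0) s_pool <- stats::sd(x)
      before <- abs(mean(x[e_num == 1]) - mean(x[e_num == 0])) / s_pool
      after <- abs(wmean(x[e_num == 1], w[e_num == 1]) -
                     wmean(x[e_num == 0], w[e_num == 0])) / s_pool
    } else {
      before <- abs(stats::cor(e_num, x))
      after <- abs(wcor(e_num, x, w))
    }
    data.frame(covariate = nm, before = before, after = after,
               zero_variance = zv)
  })
  out <- do.call(rbind, res)
  out$balanced_before <- out$before < threshold
  out$balanced_after <- out$after < threshold
  class(out) <- c("balance_report", "data.frame")
  out
}

#' Positivity and weight diagnostics
#'
#' Summarizes the stabilized weights (mean, min, max) and, for binary
#' exposures, the overlap of fitted propensity scores across exposure
#' groups. A flag is raised when the weight mean deviates from 1 by more
#' than `mean_tol` or the maximum weight exceeds `max_cap`.
#'
#' @param fit a `propensity_fit`.
#' @param weights a `weight_set` or numeric weights.
#' @param mean_tol tolerated deviation of the weight mean from 1.
#' @param max_cap tolerated maximum weight.
#' @return a list: `weight_summary`, `overlap` (binary exposures only),
#'   `flag` and the reasons behind it.
#' @export
positivity_diagnostics <- function(fit, weights, mean_tol = 0.1,
                                   max_cap = 10) {
  w <- if (inherits(weights, "weight_set")) weights$w else weights
  ws <- c(mean = mean(w), min = min(w), max = max(w))
  overlap <- NULL
  if (identical(fit$type, "binary")) {
    p <- fit$p_exposed
    e <- fit$exposure
    overlap <- data.frame(
      group = c("exposed", "unexposed"),
      p_min = c(min(p[e == 1]), min(p[e == 0])),
      p_max = c(max(p[e == 1]), max(p[e == 0]))
    )
  }
  reasons <- character(0)
  if (abs(ws[["mean"]] - 1) > mean_tol) {
    reasons <- c(reasons, sprintf("weight mean %.3f deviates from 1",
                                  ws[["mean"]]))
  }
  if (ws[["max"]] > max_cap) {
    reasons <- c(reasons, sprintf("maximum weight %.2f exceeds cap %.2f",
                                  ws[["max"]], max_cap))
  }
  list(weight_summary = ws, overlap = overlap,
       flag = length(reasons) > 0, reasons = reasons)
}
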