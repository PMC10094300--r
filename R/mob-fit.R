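# Weighted Bernoulli log-likelihood, score contributions and covariances for
# the two-parameter node model  logit P(Y=1) = beta0 + beta1 * E.
# Weights are frequency-style: they multiply each record's log-likelihood
# contribution, hence also its score; n stays the unweighted record count.

weighted_logistic <- function(X, y, w, coef_names = colnames(X)) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = stats::binomial())
  )
  p <- fit$fitted.values
  eps <- 1e-10
  separated <- any(p < eps | p > 1 - eps) || any(abs(fit$coefficients) > 15)
  converged <- isTRUE(fit$converged) && !separated &&
    all(is.finite(fit$coefficients))
  beta <- fit$coefficients
  names(beta) <- coef_names
  ll <- sum(w * (y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps))))
  scores <- X * (w * (y - p))
  info <- crossprod(X, X * (w * p * (1 - p)))
  vcov_model <- tryCatch(solve(info), error = function(e) NULL)
  vcov_sandwich <- if (!is.null(vcov_model)) {
    vcov_model %*% crossprod(scores) %*% vcov_model
  }
  structure(list(coef = beta, loglik = ll, fitted = p, scores = scores,
                 vcov_model = vcov_model, vcov_sandwich = vcov_sandwich,
                 n = length(y), sumw = sum(w), y = y, X = X, w = w,
                 converged = converged, separated = separated),
            class = "node_fit")
}

#' Weighted binary logistic exposure-outcome fit for one node
#'
#' Fits `logit P(Y = 1) = beta0 + beta1 * E` by iteratively reweighted least
#' squares, maximizing the weighted Bernoulli log-likelihood
#' `sum(w_i * (y_i log p_i + (1 - y_i) log(1 - p_i)))`. Per-record score
#' contributions, the model-based covariance (inverse weighted Fisher
#' information) and the HC0 sandwich covariance are returned; the sandwich
#' form is the basis of all downstream robust confidence intervals, since the
#' weighting invalidates the model-based standard errors.
#'
#' @param outcome binary outcome: 0/1 numeric, logical, or a two-level factor
#'   whose second level is the positive class.
#' @param exposure numeric exposure or two-level factor (second level =
#'   exposed).
#' @param weights positive weights (defaults to unit weights).
#' @param hc `"HC0"` (default) or `"HC1"` small-sample scaling of the
#'   sandwich covariance.
#' @return a `node_fit` with elements `coef`, `loglik`, `scores`,
#'   `vcov_model`, `vcov_sandwich`, `n`, `sumw`, `converged`.
#' @examples
#' # a saturated fit on a 2x2 table reproduces the cross-product ratio
#' y <- rep(c(1, 0, 1, 0), c(641, 133, 1285, 475))
#' e <- rep(c(1, 1, 0, 0), c(641, 133, 1285, 475))
#' exp(coef(fit_weighted_logistic(y, e))[2])
#' @export
fit_weighted_logistic <- function(outcome, exposure, weights = NULL,
                                  hc = c("HC0", "HC1")) {
  hc <- match.arg(hc)
  y <- outcome_numeric(outcome)
  e <- exposure_numeric(exposure)
  w <- weights %||% rep(1, length(y))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("degenerate node fit: only one outcome class present",
         call. = FALSE)
  }
  if (length(unique(e)) < 2) {
    stop("degenerate node fit: exposure is constant, slope undefined",
         call. = FALSE)
  }
  fit <- weighted_logistic(cbind("(Intercept)" = 1, exposure = e), y, w)
  if (hc == "HC1" && !is.null(fit$vcov_sandwich)) {
    k <- length(fit$coef)
    fit$vcov_sandwich <- fit$vcov_sandwich * fit$n / (fit$n - k)
  }
  fit
}

outcome_numeric <- function(y) {
  if (is.numeric(y)) {
    if (!is_binary01(y)) stop("numeric outcome must be 0/1", call. = FALSE)
    return(y)
  }
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y) && nlevels(y) == 2) return(as.integer(y) - 1L)
  stop("outcome must be 0/1 or a two-level factor", call. = FALSE)
}

#' @export
print.node_fit <- function(x, ...) {
  cat("weighted logistic node fit: n =", x$n,
      " sum(w) =", format(x$sumw, digits = 5),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  se_r <- sqrt(diag(x$vcov_sandwich))
  tab <- cbind(estimate = x$coef,
               se_model = sqrt(diag(x$vcov_model)),
               se_robust = se_r)
  print(round(tab, 4))
  cat("log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.node_fit <- function(object, ...) object$coef

#' @export
vcov.node_fit <- function(object, type = c("sandwich", "model"), ...) {
  type <- match.arg(type)
  if (type == "sandwich") object$vcov_sandwich else object$vcov_model
}

#' @export
logLik.node_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}
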