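# shared fixtures built in code

kora_confounders <- c("age", "home_owner", "urbanisation",
                      "financial_situation")

# Table-3-style 2x2 node data expanded to records:
# (exposed good, exposed bad, unexposed good, unexposed bad)
expand_2x2 <- function(a, b, c, d) {
  list(
    y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
    e = rep(c(1, 1, 0, 0), c(a, b, c, d))
  )
}

# tiny two-covariate generator config for fast unit tests
mini_config <- function(n = 500, beta1 = c(0, log(2)), conf_strength = 0.8,
                        outcome_strength = 0.6) {
  covs <- list(
    covariate_spec("x1", "binary", levels = c("no", "yes"),
                   probs = c(0.5, 0.5),
                   confounder_strength = conf_strength,
                   outcome_strength = outcome_strength),
    covariate_spec("m1", "binary", levels = c("no", "yes"),
                   probs = c(0.5, 0.5))
  )
  truth <- planted_truth(list(
    truth_subgroup("a", list(list(covariate = "m1", op = "in", value = "no")),
                   beta0 = 0.5, beta1 = beta1[1]),
    truth_subgroup("b", list(list(covariate = "m1", op = "in", value = "yes")),
                   beta0 = 0.5, beta1 = beta1[2])
  ))
  generator_config(n = n, covariates = covs, exposure_kind = "binary",
                   exposure_model = list(name = "e", intercept = -0.5,
                                         levels = c("ctrl", "exp")),
                   truth = truth)
}

# weighted logistic fit via stats::glm, used as an independent cross-check
glm_logistic_oracle <- function(y, e, w = NULL) {
  df <- data.frame(y = y, e = e)
  if (is.null(w)) w <- rep(1, length(y))
  suppressWarnings(stats::glm(y ~ e, family = stats::binomial(),
                              data = df, weights = w))
}
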