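# instability testing and split-variable selection

null_fit <- function(n = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(0.8 + 0.3 * e))
  fit_weighted_logistic(y, e)
}

test_that("supLM rejection rate under the null stays near the nominal level", {
  set.seed(301)
  reps <- 200
  rej <- vapply(seq_len(reps), function(i) {
    fit <- null_fit(2000)
    instability_test(fit, rnorm(2000), name = "z")$p_value < 0.05
  }, TRUE)
  band <- 2.576 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), band)
})

test_that("categorical instability test is calibrated under the null", {
  set.seed(302)
  reps <- 200
  rej <- vapply(seq_len(reps), function(i) {
    fit <- null_fit(2000)
    z <- factor(sample(letters[1:4], 2000, TRUE))
    instability_test(fit, z, name = "z")$p_value < 0.05
  }, TRUE)
  band <- 2.576 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), band)
})

test_that("a slope sign flip across a moderator is detected overwhelmingly", {
  set.seed(303)
  n <- 2000
  z <- rnorm(n)
  e <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(0.2 + ifelse(z > median(z), 0.9, -0.9) * e))
  fit <- fit_weighted_logistic(y, e)
  res <- instability_test(fit, z, name = "z")
  expect_lt(res$p_value, 1e-4)
  # ordinal version through the categorical route
  zf <- cut(z, quantile(z, 0:5 / 5), include.lowest = TRUE,
            ordered_result = TRUE)
  res2 <- instability_test(fit, zf, name = "zf")
  expect_identical(res2$type, "chisq")
  expect_lt(res2$p_value, 1e-4)
})

test_that("constant and degenerate covariates are skipped", {
  fit <- null_fit(500, seed = 304)
  res <- instability_test(fit, rep(1, 500), name = "const")
  expect_true(is.na(res$p_value))
  expect_identical(res$type, "constant")
})

test_that("supLM p-values interpolate the tabulated null distribution", {
  # tabulated 95% point for two parameters should give p close to 0.05
  q95 <- greenmob:::.supLM_quantiles[match(0.95, greenmob:::.supLM_probs), "k2"]
  expect_equal(greenmob:::suplm_pvalue(q95, 2), 0.05, tolerance = 1e-6)
  expect_equal(greenmob:::suplm_pvalue(0.1, 2), 1)
  expect_lt(greenmob:::suplm_pvalue(60, 2), 1e-6)
  # monotone decreasing in the statistic
  ps <- vapply(seq(2, 30, 0.5), greenmob:::suplm_pvalue, 0, k = 2)
  expect_true(all(diff(ps) <= 0))
  # Monte-Carlo fallback for a non-tabulated trimming fraction
  p_mc <- greenmob:::suplm_pvalue(q95, 2, trim = 0.15)
  expect_gt(p_mc, 0.02)
  expect_lt(p_mc, 0.12)
})

test_that("split-variable selection applies Bonferroni and honours alpha", {
  res <- data.frame(covariate = c("a", "b", "c"),
                    type = "chisq", statistic = 1, df = 1,
                    p_value = c(0.2, 0.001, 0.04))
  pick <- select_split_variable(res, mob_control(bonferroni = FALSE))
  expect_equal(pick$covariate, "b")
  # Bonferroni with 40 candidates pushes raw p = 0.01 to 0.4 -> no split
  res40 <- data.frame(covariate = paste0("m", 1:40), type = "chisq",
                      statistic = 1, df = 1,
                      p_value = c(0.01, runif(39, 0.3, 1)))
  pick40 <- select_split_variable(res40, mob_control())
  expect_true(is.na(pick40$covariate))
  expect_equal(pick40$results$p_adjusted[1], 0.4)
  # all adjusted p >= alpha -> none
  resna <- data.frame(covariate = "a", type = "chisq", statistic = 1,
                      df = 1, p_value = 0.06)
  expect_true(is.na(select_split_variable(resna, mob_control())$covariate))
})
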