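test_that("propensity model reduces to the marginal rate under independence", {
  set.seed(101)
  n <- 5000
  df <- data.frame(x = factor(sample(c("a", "b"), n, TRUE)),
                   e = factor(sample(c("u", "t"), n, TRUE, prob = c(0.7, 0.3)),
                              levels = c("u", "t")))
  fit <- fit_propensity_binary(df, "e", "x")
  expect_lt(diff(range(fit$p_exposed)), 0.05)
  expect_lt(abs(mean(fit$p_exposed) - mean(df$e == "t")), 1e-10)
})

test_that("deterministic exposure-confounder relation raises a separation error", {
  df <- data.frame(x = factor(rep(c("a", "b"), each = 50)),
                   e = factor(rep(c("u", "t"), each = 50), levels = c("u", "t")))
  expect_error(fit_propensity_binary(df, "e", "x"), "separation")
})

test_that("assignment-model coefficients are recovered on synthetic cohorts", {
  cfg <- kora_like_config("binary_quality", n = 20000)
  tab <- generate_cohort(cfg, seed = 41)
  fit <- fit_propensity_binary(tab, "green_quality", kora_confounders)
  # age enters the generator at -0.25 per 9-year SD -> -0.25/9 per year
  sm <- summary(fit$model)$coefficients
  expect_lt(abs(sm["age", "Estimate"] - (-0.25 / 9)),
            3 * sm["age", "Std. Error"])
  expect_lt(abs(sm["home_ownerown", "Estimate"] - 0.5),
            3 * sm["home_ownerown", "Std. Error"])
})

test_that("generalized propensity densities match the closed-form Gaussian", {
  set.seed(102)
  n <- 20000
  x <- rnorm(n)
  df <- data.frame(x = x, e = 0.4 + 0.2 * x + rnorm(n, 0, 0.1))
  fit <- fit_gps_continuous(df, "e", "x")
  truth <- dnorm(residuals(lm(e ~ x, df)), 0, 0.1)
  expect_lt(median(abs(fit$cond - truth) / truth), 0.05)
})

test_that("GPS weights are near 1 when exposure is independent of confounders", {
  set.seed(103)
  n <- 4000
  df <- data.frame(x = rnorm(n), e = rnorm(n, 0.5, 0.1))
  fit <- fit_gps_continuous(df, "e", "x")
  w <- stabilized_weights(fit)$w
  expect_lt(abs(mean(w) - 1), 0.05)
  expect_lt(stats::quantile(abs(w - 1), 0.9), 0.2)
  expect_error(fit_gps_continuous(data.frame(x = rnorm(5), e = rep(1, 5)),
                                  "e", "x"), "zero variance|degenerate")
})

test_that("stabilized weights follow marginal/conditional arithmetic", {
  fit <- structure(list(type = "binary", cond = c(0.6, 0.5),
                        marg = c(0.3, 0.5), exposure = c(1, 1)),
                   class = "propensity_fit")
  ws <- stabilized_weights(fit)
  expect_equal(ws$w, c(0.5, 1))
  fit$cond <- c(0.3, 0.5)  # conditional equals marginal everywhere
  expect_equal(stabilized_weights(fit)$w, c(1, 1))
  fit$cond <- c(0, 0.5)
  expect_error(stabilized_weights(fit), "records")
})

test_that("stabilized-weight mean sits near 1 on the study-scale cohort", {
  tab <- generate_cohort(kora_like_config("binary_quality", n = 2534),
                         seed = 42)
  ws <- stabilized_weights(
    fit_propensity_binary(tab, "green_quality", kora_confounders))
  expect_lt(abs(ws$summary[["mean"]] - 1), 0.05)
  diag <- positivity_diagnostics(
    fit_propensity_binary(tab, "green_quality", kora_confounders), ws)
  expect_false(diag$flag)
})

test_that("balance report: unit weights leave 'after' equal to 'before'", {
  tab <- generate_cohort(kora_like_config("binary_quality", n = 800),
                         seed = 43)
  bal <- balance_report(tab, rep(1, nrow(tab)), "green_quality",
                        kora_confounders)
  expect_equal(bal$after, bal$before)
  # one indicator row per level, reference included
  expect_true(all(c("urbanisation:city", "urbanisation:suburb",
                    "urbanisation:rural") %in% bal$covariate))
})

test_that("weighting balances truly confounded covariates below 0.1", {
  tab <- generate_cohort(kora_like_config("binary_quality", n = 10000),
                         seed = 44)
  ws <- stabilized_weights(
    fit_propensity_binary(tab, "green_quality", kora_confounders))
  bal <- balance_report(tab, ws, "green_quality", kora_confounders)
  expect_true(all(bal$after < 0.1))
  expect_true(all(bal$after < bal$before))
})

test_that("independent covariates show near-zero SMD before weighting", {
  set.seed(104)
  n <- 20000
  df <- data.frame(x = rnorm(n),
                   e = factor(sample(c("u", "t"), n, TRUE),
                              levels = c("u", "t")))
  bal <- balance_report(df, rep(1, n), "e", "x")
  expect_lt(bal$before, 0.05)
})

test_that("zero-variance covariates are flagged, not fatal", {
  df <- data.frame(x = rep(1, 100),
                   e = factor(rep(c("u", "t"), 50), levels = c("u", "t")))
  expect_warning(bal <- balance_report(df, rep(1, 100), "e", "x"),
                 "zero-variance")
  expect_equal(bal$before, 0)
  expect_true(bal$zero_variance)
})

test_that("continuous-exposure balance uses weighted correlations", {
  tab <- generate_cohort(kora_like_config("continuous", n = 5000), seed = 45)
  ws <- stabilized_weights(
    fit_gps_continuous(tab, "ndvi_300m", kora_confounders))
  bal <- balance_report(tab, ws, "ndvi_300m", kora_confounders)
  expect_true(all(bal$after < 0.1))
  expect_gt(max(bal$before), 0.1)  # the generator does confound
})

test_that("positivity diagnostics flag extreme weights and off-centre means", {
  fit <- structure(list(type = "binary", p_exposed = runif(10, 0.3, 0.6),
                        exposure = rep(c(0, 1), 5)),
                   class = "propensity_fit")
  ok <- positivity_diagnostics(fit, rep(1, 10))
  expect_false(ok$flag)
  expect_equal(ok$weight_summary[["mean"]], 1)
  bad <- positivity_diagnostics(fit, c(rep(1, 9), 50), max_cap = 20)
  expect_true(bad$flag)
  expect_match(paste(bad$reasons, collapse = " "), "maximum weight")
})
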