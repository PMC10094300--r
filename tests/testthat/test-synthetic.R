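test_that("generation is deterministic given (config, seed)", {
  cfg <- mini_config(n = 300)
  t1 <- generate_cohort(cfg, seed = 5)
  t2 <- generate_cohort(cfg, seed = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(t1$srh, t3$srh))
})

test_that("per-column RNG streams are stable when a covariate is added", {
  cfg <- mini_config(n = 400)
  cfg2 <- cfg
  cfg2$covariates <- c(cfg2$covariates,
                       list(covariate_spec("extra", "binary")))
  t1 <- generate_cohort(cfg, seed = 9)
  t2 <- generate_cohort(cfg2, seed = 9)
  expect_identical(t1$x1, t2$x1)
  expect_identical(t1$m1, t2$m1)
  expect_identical(t1$e, t2$e)
})

test_that("null configuration yields empirical OR near 1 at large n", {
  cfg <- mini_config(n = 40000, beta1 = c(0, 0), conf_strength = 0,
                     outcome_strength = 0)
  tab <- generate_cohort(cfg, seed = 2)
  ct <- table(tab$e, tab$srh)
  or <- (ct[2, 2] * ct[1, 1]) / (ct[2, 1] * ct[1, 2])
  expect_lt(abs(log(or)), 3 * sqrt(sum(1 / ct)))
})

test_that("planted subgroup reproduces its odds ratio at large n", {
  cfg <- mini_config(n = 60000, beta1 = c(0, log(2.66)), conf_strength = 0,
                     outcome_strength = 0)
  tab <- generate_cohort(cfg, seed = 3)
  sub <- tab[tab$true_subgroup == "b", ]
  fit <- fit_weighted_logistic(sub$srh, sub$e)
  se <- sqrt(fit$vcov_model[2, 2])
  expect_lt(abs(fit$coef[2] - log(2.66)), 3 * se)
})

test_that("study-scale config hits the printed marginals within 2 SE", {
  cfg <- kora_like_config("binary_quality", n = 2534)
  tab <- generate_cohort(cfg, seed = 17)
  p_exp <- mean(tab$green_quality == "high_quality")
  expect_lt(abs(p_exp - 774 / 2534),
            2 * sqrt(0.305 * 0.695 / 2534) + 0.005)
  p_good <- mean(tab$srh == "good")
  expect_lt(abs(p_good - 1926 / 2534),
            2 * sqrt(0.76 * 0.24 / 2534) + 0.005)
  expect_equal(nrow(tab), 2534)
})

test_that("greenness and continuous variants match their targets", {
  tabg <- generate_cohort(kora_like_config("binary_greenness", n = 2534),
                          seed = 18)
  expect_lt(abs(mean(tabg$green_neighbourhood == "very_green") - 2008 / 2534),
            2 * sqrt(0.792 * 0.208 / 2534) + 0.005)
  tabc <- generate_cohort(kora_like_config("continuous", n = 2534), seed = 18)
  expect_lt(abs(mean(tabc$ndvi_300m) - 0.47), 0.01)
  expect_lt(abs(stats::sd(tabc$ndvi_300m) - 0.09), 0.01)
  expect_gte(min(tabc$ndvi_300m), 0.16)
  expect_lte(max(tabc$ndvi_300m), 0.73)
})

test_that("every record belongs to exactly one planted subgroup", {
  cfg <- kora_like_config("binary_quality", n = 1000)
  tab <- generate_cohort(cfg, seed = 4)
  expect_false(anyNA(tab$true_subgroup))
  expect_equal(sum(table(tab$true_subgroup)), 1000)
  # a non-exhaustive truth is rejected
  bad <- mini_config(n = 50)
  bad$truth$subgroups <- bad$truth$subgroups[1]
  expect_error(generate_cohort(bad, seed = 1), "not a partition")
})

test_that("config validation errors name the offending field", {
  cfg <- mini_config()
  cfg$n <- -1
  expect_error(generate_cohort(cfg), "'n'")
  cfg <- mini_config()
  cfg$exposure_kind <- "ternary"
  expect_error(generate_cohort(cfg), "exposure_kind")
  expect_error(covariate_spec("p", "ordinal", levels = "one"), "levels")
  expect_error(covariate_spec("p", "nominal", levels = c("a", "b"),
                              probs = c(0.6, 0.6)), "sum to 1")
  expect_error(
    planted_truth(list(truth_subgroup("g", rep(list(
      list(covariate = "x", op = "in", value = "a")), 4), 0, 0))),
    "depth")
})

strip_meta <- function(t) {
  attr(t, "truth") <- NULL
  attr(t, "schema") <- NULL
  as.data.frame(t)
}

test_that("configs round-trip through JSON and YAML unchanged", {
  cfg <- kora_like_config("binary_quality", n = 100)
  for (ext in c("json", "yaml")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_generator_config(cfg, p)
    back <- read_generator_config(p)
    expect_equal(vapply(back$truth$subgroups, `[[`, 0, "beta1"),
                 vapply(cfg$truth$subgroups, `[[`, 0, "beta1"),
                 tolerance = 1e-12)
    t1 <- generate_cohort(cfg, seed = 12)
    t2 <- generate_cohort(back, seed = 12)
    expect_equal(strip_meta(t1), strip_meta(t2), tolerance = 1e-12)
  }
})

test_that("missingness injection honours its rates", {
  cfg <- mini_config(n = 10000)
  tab <- generate_cohort(cfg, seed = 8)
  expect_identical(inject_missing(tab, c(x1 = 0), seed = 1)$x1, tab$x1)
  allgone <- inject_missing(tab, c(x1 = 1), seed = 1)
  expect_true(all(is.na(allgone$x1)))
  some <- inject_missing(tab, c(m1 = 0.1), seed = 2)
  frac <- mean(is.na(some$m1))
  expect_lt(abs(frac - 0.1), 2 * sqrt(0.1 * 0.9 / 10000))
  expect_error(inject_missing(tab, c(x1 = 1.2)), "\\[0, 1\\]")
})

test_that("cohort tables round-trip through CSV + schema sidecar", {
  tab <- generate_cohort(mini_config(n = 40), seed = 3)
  p <- tempfile(fileext = ".csv")
  write_cohort(tab, p)
  back <- read_cohort(p)
  expect_equal(strip_meta(back), strip_meta(tab), tolerance = 1e-12)
  expect_identical(back$m1, tab$m1)
  expect_identical(back$true_subgroup, tab$true_subgroup)
  expect_equal(cohort_columns(back, "exposure"), "e")
})
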