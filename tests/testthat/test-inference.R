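test_that("node_effects reports robust-CI odds ratios per terminal node", {
  d <- expand_2x2(641, 133, 1285, 475)
  fit <- fit_weighted_logistic(d$y, d$e)
  # single-node tree built directly
  tree <- structure(list(
    nodes = list(list(id = 1L, depth = 0L, idx = seq_along(d$y), fit = fit,
                      split = NULL, kids = NULL, terminal = TRUE)),
    outcome = "y", exposure = "e", n = length(d$y),
    weights = rep(1, length(d$y)), exposure_binary = TRUE),
    class = "mob_tree")
  eff <- node_effects(tree)
  expect_equal(round(eff$or, 2), 1.78)
  expect_equal(eff$prevalence, (641 + 1285) / 2534, tolerance = 1e-12)
  expect_lt(eff$or_lo, eff$or)
  expect_gt(eff$or_hi, eff$or)
})

test_that("a zero slope gives OR 1 with a log-symmetric interval", {
  set.seed(501)
  n <- 2000
  e <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(0.4))
  fit <- fit_weighted_logistic(y, e)
  tree <- structure(list(
    nodes = list(list(id = 1L, depth = 0L, idx = seq_len(n), fit = fit,
                      split = NULL, kids = NULL, terminal = TRUE)),
    outcome = "y", exposure = "e", n = n, weights = rep(1, n),
    exposure_binary = TRUE), class = "mob_tree")
  eff <- node_effects(tree)
  expect_equal(log(eff$or_lo) + log(eff$or_hi), 2 * log(eff$or),
               tolerance = 1e-10)
})

test_that("robust CIs attain near-nominal coverage for a known slope", {
  set.seed(502)
  reps <- 400
  cover <- vapply(seq_len(reps), function(i) {
    n <- 5000
    e <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(0.3 + log(2) * e))
    fit <- fit_weighted_logistic(y, e)
    se <- sqrt(fit$vcov_sandwich[2, 2])
    abs(fit$coef[2] - log(2)) <= 1.96 * se
  }, TRUE)
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("odds-ratio rescaling to smaller increments is algebraic and monotone", {
  expect_equal(rescale_or(0), 1)
  expect_equal(rescale_or(log(2), 0.1), 2^0.1)
  expect_equal(rescale_or(log(2), 1), 2)
  b <- c(-1, 0, 0.5, 2)
  expect_true(all(diff(rescale_or(b, 0.1)) > 0))
})

test_that("risk difference matches the printed-count arithmetic", {
  d <- expand_2x2(641, 133, 1285, 475)
  res <- bootstrap_rd(d$y, d$e, B = 200, seed = 3)
  expect_equal(res$rd, 641 / 774 - 1285 / 1760, tolerance = 1e-12)
  expect_lt(res$ci[1], res$rd)
  expect_gt(res$ci[2], res$rd)
  # equal arm proportions -> RD 0
  y0 <- rep(c(1, 0, 1, 0), c(30, 70, 60, 140))
  e0 <- rep(c(1, 1, 0, 0), c(30, 70, 60, 140))
  expect_equal(bootstrap_rd(y0, e0, B = 50, seed = 1)$rd, 0)
})

test_that("bootstrap is reproducible given its seed and errors without both arms", {
  d <- expand_2x2(60, 40, 70, 30)
  r1 <- bootstrap_rd(d$y, d$e, B = 300, seed = 11)
  r2 <- bootstrap_rd(d$y, d$e, B = 300, seed = 11)
  expect_identical(r1$ci, r2$ci)
  r3 <- bootstrap_rd(d$y, d$e, B = 300, seed = 12)
  expect_false(identical(r1$ci, r3$ci))
  expect_error(bootstrap_rd(c(0, 1, 1), c(1, 1, 1), B = 10, seed = 1),
               "both exposure arms")
})

test_that("null risk differences are covered near 95% by the percentile interval", {
  set.seed(503)
  reps <- 200
  cover <- vapply(seq_len(reps), function(i) {
    n <- 1000
    e <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, 0.7)
    ci <- bootstrap_rd(y, e, B = 200, seed = i)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, TRUE)
  expect_gt(mean(cover), 0.90)
})

test_that("split classification separates slope from prevalence differences", {
  set.seed(504)
  n <- 1000
  sim_fit <- function(b0, b1) {
    e <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(b0 + b1 * e))
    fit_weighted_logistic(y, e)
  }
  # identical fits -> neither
  f <- sim_fit(0.5, 0.3)
  expect_equal(classify_split(f, f)$label, "neither")
  # planted OR contrast 2.66 vs 0.91 with equal intercepts
  hits <- vapply(1:20, function(i) {
    cl <- classify_split(sim_fit(0.85, log(2.66)), sim_fit(0.85, log(0.91)))
    cl$label %in% c("slope heterogeneity", "both")
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  # equal OR, prevalence 0.6 vs 0.9
  cl2 <- classify_split(sim_fit(qlogis(0.6), 0.2),
                        sim_fit(qlogis(0.9), 0.2))
  expect_true(cl2$label %in% c("prevalence difference", "both"))
})
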