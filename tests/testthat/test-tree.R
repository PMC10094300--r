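make_planted_run <- function(seed = 51, n = 2534) {
  tab <- generate_cohort(kora_like_config("binary_quality", n = n),
                         seed = seed)
  ws <- stabilized_weights(
    fit_propensity_binary(tab, "green_quality", kora_confounders))
  list(tab = tab,
       tree = grow_tree(tab, "srh", "green_quality", ws,
                        cohort_columns(tab, "moderator")))
}

test_that("tree structure invariants hold on a planted cohort", {
  run <- make_planted_run(seed = 52)
  tree <- run$tree
  ctl <- tree$control
  for (nd in tree$nodes) {
    expect_lte(nd$depth, ctl$maxdepth)
    expect_gte(length(nd$idx), ctl$minsize)
    if (!nd$terminal) {
      kids <- tree$nodes[nd$kids]
      expect_setequal(c(kids[[1]]$idx, kids[[2]]$idx), nd$idx)
      expect_length(intersect(kids[[1]]$idx, kids[[2]]$idx), 0)
      # likelihood gain: children jointly fit at least as well as the parent
      expect_gte(kids[[1]]$fit$loglik + kids[[2]]$fit$loglik,
                 nd$fit$loglik - 1e-8)
    }
  }
  # terminal nodes partition all records
  mem <- node_membership(tree)
  expect_true(all(mem$node > 0))
  expect_equal(sort(unique(mem$node)), sort(terminal_ids(tree)))
})

test_that("every node's OR equals its 2x2 cross-product ratio under unit weights", {
  run <- make_planted_run(seed = 53)
  tab <- run$tab
  tree <- grow_tree(tab, "srh", "green_quality", NULL,
                    cohort_columns(tab, "moderator"))
  for (id in terminal_ids(tree)) {
    nd <- tree$nodes[[id]]
    ct <- table(tab$green_quality[nd$idx], tab$srh[nd$idx])
    or <- (ct[2, 2] * ct[1, 1]) / (ct[2, 1] * ct[1, 2])
    expect_equal(exp(nd$fit$coef[[2]]), or, tolerance = 1e-8)
  }
})

test_that("the planted partition is recovered", {
  run <- make_planted_run(seed = 54)
  tree <- run$tree
  root <- tree$nodes[[1]]
  expect_false(root$terminal)
  expect_equal(root$split$covariate, "discrimination_disability")
  expect_equal(root$split$threshold, "rather_disagree")
  right <- tree$nodes[[root$kids[2]]]
  expect_equal(right$split$covariate, "school_education")
  expect_equal(right$split$threshold, "basic")
})

test_that("maxdepth = 1 yields at most two terminal nodes", {
  tab <- generate_cohort(kora_like_config("binary_quality", n = 1200),
                         seed = 55)
  tree <- grow_tree(tab, "srh", "green_quality", NULL,
                    cohort_columns(tab, "moderator"),
                    control = mob_control(maxdepth = 1))
  expect_lte(length(terminal_ids(tree)), 2)
})

test_that("tree growth is deterministic given the table ordering", {
  run1 <- make_planted_run(seed = 56, n = 1500)
  run2 <- make_planted_run(seed = 56, n = 1500)
  expect_identical(tree_to_json(run1$tree), tree_to_json(run2$tree))
})

test_that("a degenerate root fit is a hard error", {
  tab <- generate_cohort(kora_like_config("binary_quality", n = 300),
                         seed = 57)
  tab$srh <- factor(rep("good", nrow(tab)), levels = c("bad", "good"))
  expect_error(grow_tree(tab, "srh", "green_quality", NULL,
                         cohort_columns(tab, "moderator")),
               "root fit degenerate")
})

test_that("tree JSON serialization carries ids, rules and robust SEs", {
  run <- make_planted_run(seed = 58, n = 1500)
  js <- jsonlite::fromJSON(tree_to_json(run$tree), simplifyVector = FALSE)
  expect_equal(js$n, 1500)
  root <- js$nodes[[1]]
  expect_false(root$terminal)
  expect_named(root$se_robust, c("(Intercept)", "exposure"))
  expect_true(is.character(root$split$covariate))
})
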