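test_that("five-level self-rated health collapses to good/bad with counts conserved", {
  counts <- c("very good" = 269, "good" = 1657, "moderate" = 550,
              "bad" = 57, "very bad" = 1)
  df <- data.frame(self_rated_health = rep(names(counts), counts))
  out <- dichotomize_outcome(df)
  expect_equal(as.vector(table(out$srh)), c(608, 1926))  # bad, good
  expect_equal(sum(table(out$srh)), sum(counts))
  # individual mappings
  one <- dichotomize_outcome(data.frame(self_rated_health =
    c("very good", "good", "moderate", "bad", "very bad")))
  expect_equal(as.character(one$srh), c("good", "good", "bad", "bad", "bad"))
  # case-insensitive after trimming; unknown level errors with its name
  expect_equal(as.character(
    dichotomize_outcome(data.frame(self_rated_health = " Very Good "))$srh),
    "good")
  expect_error(dichotomize_outcome(data.frame(self_rated_health = "fine")),
               "fine")
})

test_that("high-quality exposure needs access plus double strong agreement", {
  df <- data.frame(
    gs_access = c("yes", "yes", "no", "yes", NA, "yes"),
    gs_quality = c("strongly agree", "strongly agree", NA, "rather agree",
                   "strongly agree", NA),
    gs_maintained = c("strongly agree", "rather agree", NA, "strongly agree",
                      "strongly agree", "strongly agree")
  )
  out <- derive_quality_exposure(df)
  expect_equal(as.character(out$green_quality),
               c("high_quality", "lower_or_no", "lower_or_no", "lower_or_no",
                 NA, NA))
})

test_that("greenness dichotomization keeps only 'very green' positive", {
  counts <- c("very green" = 2008, "a little green" = 477,
              "hardly green" = 44, "not green at all" = 5)
  df <- data.frame(neighbourhood_greenness = rep(names(counts), counts))
  out <- dichotomize_greenness(df)
  expect_equal(as.vector(table(out$green_neighbourhood)), c(526, 2008))
  expect_error(
    dichotomize_greenness(data.frame(neighbourhood_greenness = "lush")),
    "lush")
})

test_that("recodes never create missing values from observed inputs", {
  df <- data.frame(self_rated_health = c("good", "bad", NA))
  out <- dichotomize_outcome(df)
  expect_equal(is.na(out$srh), is.na(df$self_rated_health))
})

test_that("complete-case filter drops exactly the records with missing analysis values", {
  df <- data.frame(a = c(1, 2, NA, 4), b = c("x", NA, "y", "z"))
  res <- complete_case_filter(df, c("a", "b"))
  expect_equal(res$report$n_before, 4)
  expect_equal(res$report$n_after, 2)
  expect_equal(res$report$retained_fraction, 0.5)
  # identity on complete data, idempotent
  res2 <- complete_case_filter(res$table, c("a", "b"))
  expect_identical(res2$table$a, res$table$a)
  expect_equal(res2$report$retained_fraction, 1)
  expect_error(complete_case_filter(df, character(0)), "empty")
  expect_error(complete_case_filter(df, "zz"), "zz")
})

test_that("independent 10% missingness in 3 columns retains about 0.9^3", {
  cfg <- mini_config(n = 10000)
  tab <- generate_cohort(cfg, seed = 31)
  tab$m2 <- tab$m1
  tab <- inject_missing(tab, c(x1 = 0.1, m1 = 0.1, m2 = 0.1), seed = 32)
  res <- complete_case_filter(tab, c("x1", "m1", "m2"))
  p <- 0.9^3
  expect_lt(abs(res$report$retained_fraction - p),
            2 * sqrt(p * (1 - p) / 10000))
})

test_that("attrition report reproduces the response-rate arithmetic", {
  rep <- attrition_report(c(mailed = 5256, returned = 3742,
                            complete_case = 2534))
  expect_equal(round(rep$pct_of_previous[2], 1), 71.2)
  expect_equal(round(rep$pct_of_previous[3], 1), 67.7)
  expect_equal(rep$pct_of_first[1], 100)
})
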