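#' Dichotomize five-level self-rated health
#'
#' Collapses the five-level single-item self-rated health measure into the
#' binary analysis outcome: `very good` and `good` become `good`; `moderate`,
#' `bad` and `very bad` become `bad`. Level labels are matched
#' case-insensitively after trimming; counts are conserved and missing values
#' stay missing.
#'
#' @param table a data frame or [cohort_table()].
#' @param column name of the five-level outcome column.
#' @param target name of the new binary column (default `"srh"`).
#' @return the table with the binary column appended (levels
#'   `c("bad", "good")`, role `outcome` when the input carries a schema).
#' @export
dichotomize_outcome <- function(table, column = "self_rated_health",
                                target = "srh") {
  src_levels <- c("very good", "good", "moderate", "bad", "very bad")
  idx <- match_levels(table[[column]], src_levels, "self-rated health level")
  out <- factor(ifelse(is.na(idx), NA,
                       ifelse(idx <= 2, "good", "bad")),
                levels = c("bad", "good"))
  table[[target]] <- out
  add_schema_entry(table, target,
                   list(role = "outcome", kind = "binary",
                        levels = c("bad", "good")))
}

#' Derive the binary high-quality green-space exposure
#'
#' A participant counts as having access to high-quality public green spaces
#' only if they report access (`yes`) *and* answer `strongly agree` to both
#' five-point follow-up items (high quality; well maintained). Everyone else,
#' including participants without access, is classed `lower_or_no`. A missing
#' value in any of the three items makes the derived exposure missing, so the
#' subsequent complete-case filter removes the record.
#'
#' @param table a data frame or [cohort_table()].
#' @param access,quality,maintained source column names: a yes/no access item
#'   and two five-point agreement items (`strongly agree` ... `strongly
#'   disagree`).
#' @param target name of the derived column.
#' @return the table with the binary exposure appended (levels
#'   `c("lower_or_no", "high_quality")`).
#' @export
derive_quality_exposure <- function(table,
                                    access = "gs_access",
                                    quality = "gs_quality",
                                    maintained = "gs_maintained",
                                    target = "green_quality") {
  agree <- c("strongly agree", "rather agree", "neither",
             "rather disagree", "strongly disagree")
  acc <- match_levels(table[[access]], c("no", "yes"), "access level")
  q <- match_levels(table[[quality]], agree, "agreement level")
  m <- match_levels(table[[maintained]], agree, "agreement level")
  # access = no decides the exposure even if the follow-ups are missing
  pos <- (acc == 2L) & (q == 1L) & (m == 1L)
  pos[!is.na(acc) & acc == 1L] <- FALSE
  out <- factor(ifelse(is.na(pos), NA,
                       ifelse(pos, "high_quality", "lower_or_no")),
                levels = c("lower_or_no", "high_quality"))
  table[[target]] <- out
  add_schema_entry(table, target,
                   list(role = "exposure", kind = "binary",
                        levels = c("lower_or_no", "high_quality")))
}

#' Dichotomize self-rated neighbourhood greenness
#'
#' Keeps `very green` as the positive class and groups the remaining three
#' levels (`a little green`, `hardly green`, `not green at all`) into
#' `less_green`.
#'
#' @inheritParams derive_quality_exposure
#' @param column the four-level greenness column.
#' @export
dichotomize_greenness <- function(table, column = "neighbourhood_greenness",
                                  target = "green_neighbourhood") {
  lev <- c("very green", "a little green", "hardly green", "not green at all")
  idx <- match_levels(table[[column]], lev, "greenness level")
  out <- factor(ifelse(is.na(idx), NA,
                       ifelse(idx == 1L, "very_green", "less_green")),
                levels = c("less_green", "very_green"))
  table[[target]] <- out
  add_schema_entry(table, target,
                   list(role = "exposure", kind = "binary",
                        levels = c("less_green", "very_green")))
}

add_schema_entry <- function(table, column, entry) {
  if (inherits(table, "cohort_table")) {
    sch <- cohort_schema(table)
    sch[[column]] <- entry
    attr(table, "schema") <- sch
  }
  table
}

#' Complete-case filtering with an exclusion report
#'
#' Retains only records without missing values in the listed analysis
#' columns, as model-based trees cannot handle missing data. The report gives
#' per-column missing counts and the retained fraction; filtering is
#' idempotent.
#'
#' @param table a data frame or [cohort_table()].
#' @param columns analysis columns the filter applies to.
#' @return a list with elements `table` (the filtered table) and `report`
#'   (list: `n_before`, `n_after`, `retained_fraction`, `n_missing_by_column`).
#' @export
complete_case_filter <- function(table, columns) {
  if (length(columns) == 0) stop("empty column list", call. = FALSE)
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  miss <- vapply(columns, function(cl) is.na(table[[cl]]),
                 logical(nrow(table)))
  miss <- matrix(miss, nrow = nrow(table))
  keep <- rowSums(miss) == 0
  report <- list(
    n_before = nrow(table),
    n_after = sum(keep),
    retained_fraction = sum(keep) / nrow(table),
    n_missing_by_column = stats::setNames(colSums(miss), columns)
  )
  list(table = table[keep, , drop = FALSE], report = report)
}

#' Study attrition bookkeeping
#'
#' Tracks sample sizes through successive recruitment/filtering stages and
#' the percentage each stage retains of the previous one and of the first
#' (e.g. mailed questionnaires, valid responses, complete cases).
#'
#' @param counts named integer vector of stage sizes, in order.
#' @return a data frame with columns `stage`, `n`, `pct_of_previous`,
#'   `pct_of_first`.
#' @examples
#' attrition_report(c(mailed = 5256, returned = 3742, complete_case = 2534))
#' @export
attrition_report <- function(counts) {
  stopifnot(length(counts) >= 1, !is.null(names(counts)))
  n <- as.numeric(counts)
  data.frame(
    stage = names(counts),
    n = n,
    pct_of_previous = c(NA, 100 * n[-1] / n[-length(n)]),
    pct_of_first = 100 * n / n[1],
    row.names = NULL
  )
}
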