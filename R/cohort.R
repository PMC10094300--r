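#' Cohort tables with column-role metadata
#'
#' A `cohort_table` is a plain `data.frame` carrying a schema attribute that
#' records, for every column, its analysis role (`outcome`, `exposure`,
#' `confounder`, `moderator`, `truth`, `other`) and statistical kind
#' (`binary`, `ordinal`, `nominal`, `continuous`), plus the level labels of
#' categorical columns. All downstream stages (weighting, tree growth,
#' inference) read roles from the schema rather than from column names.
#'
#' @param data a `data.frame`, one row per participant.
#' @param schema a named list, one entry per column of `data`; each entry is a
#'   list with elements `role`, `kind` and (for categorical kinds) `levels`.
#' @return `cohort_table()` returns `data` with class `cohort_table` and the
#'   schema attached; `cohort_schema()` returns the schema list.
#' @examples
#' tab <- cohort_table(
#'   data.frame(y = factor(c("good", "bad"))),
#'   schema = list(y = list(role = "outcome", kind = "binary",
#'                          levels = c("bad", "good")))
#' )
#' cohort_schema(tab)$y$role
#' @export
cohort_table <- function(data, schema) {
  stopifnot(is.data.frame(data), is.list(schema))
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols)) {
    stop("schema refers to absent columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  roles <- c("outcome", "exposure", "confounder", "moderator", "truth", "other")
  kinds <- c("binary", "ordinal", "nominal", "continuous")
  for (nm in names(schema)) {
    e <- schema[[nm]]
    if (!e$role %in% roles) stop("invalid role for column ", nm, call. = FALSE)
    if (!e$kind %in% kinds) stop("invalid kind for column ", nm, call. = FALSE)
  }
  structure(data, schema = schema, class = c("cohort_table", "data.frame"))
}

#' @rdname cohort_table
#' @param table a `cohort_table`.
#' @export
cohort_schema <- function(table) attr(table, "schema")

#' @rdname cohort_table
#' @param role a role string.
#' @return `cohort_columns()` returns the names of columns having `role`.
#' @export
cohort_columns <- function(table, role) {
  sch <- cohort_schema(table)
  names(sch)[vapply(sch, function(e) identical(e$role, role), logical(1))]
}

#' @export
print.cohort_table <- function(x, ...) {
  sch <- cohort_schema(x)
  cat("cohort_table: ", nrow(x), " records, ", ncol(x), " columns\n", sep = "")
  if (!is.null(sch)) {
    roles <- vapply(sch, `[[`, "", "role")
    for (r in unique(roles)) {
      cat("  ", r, ": ", paste(names(roles)[roles == r], collapse = ", "),
          "\n", sep = "")
    }
  }
  NextMethod()
  invisible(x)
}

# keep schema through row subsetting
#' @export
`[.cohort_table` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    sch <- cohort_schema(x)
    out <- structure(out, schema = sch[intersect(names(sch), names(out))],
                     class = c("cohort_table", "data.frame"))
  }
  out
}

#' Read and write cohort tables as CSV plus a JSON schema sidecar
#'
#' The on-disk format is a UTF-8 CSV with header row and a sidecar JSON file
#' (`<path>.schema.json` by default) mapping each column to its role, kind and
#' levels, so that categorical columns round-trip with their level order
#' (ordinal order matters for the split search).
#'
#' @param table a `cohort_table`.
#' @param path CSV file path.
#' @param schema_path sidecar path; defaults to `paste0(path, ".schema.json")`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns a
#'   `cohort_table`.
#' @export
write_cohort <- function(table, path, schema_path = paste0(path, ".schema.json")) {
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(cohort_schema(table), schema_path, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema_path = paste0(path, ".schema.json")) {
  sch <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  sch <- lapply(sch, function(e) {
    e <- as.list(e)
    if (!is.null(e$levels)) e$levels <- as.character(e$levels)
    e
  })
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (nm in names(sch)) {
    e <- sch[[nm]]
    if (e$kind %in% c("binary", "nominal", "ordinal") && !is.null(e$levels)) {
      df[[nm]] <- factor(df[[nm]], levels = e$levels,
                         ordered = identical(e$kind, "ordinal"))
    }
  }
  cohort_table(df, sch)
}
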