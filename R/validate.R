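#' Validate a taxonomy table against its sample metadata
#'
#' Cross-checks the two inputs the way the interactive app does before
#' any analysis: sample names must agree between the count table and the
#' metadata, counts must be finite and nonnegative, sample IDs non-empty,
#' and grouping variables should offer at least two categories. All
#' problems are collected into one report rather than stopping at the
#' first, so non-expert users see everything to fix at once.
#'
#' Severity `"error"` marks a problem that blocks analysis; `"warning"`
#' (single-category variables, non-integer counts, mixed lineage depths)
#' does not. `ok` is `TRUE` iff there are no errors.
#'
#' @param table taxonomy-table data frame ([read_taxonomy_table()]).
#' @param meta metadata data frame ([read_metadata()]).
#' @return A `validation_report`: data frame of issues with columns
#'   `code`, `severity`, `message`, `location`, and attribute `ok`.
#' @examples
#' demo <- demo_dataset()
#' rep <- validate_input_files(demo$table, demo$metadata)
#' attr(rep, "ok")
#' @export
validate_input_files <- function(table, meta) {
  issues <- list()
  add <- function(code, severity, message, location = "") {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, severity = severity, message = message,
      location = location, stringsAsFactors = FALSE)
  }

  if (!"sum.taxonomy" %in% names(table)) {
    add("missing_taxonomy_column", "error",
        "taxonomy table has no `sum.taxonomy` column", "taxonomy")
    return(validation_report(issues))
  }
  sample_ids <- setdiff(names(table), "sum.taxonomy")
  meta_ids <- metadata_sample_ids(meta)

  if (any(!nzchar(sample_ids))) {
    add("empty_sample_id", "error", "taxonomy table has an empty sample name",
        "taxonomy header")
  }
  if (any(!nzchar(meta_ids))) {
    add("empty_sample_id", "error", "metadata has an empty sample name",
        "metadata column 1")
  }
  if (anyDuplicated(meta_ids)) {
    add("duplicate_sample_id", "error",
        paste0("duplicate sample ID in metadata: ",
               paste(unique(meta_ids[duplicated(meta_ids)]), collapse = ", ")),
        "metadata column 1")
  }

  only_table <- setdiff(sample_ids, meta_ids)
  only_meta <- setdiff(meta_ids, sample_ids)
  if (length(only_table) > 0L) {
    add("sample_mismatch", "error",
        paste0("samples in taxonomy table but not metadata: ",
               paste(only_table, collapse = ", ")), "sample names")
  }
  if (length(only_meta) > 0L) {
    add("sample_mismatch", "error",
        paste0("samples in metadata but not taxonomy table: ",
               paste(only_meta, collapse = ", ")), "sample names")
  }

  for (s in intersect(sample_ids, names(table))) {
    v <- table[[s]]
    if (!is.numeric(v)) {
      add("non_numeric_count", "error",
          paste0("column '", s, "' is not numeric"), paste0("column ", s))
      next
    }
    if (any(!is.finite(v))) {
      add("non_finite_count", "error",
          paste0("non-finite count at row ", which(!is.finite(v))[1],
                 " of column '", s, "'"), paste0("column ", s))
    }
    if (any(v < 0, na.rm = TRUE)) {
      add("negative_count", "error",
          paste0("negative count at row ", which(v < 0)[1],
                 " of column '", s, "'"), paste0("column ", s))
    }
    if (any(is.finite(v) & v != round(v))) {
      add("non_integer_count", "warning",
          paste0("column '", s, "' holds non-integer counts; rarefaction ",
                 "requires integers"), paste0("column ", s))
    }
  }

  for (v in metadata_variables(meta)) {
    ncat <- length(unique(meta[[v]]))
    if (ncat < 2L) {
      add("single_category", "warning",
          paste0("metadata variable '", v, "' has a single category; group ",
                 "comparisons need >= 2"), paste0("variable ", v))
    }
    if (any(!nzchar(as.character(meta[[v]])))) {
      add("missing_metadata_value", "error",
          paste0("metadata variable '", v, "' has empty cells"),
          paste0("variable ", v))
    }
  }

  lineage <- as.character(table[["sum.taxonomy"]])
  if (length(lineage) > 0L) {
    nf <- nchar(lineage) - nchar(gsub(";", "", lineage, fixed = TRUE)) + 1L
    if (length(unique(nf)) > 1L) {
      add("mixed_rank_depth", "warning",
          paste0("lineages mix rank depths (", paste(sort(unique(nf)),
                 collapse = ", "), " fields)"), "sum.taxonomy")
    }
  }

  validation_report(issues)
}

validation_report <- function(issues) {
  df <- if (length(issues) == 0L) {
    data.frame(code = character(0), severity = character(0),
               message = character(0), location = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
  attr(df, "ok") <- !any(df$severity == "error")
  class(df) <- c("validation_report", "data.frame")
  df
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation %s: %d error(s), %d warning(s)\n",
              if (attr(x, "ok")) "OK" else "FAILED",
              sum(x$severity == "error"), sum(x$severity == "warning")))
  if (nrow(x) > 0L) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$code[i], x$message[i]))
    }
  }
  invisible(x)
}
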