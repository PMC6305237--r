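#' Read an Anacapa-style taxonomy table or a BIOM table
#'
#' The Anacapa dialect is a tab-separated text file with a header row, one
#' column named `sum.taxonomy` holding a semicolon-delimited taxonomic
#' lineage per row, and all remaining columns holding per-sample read
#' counts. BIOM input (1.0 JSON or 2.1 HDF5) is accepted as an equivalent:
#' the observation table supplies the counts and the observation metadata
#' (taxonomy ranks) is joined with `";"` into the lineage string.
#'
#' @param path path to the input file.
#' @param dialect `"anacapa_tsv"` (default) or `"biom"`.
#' @return A data frame with one `sum.taxonomy` character column and one
#'   numeric column per sample, columns in file order.
#' @export
read_taxonomy_table <- function(path, dialect = c("anacapa_tsv", "biom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("file not found: ", path)
  if (dialect == "biom") return(read_taxonomy_biom(path))

  first_line <- readLines(path, n = 1L)
  if (length(first_line) == 0L || !nzchar(first_line)) {
    stop_format(path, ": empty file (expected a header line)")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          na.strings = character(0))
  if (sum(names(df) == "sum.taxonomy") != 1L) {
    stop_format(path, ": input must contain exactly one `sum.taxonomy` column")
  }
  sample_cols <- setdiff(seq_along(df), which(names(df) == "sum.taxonomy"))
  sample_ids <- names(df)[sample_cols]
  if (anyDuplicated(sample_ids)) {
    stop_format(path, ": duplicate sample column name: ",
                paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  for (j in sample_cols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad) > 0L) {
      stop_format(path, ": non-numeric count '", df[[j]][bad[1]],
                  "' at row ", bad[1], ", column '", names(df)[j], "'")
    }
    if (anyNA(v)) {
      stop_format(path, ": missing count at row ", which(is.na(v))[1],
                  ", column '", names(df)[j], "'")
    }
    df[[j]] <- v
  }
  df
}

# BIOM reader: counts from the observation table, lineage from the
# observation metadata ranks joined with ";".
read_taxonomy_biom <- function(path) {
  b <- biomformat::read_biom(path)
  counts <- as(biomformat::biom_data(b), "matrix")
  om <- biomformat::observation_metadata(b)
  if (is.null(om)) {
    stop_format(path, ": BIOM table carries no observation (taxonomy) metadata")
  }
  if (is.data.frame(om)) {
    lineage <- apply(as.matrix(om), 1L, function(r) paste(r, collapse = ";"))
  } else {
    lineage <- vapply(om, function(r) paste(unlist(r), collapse = ";"), character(1))
  }
  df <- data.frame(sum.taxonomy = unname(lineage),
                   as.data.frame(counts, check.names = FALSE),
                   check.names = FALSE, row.names = NULL,
                   stringsAsFactors = FALSE)
  df
}

#' Drop sequence-number bookkeeping columns
#'
#' Some versions of the Anacapa pipeline append per-run `xxx_seq_number`
#' columns to the taxonomy table; they are bookkeeping, not samples, and
#' are removed before analysis. Matching is by the case-insensitive
#' column-name suffix `_seq_number`; a table with no such column is
#' returned unchanged.
#'
#' @param table taxonomy-table data frame from [read_taxonomy_table()].
#' @return The table without seq-number columns, other columns untouched.
#' @export
scrub_seq_number_columns <- function(table) {
  drop <- grepl("_seq_number$", names(table), ignore.case = TRUE) &
    names(table) != "sum.taxonomy"
  table[, !drop, drop = FALSE]
}

#' Replace empty taxonomy fields with "Unknown"
#'
#' Splits each `sum.taxonomy` lineage on `";"` and replaces every empty
#' field (including trailing ones, which Anacapa emits when lower ranks
#' are unassigned) with `"Unknown"`. A fully empty lineage expands to
#' `"Unknown"` repeated to the table's rank depth (the maximum field
#' count observed across rows). Counts are untouched; the operation is
#' idempotent.
#'
#' @param table taxonomy-table data frame with a `sum.taxonomy` column.
#' @return The table with scrubbed lineages.
#' @export
scrub_taxon_paths <- function(table) {
  if (!"sum.taxonomy" %in% names(table)) {
    stop_format("table has no `sum.taxonomy` column")
  }
  lineage <- as.character(table[["sum.taxonomy"]])
  # strsplit drops trailing empty fields; field count = separators + 1
  nfields <- nchar(lineage) - nchar(gsub(";", "", lineage, fixed = TRUE)) + 1L
  depth <- max(nfields, 1L)
  pieces <- strsplit(lineage, ";", fixed = TRUE)
  scrubbed <- mapply(function(p, n, full) {
    if (full) return(paste(rep("Unknown", depth), collapse = ";"))
    p <- c(p, rep("", n - length(p)))
    p[!nzchar(trimws(p))] <- "Unknown"
    paste(p, collapse = ";")
  }, pieces, nfields, !nzchar(trimws(lineage)), USE.NAMES = FALSE)
  table[["sum.taxonomy"]] <- scrubbed
  table
}

#' Read a sample-metadata table
#'
#' Tab-separated text with a header row; the first column holds sample
#' names (matching the taxonomy-table columns) and every remaining column
#' is a categorical variable describing the samples.
#'
#' @param path path to the metadata file.
#' @return A data frame whose first column is the sample ID and whose
#'   remaining columns are character categories.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(fields) == 0L) stop_format(path, ": empty file")
  if (length(unique(fields)) != 1L) {
    stop_format(path, ": ragged rows (line ",
                which(fields != fields[1])[1], " has ",
                fields[which(fields != fields[1])[1]], " fields, expected ",
                fields[1], ")")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          na.strings = character(0))
  if (ncol(df) < 2L) {
    stop_format(path, ": metadata needs a sample column plus >= 1 variable")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop_format(path, ": duplicate sample ID: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  df
}

metadata_sample_ids <- function(meta) as.character(meta[[1]])

metadata_variables <- function(meta) names(meta)[-1]
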