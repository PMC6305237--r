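#' Taxon-by-sample community matrix
#'
#' The central container for all analyses: a numeric matrix of read counts
#' with one row per taxon and one column per sample. Row names hold the
#' serialized taxonomic lineage (ranks joined by `";"`, the `sum.taxonomy`
#' convention of the Anacapa pipeline); column names hold sample IDs.
#'
#' @param counts numeric matrix (or object coercible to one), taxa in rows.
#' @param taxa character vector of serialized lineages; defaults to
#'   `rownames(counts)`.
#' @param samples character vector of sample IDs; defaults to
#'   `colnames(counts)`.
#' @return An object of class `community_matrix`: the count matrix with
#'   lineages as row names and sample IDs as column names.
#' @examples
#' m <- community_matrix(matrix(c(5, 0, 2, 7), 2, 2,
#'   dimnames = list(c("A;B", "A;C"), c("s1", "s2"))))
#' sample_totals(m)
#' @export
community_matrix <- function(counts, taxa = rownames(counts),
                             samples = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(taxa)) stop_format("community_matrix needs taxon lineages (row names)")
  if (is.null(samples)) stop_format("community_matrix needs sample IDs (column names)")
  taxa <- as.character(taxa)
  samples <- as.character(samples)
  if (length(taxa) != nrow(counts) || length(samples) != ncol(counts)) {
    stop_format("dimnames do not match count matrix dimensions")
  }
  if (anyDuplicated(taxa)) {
    stop_format("duplicate taxon lineage: ",
                paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
                " (aggregate with group_by_taxonomy first)")
  }
  if (anyDuplicated(samples)) {
    stop_format("duplicate sample ID: ",
                paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (any(!is.finite(counts))) stop_format("counts must be finite")
  if (any(counts < 0)) stop_format("counts must be nonnegative")
  dimnames(counts) <- list(taxa, samples)
  class(counts) <- c("community_matrix", "matrix", "array")
  counts
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d taxa x %d samples (total reads %s)\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  y <- unclass(x)
  print(utils::head(y, 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more taxa\n", nrow(x) - 6L))
  invisible(x)
}

#' Per-sample read totals
#'
#' @param m a [community_matrix()].
#' @return Named numeric vector of column sums.
#' @export
sample_totals <- function(m) colSums(m)

#' Split serialized lineages into rank vectors
#'
#' @param lineage character vector of `";"`-joined lineages.
#' @return List of character vectors, one per lineage.
#' @export
split_lineage <- function(lineage) strsplit(lineage, ";", fixed = TRUE)

#' Join rank vectors into serialized lineages
#'
#' @param ranks list of character vectors (or a single character vector).
#' @return Character vector of `";"`-joined lineages.
#' @export
join_lineage <- function(ranks) {
  if (!is.list(ranks)) ranks <- list(ranks)
  vapply(ranks, paste, character(1), collapse = ";")
}

# internal: coerce community_matrix <-> RawTaxonomyTable data.frame
as_taxonomy_table <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  df <- data.frame(sum.taxonomy = rownames(m), unclass(m),
                   check.names = FALSE, row.names = NULL,
                   stringsAsFactors = FALSE)
  df
}
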