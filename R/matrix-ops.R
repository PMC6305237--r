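#' Aggregate a taxonomy table to one row per unique taxon
#'
#' Anacapa tables may list the same lineage on several rows (one per
#' sequence variant). Rows sharing an identical serialized lineage are
#' merged by summing their counts per sample; the result is the
#' community matrix all downstream analyses consume, with taxa sorted
#' lexicographically by lineage.
#'
#' @param table taxonomy-table data frame (ideally scrubbed with
#'   [scrub_taxon_paths()]).
#' @return A [community_matrix()].
#' @export
group_by_taxonomy <- function(table) {
  if (!"sum.taxonomy" %in% names(table)) {
    stop_format("table has no `sum.taxonomy` column")
  }
  sample_ids <- setdiff(names(table), "sum.taxonomy")
  lineage <- as.character(table[["sum.taxonomy"]])
  counts <- as.matrix(table[, sample_ids, drop = FALSE])
  if (nrow(counts) == 0L) {
    out <- matrix(0, 0L, length(sample_ids),
                  dimnames = list(character(0), sample_ids))
    return(community_matrix(out))
  }
  agg <- rowsum(counts, group = lineage, reorder = TRUE)
  community_matrix(agg)
}

#' Collapse a community matrix to a coarser taxonomic rank
#'
#' Truncates each lineage to its first `level` semicolon-delimited
#' fields (e.g. `level = 2` keeps phylum and class) and merges taxa that
#' become identical by summing counts. Per-sample totals are preserved
#' exactly.
#'
#' @param m a [community_matrix()].
#' @param level integer rank depth to keep, `1 <= level`.
#' @return A [community_matrix()] at the coarser rank.
#' @export
collapse_to_rank <- function(m, level) {
  stopifnot(inherits(m, "community_matrix"))
  if (length(level) != 1L || is.na(level) || level < 1) {
    stop_domain("level must be a positive integer")
  }
  level <- as.integer(level)
  trunc <- vapply(split_lineage(rownames(m)), function(p) {
    paste(p[seq_len(min(level, length(p)))], collapse = ";")
  }, character(1))
  agg <- rowsum(unclass(m), group = trunc, reorder = TRUE)
  community_matrix(agg)
}

#' Categorize a continuous variable into low / medium / high tertiles
#'
#' Continuous metadata (e.g. temperature, depth) is turned into a
#' three-level factor so it can drive group comparisons: values at or
#' below the 1/3 empirical quantile are `"low"`, those at or below the
#' 2/3 quantile `"medium"`, and the rest `"high"`. Quantiles use linear
#' interpolation between order statistics ([stats::quantile] type 7);
#' ties share a label, so heavily tied data may leave a level empty.
#' The labels depend only on the rank order of the input.
#'
#' @param values named numeric vector (names are sample IDs) or plain
#'   numeric vector.
#' @return Character vector of `"low"`/`"medium"`/`"high"`, same names.
#' @examples
#' categorize_continuous(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4, s5 = 5, s6 = 6))
#' @export
categorize_continuous <- function(values) {
  if (any(!is.finite(values))) stop_domain("values must be finite")
  if (length(unique(values)) < 2L) {
    stop_domain("all values identical; cannot form categories")
  }
  q <- stats::quantile(values, c(1, 2) / 3, names = FALSE, type = 7)
  out <- ifelse(values <= q[1], "low", ifelse(values <= q[2], "medium", "high"))
  names(out) <- names(values)
  out
}
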