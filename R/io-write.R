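# Format numbers so that read.delim()/as.numeric() round-trips them
# bit-exactly: integers print without decimals, everything else with 17
# significant digits.
format_count <- function(x) {
  out <- sprintf("%.17g", x)
  whole <- is.finite(x) & x == round(x) & abs(x) < 2^53
  out[whole] <- sprintf("%.0f", x[whole])
  out
}

write_tsv_raw <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) format_count(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write a taxonomy table or community matrix as Anacapa TSV
#'
#' Output is tab-separated with a `sum.taxonomy` column and one numeric
#' column per sample, and reads back bit-exactly through
#' [read_taxonomy_table()].
#'
#' @param x taxonomy-table data frame or [community_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(x, path) {
  if (inherits(x, "community_matrix")) x <- as_taxonomy_table(x)
  if (!"sum.taxonomy" %in% names(x)) {
    stop_format("object has no `sum.taxonomy` column")
  }
  write_tsv_raw(x, path)
}

#' Write sample metadata as TSV
#'
#' @param meta metadata data frame ([read_metadata()] layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) write_tsv_raw(meta, path)

#' Write a distance matrix as a square symmetric TSV
#'
#' The layout is a header of sample IDs, then one row per sample with the
#' ID in the first column; the diagonal is zero.
#'
#' @param dm a [stats::dist] object or square symmetric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(sample = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
}

#' Read a square distance-matrix TSV written by [write_distance_matrix()]
#'
#' @param path input path.
#' @return A [stats::dist] object with sample labels.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", na.strings = character(0))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}

#' Write a taxonomy table as a BIOM 1.0 (JSON) file
#'
#' Counts go into the observation table; the lineage is split on `";"`
#' and stored as per-rank observation metadata, so the file reads back
#' through [read_taxonomy_table()] with `dialect = "biom"` unchanged.
#'
#' @param x taxonomy-table data frame or [community_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biom_table <- function(x, path) {
  if (inherits(x, "community_matrix")) x <- as_taxonomy_table(x)
  lineage <- as.character(x[["sum.taxonomy"]])
  counts <- as.matrix(x[, setdiff(names(x), "sum.taxonomy"), drop = FALSE])
  rownames(counts) <- make.unique(lineage, sep = "~dup")
  nf <- nchar(lineage) - nchar(gsub(";", "", lineage, fixed = TRUE)) + 1L
  depth <- max(nf, 1L)
  ranks <- t(vapply(strsplit(lineage, ";", fixed = TRUE), function(p) {
    c(p, rep("", depth - length(p)))
  }, character(depth)))
  om <- as.data.frame(ranks, stringsAsFactors = FALSE)
  rownames(om) <- rownames(counts)
  b <- biomformat::make_biom(counts, observation_metadata = om)
  biomformat::write_biom(b, path)
  invisible(path)
}

#' Write a dendrogram in Newick format
#'
#' @param hc an `hclust` object (e.g. from [ward_cluster()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write any analysis artifact to disk
#'
#' Dispatching convenience over the specific writers: `"tsv"` accepts
#' data frames, community matrices, and distance matrices; `"biom"`
#' accepts taxonomy tables / community matrices; `"newick"` accepts
#' `hclust` dendrograms.
#'
#' @param obj object to serialize.
#' @param path output path.
#' @param format `"tsv"`, `"biom"`, or `"newick"`.
#' @return `path`, invisibly.
#' @export
write_output <- function(obj, path, format = c("tsv", "biom", "newick")) {
  format <- match.arg(format)
  switch(format,
    tsv = {
      if (inherits(obj, "community_matrix")) {
        write_taxonomy_table(obj, path)
      } else if (inherits(obj, "dist")) {
        write_distance_matrix(obj, path)
      } else if (is.matrix(obj)) {
        write_distance_matrix(obj, path)
      } else if (is.data.frame(obj)) {
        write_tsv_raw(obj, path)
      } else {
        stop_format("cannot write objects of class ",
                    paste(class(obj), collapse = "/"), " as TSV")
      }
    },
    biom = write_biom_table(obj, path),
    newick = write_newick(obj, path)
  )
  invisible(path)
}
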