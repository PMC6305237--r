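#' Built-in demonstration dataset (4 eDNA samples, 10 taxa)
#'
#' A small taxon-by-sample table in the Anacapa dialect together with
#' its metadata: four seawater eDNA samples from two rocky-reef
#' localities, one inside a marine protected area (MPA) and one
#' outside. Counts are fixed and byte-stable across calls; the
#' lineages are synthetic 6-rank placeholders (the counts, not the
#' names, carry the structure). Column totals are 24, 36, 89, and 280
#' reads.
#'
#' @return A list with elements `table` (taxonomy-table data frame,
#'   [read_taxonomy_table()] layout) and `metadata` (metadata data
#'   frame, [read_metadata()] layout).
#' @examples
#' demo <- demo_dataset()
#' colSums(demo$table[, -1])
#' @export
demo_dataset <- function() {
  lineage <- sprintf(
    "Animalia;Chordata;Actinopteri;Order_%02d;Genus_%02d;Species_%02d",
    1:10, 1:10, 1:10)
  table <- data.frame(
    sum.taxonomy = lineage,
    Arch_point_1         = c(0, 0, 0, 0, 24, 0, 0, 0, 0, 0),
    Arch_point_2         = c(0, 0, 0, 0, 36, 0, 0, 0, 0, 0),
    Black_seabass_reef_1 = c(0, 43, 0, 0, 30, 0, 0, 16, 0, 0),
    Black_seabass_reef_2 = c(0, 87, 0, 0, 16, 0, 0, 177, 0, 0),
    check.names = FALSE, stringsAsFactors = FALSE)
  metadata <- data.frame(
    Sample = c("Black_seabass_reef_1", "Arch_point_1", "Arch_point_2",
               "Black_seabass_reef_2"),
    Sample_or_Control = c("Sample", "Sample", "Sample", "Sample"),
    Island = c("Anacapa", "Santa Barbara", "Santa Barbara", "Anacapa"),
    Protection = c("MPA", "non-MPA", "non-MPA", "MPA"),
    Locality = c("Black_seabass_reef", "Arch_point", "Arch_point",
                 "Black_seabass_reef"),
    check.names = FALSE, stringsAsFactors = FALSE)
  list(table = table, metadata = metadata)
}

#' Simulate a grouped eDNA community (Dirichlet-multinomial)
#'
#' Generates a community matrix with known group structure for power
#' and calibration studies. A base composition is drawn once from a
#' flat Dirichlet; each group's composition tilts the base by a
#' log-normal factor with standard deviation `effect_size` (so
#' `effect_size = 0` makes the groups exchangeable — the null model).
#' Within a group, each sample's composition is a Dirichlet draw around
#' the group composition with concentration `concentration`
#' (non-reference groups use `concentration / dispersion_ratio^2`, so
#' `dispersion_ratio > 1` spreads them more; `1` means homogeneous
#' dispersions). Reads are then a multinomial draw at a depth uniform
#' over `depth_range`.
#'
#' @param n_taxa number of taxa.
#' @param n_samples_per_group samples in each group.
#' @param group_labels character vector of group names.
#' @param effect_size between-group compositional shift, `>= 0`.
#' @param dispersion_ratio within-group spread of non-reference groups
#'   relative to the first group, `> 0`.
#' @param depth_range integer `c(min, max)` sequencing depth per sample.
#' @param concentration Dirichlet concentration of the within-group
#'   sample-to-sample variation (default 200; larger = tighter).
#' @param seed integer seed; the same seed reproduces the matrix.
#' @return A list with `matrix` (a [community_matrix()]) and `metadata`
#'   (data frame with columns `Sample` and `group`).
#' @export
simulate_community <- function(n_taxa = 50L, n_samples_per_group = 5L,
                               group_labels = c("A", "B"),
                               effect_size = 0, dispersion_ratio = 1,
                               depth_range = c(5000L, 10000L),
                               concentration = 200, seed = 1L) {
  if (n_taxa < 2L) stop_domain("need >= 2 taxa")
  if (n_samples_per_group < 1L) stop_domain("need >= 1 sample per group")
  if (length(group_labels) < 2L) stop_domain("need >= 2 groups")
  if (effect_size < 0) stop_domain("effect_size must be >= 0")
  if (dispersion_ratio <= 0) stop_domain("dispersion_ratio must be > 0")
  if (length(depth_range) != 2L || depth_range[1] > depth_range[2] ||
      depth_range[1] < 1) {
    stop_domain("depth_range must be c(min, max) with 1 <= min <= max")
  }
  lineage <- sprintf(
    "Synthetica;Simulata;Order_%02d;Family_%02d;Genus_%02d;Species_%03d",
    ((seq_len(n_taxa) - 1L) %% 7L) + 1L, ((seq_len(n_taxa) - 1L) %% 13L) + 1L,
    ((seq_len(n_taxa) - 1L) %% 29L) + 1L, seq_len(n_taxa))

  with_seed(seed, {
    base <- stats::rgamma(n_taxa, shape = 1)
    base <- base / sum(base)
    counts <- NULL
    ids <- character(0)
    glab <- character(0)
    for (k in seq_along(group_labels)) {
      tilt <- exp(effect_size * stats::rnorm(n_taxa))
      comp <- base * tilt
      comp <- comp / sum(comp)
      theta <- if (k == 1L) concentration else concentration / dispersion_ratio^2
      for (s in seq_len(n_samples_per_group)) {
        p <- stats::rgamma(n_taxa, shape = comp * theta)
        if (sum(p) == 0) p <- comp
        p <- p / sum(p)
        depth <- sample(seq.int(depth_range[1], depth_range[2]), 1L)
        x <- stats::rmultinom(1L, depth, p)[, 1]
        counts <- cbind(counts, x)
        ids <- c(ids, sprintf("%s_%02d", group_labels[k], s))
        glab <- c(glab, group_labels[k])
      }
    }
    dimnames(counts) <- list(lineage, ids)
    list(matrix = community_matrix(counts),
         metadata = data.frame(Sample = ids, group = glab,
                               check.names = FALSE, stringsAsFactors = FALSE))
  })
}
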