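#' Rarefy each sample to a fixed read depth (single draw)
#'
#' Standardizes sequencing effort by drawing exactly `depth` reads
#' without replacement from each sample (a multivariate hypergeometric
#' draw on the sample's read pool), so every retained sample's total
#' equals `depth`. Samples whose total is below `depth` cannot supply
#' enough reads and are dropped with a warning.
#'
#' @param m a [community_matrix()] with integer counts.
#' @param depth target reads per sample, positive integer.
#' @param seed integer seed; the draw is reproducible.
#' @return A [community_matrix()] whose retained columns each sum to
#'   `depth`. Dropped sample IDs are recorded in attribute
#'   `"dropped_samples"`.
#' @export
rarefy_once <- function(m, depth, seed = 1L) {
  stopifnot(inherits(m, "community_matrix"))
  if (length(depth) != 1L || is.na(depth) || depth <= 0) {
    stop_domain("depth must be a positive integer")
  }
  if (any(m != round(m))) {
    stop_domain("rarefaction requires integer counts")
  }
  depth <- as.integer(round(depth))
  totals <- colSums(m)
  keep <- totals >= depth
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) with fewer than ", depth,
            " reads: ", paste(colnames(m)[!keep], collapse = ", "),
            call. = FALSE)
  }
  if (!any(keep)) {
    stop_domain("no sample has at least ", depth, " reads")
  }
  kept <- which(keep)
  out <- with_seed(seed, {
    vapply(kept, function(j) {
      draw_hypergeometric(unclass(m)[, j], depth)
    }, numeric(nrow(m)))
  })
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), colnames(m)[kept]))
  res <- community_matrix(out)
  attr(res, "dropped_samples") <- colnames(m)[!keep]
  res
}

# Draw `depth` reads without replacement from a pool where taxon i
# contributes counts[i] reads (multivariate hypergeometric).
draw_hypergeometric <- function(counts, depth) {
  pool <- rep.int(seq_along(counts), counts)
  picked <- sample(pool, depth, replace = FALSE)
  tabulate(picked, nbins = length(counts))
}

#' Rarefy with replicate draws averaged per cell
#'
#' Performs [rarefy_once()] `replicates` times with distinct seeds
#' derived from `seed`, then returns the per-cell mean rounded to the
#' nearest integer (ties round half away from zero). Averaging smooths
#' the sampling noise of a single draw while keeping integer counts.
#'
#' @inheritParams rarefy_once
#' @param replicates number of independent draws, `>= 1`.
#' @return A [community_matrix()]; column sums are within rounding of
#'   `depth`.
#' @export
custom_rarefaction <- function(m, depth, replicates = 10L, seed = 1L) {
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1) {
    stop_domain("replicates must be >= 1")
  }
  replicates <- as.integer(replicates)
  acc <- NULL
  dropped <- character(0)
  for (r in seq_len(replicates)) {
    ri <- withCallingHandlers(
      rarefy_once(m, depth, seed = derive_seed(seed, r)),
      warning = function(w) if (r > 1L) invokeRestart("muffleWarning"))
    if (is.null(acc)) {
      acc <- unclass(ri)
      dropped <- attr(ri, "dropped_samples")
    } else {
      acc <- acc + unclass(ri)
    }
  }
  mean_counts <- acc / replicates
  # round half away from zero (counts are nonnegative: floor(x + 0.5))
  out <- floor(mean_counts + 0.5)
  res <- community_matrix(out)
  attr(res, "dropped_samples") <- dropped
  res
}

#' Analytic taxon-accumulation (rarefaction) curves
#'
#' For a sample with total \eqn{N} reads of which taxon \eqn{i} has
#' \eqn{N_i}, the expected number of distinct taxa in a random subsample
#' of \eqn{n} reads drawn without replacement is
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N-N_i}{n} / \binom{N}{n}\right],}
#' the hypergeometric expectation classically used for rarefaction
#' curves. Curves are evaluated at depths \eqn{1, 1+step, 1+2\,step,
#' \ldots} up to \eqn{N}, with \eqn{N} always included so the final
#' point equals the observed richness exactly.
#'
#' @param m a [community_matrix()] with integer counts.
#' @param step depth increment between evaluation points, `>= 1`.
#' @return A long-format data frame with columns `sample_id`, `depth`,
#'   `expected_richness`.
#' @export
rarefaction_curve <- function(m, step = 1L) {
  stopifnot(inherits(m, "community_matrix"))
  if (length(step) != 1L || is.na(step) || step < 1) {
    stop_domain("step must be >= 1")
  }
  if (any(m != round(m))) stop_domain("rarefaction curves require integer counts")
  step <- as.integer(step)
  out <- lapply(colnames(m), function(s) {
    counts <- unclass(m)[, s]
    counts <- counts[counts > 0]
    N <- sum(counts)
    if (N == 0) {
      return(data.frame(sample_id = s, depth = 0L, expected_richness = 0,
                        stringsAsFactors = FALSE))
    }
    depths <- unique(c(seq.int(1L, N, by = step), N))
    er <- vapply(depths, function(n) expected_richness(counts, N, n), numeric(1))
    data.frame(sample_id = s, depth = depths, expected_richness = er,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# E[richness at depth n] for one sample; log-space binomials avoid
# overflow at sequencing-scale N.
expected_richness <- function(counts, N, n) {
  # P(taxon i absent from subsample) = C(N - Ni, n) / C(N, n)
  p_absent <- exp(lchoose(N - counts, n) - lchoose(N, n))
  p_absent[N - counts < n] <- 0
  sum(1 - p_absent)
}
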