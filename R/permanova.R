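#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the variation of a dissimilarity matrix among the levels
#' of a grouping factor (the adonis formulation). With squared
#' dissimilarities \eqn{d_{ij}^2},
#' \deqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2, \qquad
#'       SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,}
#' \eqn{SS_{between} = SS_{total} - SS_{within}}, and the pseudo-F
#' statistic is \eqn{[SS_B/(a-1)] / [SS_W/(N-a)]}. Significance comes
#' from permuting the group labels. When the number of distinct label
#' arrangements is at most `min(n_permutations, 10000)` they are
#' enumerated exhaustively and the p-value is the exact fraction
#' \eqn{\#\{F_{perm} \ge F_{obs}\}/\#perms}; otherwise
#' `n_permutations` random permutations are drawn and
#' \eqn{p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(n_{perm} + 1)}.
#'
#' @param dm a [stats::dist] object or square symmetric matrix.
#' @param groups group label per sample (named by sample ID, or in
#'   distance-matrix order).
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @param scheme `"auto"` (exhaustive when feasible, as described
#'   above) or `"sampled"` (always draw random permutations, e.g. to
#'   study the sampling convergence itself).
#' @return An object of class `permanova_result`: list with `statistic`
#'   (pseudo-F), `df`, `sums_of_squares`, `R2`, `p`, `n_permutations`
#'   (permutations actually used), and `exhaustive`.
#' @export
permanova <- function(dm, groups, n_permutations = 999L, seed = 1L,
                      scheme = c("auto", "sampled")) {
  scheme <- match.arg(scheme)
  d <- as.matrix(dm)
  n <- nrow(d)
  groups <- align_to_dist(d, groups)
  g <- factor(groups)
  a <- nlevels(g)
  if (a < 2L) stop_domain("PERMANOVA needs >= 2 groups")
  if (any(tabulate(g) == 0L)) stop_domain("every group must be nonempty")
  if (n - a < 1L) stop_domain("no residual degrees of freedom")
  d2 <- d^2

  obs <- permanova_decompose(d2, as.integer(g), a)
  n_distinct <- multinomial_coefficient(tabulate(g))
  exhaustive <- scheme == "auto" && is.finite(n_distinct) &&
    n_distinct <= min(n_permutations, 10000)

  if (exhaustive) {
    perms <- multiset_permutations(as.integer(g))
    f_perm <- permanova_f_batch(d2, perms, a, tabulate(g))
    p <- sum(f_perm >= obs["F"] - 1e-12) / ncol(perms)
    n_used <- ncol(perms)
  } else {
    perms <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        as.integer(g)[sample.int(n)]
      }, integer(n))
    })
    f_perm <- permanova_f_batch(d2, perms, a, tabulate(g))
    p <- (sum(f_perm >= obs["F"] - 1e-12) + 1) / (n_permutations + 1)
    n_used <- n_permutations
  }

  structure(list(
    statistic = unname(obs["F"]),
    df = c(between = a - 1L, within = n - a),
    sums_of_squares = c(between = unname(obs["ssb"]),
                        within = unname(obs["ssw"]),
                        total = unname(obs["sst"])),
    R2 = unname(obs["ssb"] / obs["sst"]),
    p = p,
    n_permutations = n_used,
    exhaustive = exhaustive,
    groups = levels(g)
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (one factor)\n")
  cat(sprintf("  pseudo-F = %.4f on df (%d, %d), R2 = %.4f\n",
              x$statistic, x$df["between"], x$df["within"], x$R2))
  cat(sprintf("  p = %.4g (%s%d permutations)\n", x$p,
              if (x$exhaustive) "exhaustive, " else "", x$n_permutations))
  invisible(x)
}

# Observed decomposition from squared dissimilarities and integer labels.
permanova_decompose <- function(d2, gi, a) {
  n <- nrow(d2)
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (l in seq_len(a)) {
    idx <- which(gi == l)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssb <- sst - ssw
  f <- if (ssw == 0) {
    if (ssb <= 0) 0 else Inf
  } else {
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  c(F = f, ssb = ssb, ssw = ssw, sst = sst)
}

# Pseudo-F for every column of an integer label matrix, vectorized via
# quadratic forms z' D2 z per group.
permanova_f_batch <- function(d2, label_mat, a, group_sizes) {
  n <- nrow(d2)
  sst <- sum(d2) / (2 * n)
  ssw <- numeric(ncol(label_mat))
  for (l in seq_len(a)) {
    z <- (label_mat == l) * 1
    quad <- colSums(z * (d2 %*% z))   # z' D2 z per permutation
    ssw <- ssw + quad / (2 * group_sizes[l])
  }
  ssb <- sst - ssw
  f <- ifelse(ssw == 0, ifelse(ssb <= 0, 0, Inf),
              (ssb / (a - 1)) / (ssw / (n - a)))
  f
}

multinomial_coefficient <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# All distinct arrangements of an integer label multiset, one column
# per arrangement. Only called when the count is small.
multiset_permutations <- function(labels) {
  n <- length(labels)
  counts <- tabulate(labels)
  out <- list()
  current <- integer(n)
  recurse <- function(pos, counts) {
    if (pos > n) {
      out[[length(out) + 1L]] <<- current
      return(invisible(NULL))
    }
    for (l in seq_along(counts)) {
      if (counts[l] > 0L) {
        current[pos] <<- l
        counts[l] <- counts[l] - 1L
        recurse(pos + 1L, counts)
        counts[l] <- counts[l] + 1L
      }
    }
  }
  recurse(1L, counts)
  matrix(unlist(out), nrow = n)
}

#' Pairwise PERMANOVA with multiplicity adjustment
#'
#' Runs [permanova()] on the sub-matrix of every unordered pair of
#' group levels and adjusts the p-values for the number of pairs
#' (Bonferroni by default, Benjamini-Hochberg optional).
#'
#' @inheritParams permanova
#' @param adjust `"bonferroni"` (default) or `"bh"`.
#' @return Data frame with one row per pair: `group_a`, `group_b`, `F`,
#'   `R2`, `p`, `p_adj`, `exhaustive`.
#' @export
pairwise_permanova <- function(dm, groups, n_permutations = 999L,
                               adjust = c("bonferroni", "bh"), seed = 1L) {
  adjust <- match.arg(adjust)
  d <- as.matrix(dm)
  groups <- align_to_dist(d, groups)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop_domain("need >= 2 groups")
  pairs <- utils::combn(levels(g), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    keep <- groups %in% pairs[, k]
    sub <- d[keep, keep, drop = FALSE]
    res <- permanova(sub, groups[keep], n_permutations = n_permutations,
                     seed = derive_seed(seed, k))
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               F = res$statistic, R2 = res$R2, p = res$p,
               exhaustive = res$exhaustive, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p,
                               method = if (adjust == "bh") "BH" else "bonferroni")
  out[, c("group_a", "group_b", "F", "R2", "p", "p_adj", "exhaustive")]
}

# Align a grouping vector to the row order of a distance matrix,
# matching by names when available.
align_to_dist <- function(d, groups) {
  ids <- rownames(d)
  if (!is.null(ids) && !is.null(names(groups))) {
    missing <- setdiff(ids, names(groups))
    if (length(missing) > 0L) {
      stop_domain("no group label for sample(s): ",
                  paste(missing, collapse = ", "))
    }
    groups <- groups[ids]
  }
  if (length(groups) != nrow(d)) {
    stop_domain("groups length does not match the distance matrix")
  }
  as.character(groups)
}
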