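#' Homogeneity of multivariate dispersions (betadisper formulation)
#'
#' Tests whether groups differ in their within-group spread rather than
#' their location: samples are embedded by PCoA keeping the axes of
#' negative eigenvalues separately (scaled by \eqn{\sqrt{|\lambda|}}),
#' each sample's distance to its group center is
#' \deqn{z_i = \sqrt{\max(0,\; \|u_i - c_u\|^2 - \|v_i - c_v\|^2)}}
#' (real-axis part minus imaginary-axis part, the standard correction
#' for semi-metric dissimilarities), and a one-way ANOVA F is computed
#' on the \eqn{z_i}. The permutation p-value reassigns group labels and
#' recomputes the distances to the permuted groups' centers.
#'
#' @param dm a [stats::dist] object or square symmetric matrix.
#' @param groups group label per sample; every group needs `>= 2`
#'   samples.
#' @param center_type `"centroid"` (coordinate mean, default) or
#'   `"spatial_median"` (geometric median by iterative reweighting,
#'   tolerance 1e-8, at most 200 iterations).
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return An object of class `dispersion_result`: list with
#'   `center_type`, `distances_to_center` (named), `group_means`, `F`,
#'   `df`, `p`, `n_permutations`.
#' @export
dispersion_test <- function(dm, groups,
                            center_type = c("centroid", "spatial_median"),
                            n_permutations = 999L, seed = 1L) {
  center_type <- match.arg(center_type)
  d <- as.matrix(dm)
  groups <- align_to_dist(d, groups)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop_domain("dispersion test needs >= 2 groups")
  if (any(tabulate(g) < 2L)) {
    stop_domain("every group needs >= 2 samples (singleton group found)")
  }
  ord <- pcoa(d)
  u <- ord$coordinates
  v <- ord$negative_coordinates

  z_obs <- distances_to_centers(u, v, as.integer(g), nlevels(g), center_type)
  f_obs <- dispersion_f(z_obs, as.integer(g), nlevels(g))

  n <- nrow(d)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      gi <- as.integer(g)[sample.int(n)]
      z <- distances_to_centers(u, v, gi, nlevels(g), center_type)
      dispersion_f(z, gi, nlevels(g))
    }, numeric(1))
  })
  p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_permutations + 1)

  names(z_obs) <- rownames(d)
  structure(list(
    center_type = center_type,
    distances_to_center = z_obs,
    group_means = c(tapply(z_obs, g, mean)),
    F = f_obs,
    df = c(between = nlevels(g) - 1L, within = n - nlevels(g)),
    p = p,
    n_permutations = n_permutations
  ), class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Homogeneity of multivariate dispersions\n")
  cat(sprintf("  center: %s; F = %.4f on df (%d, %d); permutation p = %.4g\n",
              x$center_type, x$F, x$df["between"], x$df["within"], x$p))
  cat("  mean distance to center by group:\n")
  print(round(x$group_means, 4))
  invisible(x)
}

# Distance of every sample to its group's center in the signed PCoA
# embedding (u: positive axes, v: negative axes).
distances_to_centers <- function(u, v, gi, a, center_type) {
  z <- numeric(length(gi))
  for (l in seq_len(a)) {
    idx <- which(gi == l)
    if (center_type == "centroid") {
      cu <- colMeans(u[idx, , drop = FALSE])
      cv <- if (ncol(v) > 0L) colMeans(v[idx, , drop = FALSE]) else numeric(0)
    } else {
      cen <- spatial_median(u[idx, , drop = FALSE], v[idx, , drop = FALSE])
      cu <- cen$u
      cv <- cen$v
    }
    du2 <- rowSums((u[idx, , drop = FALSE] -
                      matrix(cu, length(idx), ncol(u), byrow = TRUE))^2)
    dv2 <- if (ncol(v) > 0L) {
      rowSums((v[idx, , drop = FALSE] -
                 matrix(cv, length(idx), ncol(v), byrow = TRUE))^2)
    } else {
      0
    }
    z[idx] <- sqrt(pmax(0, du2 - dv2))
  }
  z
}

dispersion_f <- function(z, gi, a) {
  n <- length(z)
  grand <- mean(z)
  ssb <- 0; ssw <- 0
  for (l in seq_len(a)) {
    idx <- which(gi == l)
    gm <- mean(z[idx])
    ssb <- ssb + length(idx) * (gm - grand)^2
    ssw <- ssw + sum((z[idx] - gm)^2)
  }
  if (ssw == 0) return(if (ssb <= 0) 0 else Inf)
  (ssb / (a - 1)) / (ssw / (n - a))
}

# Geometric median in the signed embedding by iterative reweighting
# (Weiszfeld-type); weights use the signed distance clamped at a floor.
spatial_median <- function(u, v, tol = 1e-8, max_iter = 200L) {
  cu <- colMeans(u)
  cv <- if (ncol(v) > 0L) colMeans(v) else numeric(0)
  for (it in seq_len(max_iter)) {
    du2 <- rowSums((u - matrix(cu, nrow(u), ncol(u), byrow = TRUE))^2)
    dv2 <- if (ncol(v) > 0L) {
      rowSums((v - matrix(cv, nrow(v), ncol(v), byrow = TRUE))^2)
    } else {
      0
    }
    di <- sqrt(pmax(du2 - dv2, 1e-12))
    w <- 1 / di
    w <- w / sum(w)
    new_u <- colSums(u * w)
    new_v <- if (ncol(v) > 0L) colSums(v * w) else numeric(0)
    delta <- sqrt(sum((new_u - cu)^2) + sum((new_v - cv)^2))
    cu <- new_u
    cv <- new_v
    if (delta < tol) break
  }
  list(u = cu, v = cv)
}
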