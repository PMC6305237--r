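#' Between-sample dissimilarity matrices
#'
#' Three dissimilarities over the samples of a community matrix:
#' \describe{
#'   \item{`bray`}{Bray-Curtis,
#'     \eqn{d = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}.}
#'   \item{`jaccard_abund`}{abundance-based Jaccard, the monotone
#'     transform \eqn{d = 2B/(1+B)} of the Bray-Curtis value \eqn{B}
#'     (the default meaning of "Jaccard" on count data in vegan-style
#'     toolkits).}
#'   \item{`jaccard_binary`}{classical Jaccard on presence/absence,
#'     \eqn{d = 1 - |shared| / |union|}.}
#' }
#' All three lie in \eqn{[0, 1]}, are symmetric, and are zero on the
#' diagonal. A sample with zero total has no composition; its distance
#' to any nonempty sample is set to 1 with a warning (and 0 to another
#' empty sample).
#'
#' @param m a [community_matrix()] with `>= 2` samples.
#' @param method `"bray"`, `"jaccard_abund"`, or `"jaccard_binary"`.
#' @return A [stats::dist] object with `attr(, "method")` set.
#' @examples
#' demo <- demo_dataset()
#' m <- group_by_taxonomy(scrub_taxon_paths(demo$table))
#' community_distance(m, "bray")
#' @export
community_distance <- function(m, method = c("bray", "jaccard_abund",
                                             "jaccard_binary")) {
  stopifnot(inherits(m, "community_matrix"))
  method <- match.arg(method)
  n <- ncol(m)
  if (n < 2L) stop_domain("need >= 2 samples for a distance matrix")
  x <- unclass(m)
  totals <- colSums(x)
  if (any(totals == 0)) {
    warning("sample(s) with zero reads: ",
            paste(colnames(m)[totals == 0], collapse = ", "),
            "; their dissimilarity to nonempty samples is set to 1",
            call. = FALSE)
  }
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- pair_dissimilarity(x[, i], x[, j], method)
    }
  }
  out <- stats::as.dist(d)
  attr(out, "method") <- method
  out
}

pair_dissimilarity <- function(x, y, method) {
  if (method == "jaccard_binary") {
    px <- x > 0; py <- y > 0
    uni <- sum(px | py)
    if (uni == 0) return(0)
    return(1 - sum(px & py) / uni)
  }
  tot <- sum(x + y)
  if (tot == 0) return(0)          # two empty samples: identical
  if (sum(x) == 0 || sum(y) == 0) return(1)
  b <- sum(abs(x - y)) / tot
  if (method == "bray") b else 2 * b / (1 + b)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Embeds a dissimilarity matrix in Euclidean space: Gower
#' double-centering \eqn{B = -\tfrac12 J D^{(2)} J} with
#' \eqn{J = I - \mathbf{1}\mathbf{1}^\top/n}, followed by an
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues. Non-Euclidean dissimilarities
#' (Bray-Curtis often is) produce negative eigenvalues; these axes are
#' not returned and no Cailliez/Lingoes correction is applied — the
#' count is reported instead, and the full signed spectrum is kept for
#' the dispersion test.
#'
#' @param dm a [stats::dist] object or square symmetric matrix.
#' @return An object of class `pcoa_ordination`: list with
#'   `coordinates` (samples x positive axes), `eigenvalues` (all, in
#'   decreasing order), `proportion_explained` (positive axes, relative
#'   to the positive-eigenvalue total), `n_negative_eigenvalues`, and
#'   `negative_coordinates` (samples x negative axes, scaled by
#'   \eqn{\sqrt{|\lambda|}}; used internally by [dispersion_test()]).
#' @export
pcoa <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 2L) stop_domain("PCoA needs >= 2 samples")
  d2 <- d^2
  centered <- scale(t(scale(t(d2), scale = FALSE)), scale = FALSE)
  b <- -0.5 * centered
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  lambda <- eig$values
  tol <- max(abs(lambda)) * 1e-9
  pos <- which(lambda > tol)
  neg <- which(lambda < -tol)
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lambda[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis.", seq_along(pos))
  neg_coords <- eig$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-lambda[neg]), length(neg))
  rownames(neg_coords) <- rownames(d)
  structure(list(
    coordinates = coords,
    eigenvalues = lambda,
    proportion_explained = lambda[pos] / sum(lambda[pos]),
    n_negative_eigenvalues = length(neg),
    negative_coordinates = neg_coords
  ), class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes, %d negative eigenvalue(s)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              x$n_negative_eigenvalues))
  pe <- x$proportion_explained
  cat(sprintf("axis 1-%d variance explained: %s\n", min(3L, length(pe)),
              paste(sprintf("%.1f%%", 100 * pe[seq_len(min(3L, length(pe)))]),
                    collapse = ", ")))
  invisible(x)
}
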