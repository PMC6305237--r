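#' Ward.D2 hierarchical clustering of samples
#'
#' Agglomerative clustering that at each step merges the pair of
#' clusters whose union has the smallest increase in within-cluster
#' variance, operating on squared dissimilarities. After merging
#' clusters \eqn{i} and \eqn{j}, the dissimilarity to any other cluster
#' \eqn{k} follows the Lance-Williams update
#' \deqn{d(ij,k) = \sqrt{\frac{(n_i+n_k)\,d_{ik}^2 + (n_j+n_k)\,d_{jk}^2
#'       - n_k\,d_{ij}^2}{n_i+n_j+n_k}}.}
#' Ties are broken deterministically by the smallest pair of cluster
#' positions (positions follow original sample order; a merged cluster
#' keeps the position of its first member).
#'
#' @param dm a [stats::dist] object or square symmetric matrix with
#'   `>= 2` samples.
#' @return An `hclust` object (method `"ward.D2"`), directly usable
#'   with [stats::cutree], [plot()], and [write_newick()].
#' @examples
#' d <- dist(c(a = 0, b = 1, c = 10))
#' hc <- ward_cluster(d)
#' hc$height  # 1 and sqrt(361/3)
#' @export
ward_cluster <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 2L) stop_domain("clustering needs >= 2 samples")
  labels <- rownames(d) %||% as.character(seq_len(n))

  active <- seq_len(n)          # positions of live clusters
  size <- rep(1L, n)            # cluster sizes by position
  code <- -seq_len(n)           # hclust codes: negative leaf, positive merge
  cur <- d                      # current dissimilarities by position
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq.int(ii + 1L, length(active))) {
        pi <- active[ii]; pj <- active[jj]
        dij <- cur[pi, pj]
        if (dij < best_d) {   # strict improvement; ties keep the first pair
          best_d <- dij
          best <- c(pi, pj)
        }
      }
    }
    pi <- best[1]; pj <- best[2]
    merge[step, ] <- sort_merge_codes(code[pi], code[pj])
    height[step] <- best_d
    # Lance-Williams Ward.D2 update against every other live cluster
    for (pk in setdiff(active, c(pi, pj))) {
      ni <- size[pi]; nj <- size[pj]; nk <- size[pk]
      new_d2 <- ((ni + nk) * cur[pi, pk]^2 + (nj + nk) * cur[pj, pk]^2 -
                   nk * best_d^2) / (ni + nj + nk)
      cur[pi, pk] <- cur[pk, pi] <- sqrt(max(0, new_d2))
    }
    size[pi] <- size[pi] + size[pj]
    code[pi] <- step
    active <- setdiff(active, pj)
  }

  hc <- list(merge = merge, height = height,
             order = hclust_order(merge),
             labels = labels, method = "ward.D2",
             call = match.call(), dist.method = attr(dm, "method") %||% "unknown")
  class(hc) <- "hclust"
  hc
}

# hclust convention: singletons (negative codes) listed before merged
# clusters, otherwise ascending.
sort_merge_codes <- function(a, b) {
  both <- c(a, b)
  both[order(both >= 0, abs(both))]
}

# Leaf plotting order by left-to-right traversal of the merge tree.
hclust_order <- function(merge) {
  walk <- function(code) {
    if (code < 0) return(-code)
    c(walk(merge[code, 1]), walk(merge[code, 2]))
  }
  walk(nrow(merge))
}
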