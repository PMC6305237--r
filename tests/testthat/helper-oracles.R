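# Independent oracles and random-fixture builders shared across tests.

# Random Anacapa-style taxonomy table: some duplicated lineages, some
# empty rank fields, integer counts.
random_taxonomy_table <- function(n_rows = 12L, n_samples = 4L, seed = 1L,
                                  with_gaps = FALSE) {
  set.seed(seed)
  phyla <- c("Chordata", "Mollusca", "Arthropoda")
  lineages <- replicate(n_rows, {
    p <- sample(phyla, 1)
    ranks <- c(p, paste0("Class_", sample(3, 1)), paste0("Order_", sample(4, 1)),
               paste0("Family_", sample(5, 1)), paste0("Genus_", sample(6, 1)),
               paste0("Species_", sample(8, 1)))
    if (with_gaps && stats::runif(1) < 0.3) {
      cut <- sample(2:6, 1)
      ranks[cut:6] <- ""
    }
    paste(ranks, collapse = ";")
  })
  counts <- matrix(as.numeric(stats::rpois(n_rows * n_samples, lambda = 20)),
                   n_rows, n_samples)
  df <- data.frame(sum.taxonomy = lineages, counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- paste0("sample_", seq_len(n_samples))
  df
}

random_metadata <- function(sample_ids, seed = 1L) {
  set.seed(seed)
  data.frame(
    Sample = sample_ids,
    site = sample(c("north", "south"), length(sample_ids), replace = TRUE),
    habitat = sample(c("reef", "kelp", "sand"), length(sample_ids),
                     replace = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE)
}

# Euclidean distance matrix of random points (always a valid metric).
random_euclidean_dist <- function(n, dim = 3L, seed = 1L) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(n * dim), n, dim)
  rownames(pts) <- paste0("s", seq_len(n))
  stats::dist(pts)
}

# Ward.D2 oracle: recompute every cluster-pair distance from scratch at
# each step via centroid algebra on squared dissimilarities:
#   ||cA - cB||^2 = mean cross d^2 - V_A - V_B,
#   V_A = (1/|A|^2) sum_{a<a'} d^2,  d_ward(A,B) = sqrt(2|A||B|/(|A|+|B|) ||cA-cB||^2)
ward_oracle <- function(dm) {
  d2 <- as.matrix(dm)^2
  clusters <- as.list(seq_len(nrow(d2)))
  heights <- numeric(0)
  merges <- list()
  cluster_d <- function(A, B) {
    cross <- mean(d2[A, B, drop = FALSE])
    vA <- sum(d2[A, A]) / (2 * length(A)^2)
    vB <- sum(d2[B, B]) / (2 * length(B)^2)
    gap2 <- cross - vA - vB
    sqrt(max(0, 2 * length(A) * length(B) / (length(A) + length(B)) * gap2))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq.int(i + 1L, length(clusters))) {
        dd <- cluster_d(clusters[[i]], clusters[[j]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merges[[length(merges) + 1L]] <- list(a = clusters[[best[1]]],
                                          b = clusters[[best[2]]])
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Leaf sets merged at each hclust step, as sorted index vectors.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  members <- function(code) {
    if (code < 0) return(-code)
    sort(c(members(hc$merge[code, 1]), members(hc$merge[code, 2])))
  }
  lapply(seq_len(nrow(hc$merge)), function(s) {
    list(a = members(hc$merge[s, 1]), b = members(hc$merge[s, 2]))
  })
}

# Rigid Procrustes residual: translate + rotate/reflect Y onto X, no
# scaling; returns sum of squared residuals.
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  k <- max(ncol(Xc), ncol(Yc))
  pad <- function(M) cbind(M, matrix(0, nrow(M), k - ncol(M)))
  Xc <- pad(Xc); Yc <- pad(Yc)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  sum((Xc - Yc %*% R)^2)
}

# Studentized-range upper tail by direct double quadrature:
# P(Q > q) = 1 - int_0^inf f_S(s) k int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# with S = sqrt(chisq_nu / nu).
tukey_tail_oracle <- function(q, k, nu) {
  inner <- function(s) {
    f <- function(z) {
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  f_s <- function(s) {
    # density of sqrt(chisq_nu/nu)
    exp(log(2) + (nu / 2) * log(nu / 2) - lgamma(nu / 2) +
          (nu - 1) * log(s) - nu * s^2 / 2)
  }
  cdf <- stats::integrate(function(sv) {
    vapply(sv, function(s) f_s(s) * inner(s), numeric(1))
  }, 0, Inf, rel.tol = 1e-9)$value
  1 - cdf
}

# One-way ANOVA by explicit least-squares projection algebra.
anova_projection_oracle <- function(values, groups) {
  g <- factor(groups)
  X <- stats::model.matrix(~g)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  n <- length(values)
  J <- matrix(1 / n, n, n)
  ssb <- drop(t(values) %*% (H - J) %*% values)
  ssw <- drop(t(values) %*% (diag(n) - H) %*% values)
  f <- (ssb / (nlevels(g) - 1)) / (ssw / (n - nlevels(g)))
  list(ssb = ssb, ssw = ssw, F = f,
       p = stats::pf(f, nlevels(g) - 1, n - nlevels(g), lower.tail = FALSE))
}

expect_community_equal <- function(a, b, tolerance = 0) {
  expect_equal(rownames(a), rownames(b))
  expect_equal(colnames(a), colnames(b))
  expect_equal(unclass(a), unclass(b), tolerance = tolerance,
               ignore_attr = TRUE)
}
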