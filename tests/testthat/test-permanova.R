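# 4 samples in 2 groups of 2: distance 0 within pairs, 1 across.
block_dist <- function() {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  d
}

test_that("exhaustive PERMANOVA on the block design gives p = 1/3 exactly", {
  res <- permanova(block_dist(), c("A", "A", "B", "B"))
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 6L)  # all distinct label arrangements
  expect_identical(res$statistic, Inf)  # zero within-group variation
  expect_equal(res$p, 1 / 3)
  # decomposition: SS_total = 1, all of it between groups
  expect_equal(unname(res$sums_of_squares["total"]), 1)
  expect_equal(unname(res$sums_of_squares["within"]), 0)
  expect_equal(res$R2, 1)
})

test_that("sampled permutations converge to the exhaustive p", {
  res <- permanova(block_dist(), c("A", "A", "B", "B"),
                   n_permutations = 9999, seed = 7, scheme = "sampled")
  expect_false(res$exhaustive)
  # binomial error around 1/3 at 9999 draws (add-one estimator)
  se <- sqrt(1 / 3 * 2 / 3 / 9999)
  expect_lt(abs(res$p - 1 / 3), 4 * se)
})

test_that("the decomposition sums exactly and matches vegan::adonis2", {
  set.seed(9)
  sim <- simulate_community(n_taxa = 25, n_samples_per_group = 4,
                            group_labels = c("A", "B", "C"),
                            effect_size = 0.6, depth_range = c(800, 1200),
                            seed = 42)
  dm <- community_distance(sim$matrix, "bray")
  g <- stats::setNames(sim$metadata$group, sim$metadata$Sample)
  res <- permanova(dm, g, n_permutations = 99, seed = 1)
  ss <- res$sums_of_squares
  expect_equal(unname(ss["between"] + ss["within"]), unname(ss["total"]),
               tolerance = 1e-10)
  expect_equal(res$R2, unname(ss["between"] / ss["total"]))
  expect_gte(res$R2, 0); expect_lte(res$R2, 1)

  skip_if_not_installed("vegan")
  df <- data.frame(g = factor(g[labels(dm)]))
  ref <- vegan::adonis2(dm ~ g, data = df, permutations = 99)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(unname(ss["between"]), ref$SumOfSqs[1], tolerance = 1e-10)
  expect_equal(unname(ss["total"]), ref$SumOfSqs[3], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("the pseudo-F is invariant under sample reordering", {
  set.seed(2)
  d <- as.matrix(random_euclidean_dist(9, seed = 2))
  g <- rep(c("A", "B", "C"), each = 3)
  names(g) <- rownames(d)
  res <- permanova(d, g, n_permutations = 49, seed = 1)
  perm <- sample(9)
  res2 <- permanova(d[perm, perm], g[perm], n_permutations = 49, seed = 1)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(res2$sums_of_squares, res$sums_of_squares, tolerance = 1e-12)
})

test_that("exhaustive and sampled p agree within binomial error", {
  set.seed(30)
  d <- as.matrix(random_euclidean_dist(7, seed = 30))
  g <- c("A", "A", "A", "B", "B", "B", "B")
  names(g) <- rownames(d)
  ex <- permanova(d, g, n_permutations = 999)
  expect_true(ex$exhaustive)
  expect_equal(ex$n_permutations, choose(7, 3) * 1L)  # 35 arrangements
  sa <- permanova(d, g, n_permutations = 9999, seed = 3, scheme = "sampled")
  se <- sqrt(ex$p * (1 - ex$p) / 9999)
  expect_lt(abs(sa$p - ex$p), 4 * se + 2 / 9999)
})

test_that("PERMANOVA p is uniform under label exchange (type I error)", {
  set.seed(55)
  n_rep <- 300L
  pvals <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_community(n_taxa = 20, n_samples_per_group = 4,
                              effect_size = 0, dispersion_ratio = 1,
                              depth_range = c(400, 800), seed = 1000 + i)
    dm <- community_distance(sim$matrix, "bray")
    permanova(dm, stats::setNames(sim$metadata$group, sim$metadata$Sample),
              n_permutations = 70)$p   # C(8,4)=70 -> exhaustive, exact p
  }, numeric(1))
  rej <- mean(pvals <= 0.05)
  # balanced 2-group arrangements come in label-swapped mirror pairs
  # with identical F, so exhaustive p is uniform on even multiples of
  # 1/70; the exact attainable level at 0.05 is P(p = 2/70) = 1/35
  level <- 1 / 35
  expect_lt(abs(rej - level), 3 * sqrt(level * (1 - level) / n_rep))
})

test_that("degenerate groupings are rejected", {
  d <- block_dist()
  expect_error(permanova(d, rep("A", 4)), ">= 2 groups")
  expect_error(permanova(d, c("A", "B", "C", "D")), "degrees of freedom")
})

test_that("pairwise PERMANOVA adjusts p per pair", {
  set.seed(77)
  sim <- simulate_community(n_taxa = 20, n_samples_per_group = 4,
                            group_labels = c("A", "B", "C"),
                            effect_size = 0.4, depth_range = c(500, 900),
                            seed = 77)
  dm <- community_distance(sim$matrix, "bray")
  g <- stats::setNames(sim$metadata$group, sim$metadata$Sample)

  bon <- pairwise_permanova(dm, g, n_permutations = 99, seed = 5)
  expect_equal(nrow(bon), 3L)
  expect_equal(bon$p_adj, pmin(1, 3 * bon$p))

  bh <- pairwise_permanova(dm, g, n_permutations = 99, adjust = "bh", seed = 5)
  expect_true(all(bh$p_adj <= bon$p_adj + 1e-12))

  # two groups: single row, same subset as a direct global test
  g2 <- g[g %in% c("A", "B")]
  sub <- as.matrix(dm)[names(g2), names(g2)]
  pw2 <- pairwise_permanova(sub, g2, n_permutations = 99, seed = 5)
  expect_equal(nrow(pw2), 1L)
  direct <- permanova(sub, g2, n_permutations = 99,
                      seed = ednascope:::derive_seed(5, 1))
  expect_equal(pw2$F, direct$statistic)
  expect_equal(pw2$p, direct$p)
})
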