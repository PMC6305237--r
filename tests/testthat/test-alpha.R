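test_that("alpha diversity matches hand computation on the demo table", {
  m <- group_by_taxonomy(scrub_taxon_paths(demo_dataset()$table))
  obs <- alpha_diversity(m, "observed")
  expect_equal(obs$value[match(c("Arch_point_1", "Arch_point_2",
                                 "Black_seabass_reef_1",
                                 "Black_seabass_reef_2"), obs$sample_id)],
               c(1, 1, 3, 3))
  sh <- alpha_diversity(m, "shannon")
  h <- function(x) { p <- x / sum(x); -sum(p * log(p)) }
  expect_equal(sh$value[sh$sample_id == "Black_seabass_reef_1"],
               h(c(43, 30, 16)), tolerance = 1e-10)
  expect_equal(sh$value[sh$sample_id == "Black_seabass_reef_1"], 1.0265134,
               tolerance = 1e-6)
  expect_equal(sh$value[sh$sample_id == "Black_seabass_reef_2"],
               h(c(87, 16, 177)), tolerance = 1e-10)
  # single-taxon samples have zero entropy
  expect_equal(sh$value[grepl("Arch_point", sh$sample_id)], c(0, 0))
})

test_that("Shannon respects its bounds and invariances", {
  set.seed(4)
  for (i in 1:8) {
    x <- stats::rpois(12, 30) + 1
    m <- community_matrix(matrix(x, 12, 1,
      dimnames = list(paste0("t;", 1:12), "s")))
    hx <- alpha_diversity(m, "shannon")$value
    expect_gte(hx, 0)
    expect_lte(hx, log(12) + 1e-12)
    # permutation invariance in taxa
    mp <- community_matrix(matrix(sample(x), 12, 1,
      dimnames = list(paste0("t;", 1:12), "s")))
    expect_equal(alpha_diversity(mp, "shannon")$value, hx)
    # scale invariance in counts
    ms <- community_matrix(matrix(7 * x, 12, 1,
      dimnames = list(paste0("t;", 1:12), "s")))
    expect_equal(alpha_diversity(ms, "shannon")$value, hx, tolerance = 1e-12)
  }
  # uniform composition attains the log-richness bound; base option rescales
  mu <- community_matrix(matrix(rep(5, 8), 8, 1,
    dimnames = list(paste0("t;", 1:8), "s")))
  expect_equal(alpha_diversity(mu, "shannon")$value, log(8))
  expect_equal(alpha_diversity(mu, "shannon", base = 2)$value, 3)
  # empty sample
  m0 <- community_matrix(matrix(0, 2, 1, dimnames = list(c("a;1", "a;2"), "s")))
  expect_equal(alpha_diversity(m0, "shannon")$value, 0)
  expect_equal(alpha_diversity(m0, "observed")$value, 0)
})

test_that("one-way ANOVA reproduces the hand-decomposed example", {
  at <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(at$sum_sq[at$term == "between"], 13.5)
  expect_equal(at$sum_sq[at$term == "within"], 4)
  expect_equal(at$df, c(1L, 4L, 5L))
  expect_equal(at$F[1], 13.5)
  # independent tail oracle: numeric integration of the F density
  p_oracle <- stats::integrate(function(x) stats::df(x, 1, 4), 13.5, Inf,
                               rel.tol = 1e-10)$value
  expect_equal(at$p[1], p_oracle, tolerance = 1e-8)
  expect_equal(at$p[1], 0.0213, tolerance = 1e-3)

  flat <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(flat$F[1], 0)
  expect_equal(flat$p[1], 1)

  # zero within-group variance with distinct means
  degen <- anova_oneway(c(1, 1, 2, 2), rep(c("a", "b"), each = 2))
  expect_identical(degen$F[1], Inf)
  expect_equal(degen$p[1], 0)

  expect_error(anova_oneway(1:4, rep("a", 4)), ">= 2 groups")
})

test_that("ANOVA decomposition matches the least-squares projection oracle", {
  set.seed(8)
  for (i in 1:10) {
    g <- sample(letters[1:3], 12, replace = TRUE)
    if (length(unique(g)) < 2) next
    y <- stats::rnorm(12)
    at <- anova_oneway(y, g)
    or <- anova_projection_oracle(y, g)
    expect_equal(at$sum_sq[1], or$ssb, tolerance = 1e-10)
    expect_equal(at$sum_sq[2], or$ssw, tolerance = 1e-10)
    expect_equal(at$F[1], or$F, tolerance = 1e-10)
    expect_equal(at$p[1], or$p, tolerance = 1e-12)
    # sums are exact
    expect_equal(at$sum_sq[3], at$sum_sq[1] + at$sum_sq[2])
    expect_equal(at$sum_sq[3], sum((y - mean(y))^2), tolerance = 1e-12)
  }
})

test_that("ANOVA p-values are uniform under a simulated null", {
  set.seed(21)
  pvals <- vapply(seq_len(2000), function(i) {
    y <- stats::rnorm(12)
    g <- rep(c("a", "b", "c"), each = 4)
    anova_oneway(y, g)$p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Tukey HSD: two-group case collapses to the ANOVA p", {
  tk <- tukey_hsd(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(tk$mean_diff, -3)
  at <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(tk$p_adj, at$p[1], tolerance = 1e-12)

  set.seed(31)
  for (i in 1:100) {
    y <- stats::rnorm(10)
    g <- rep(c("a", "b"), each = 5)
    expect_equal(tukey_hsd(y, g)$p_adj, anova_oneway(y, g)$p[1],
                 tolerance = 1e-10)
  }
})

test_that("Tukey HSD agrees with a studentized-range quadrature oracle", {
  set.seed(17)
  y <- stats::rnorm(12, mean = rep(c(0, 0.8, 2), each = 4))
  g <- rep(c("a", "b", "c"), each = 4)
  tk <- tukey_hsd(y, g)
  at <- anova_oneway(y, g)
  ms_w <- at$mean_sq[2]; df_w <- at$df[2]
  gm <- tapply(y, g, mean)
  for (r in seq_len(nrow(tk))) {
    q <- abs(gm[tk$group_a[r]] - gm[tk$group_b[r]]) /
      sqrt(ms_w / 2 * (2 / 4))
    expect_lt(abs(tk$p_adj[r] - tukey_tail_oracle(q, 3, df_w)), 1e-6)
  }
  # intervals bracket the difference, one row per unordered pair
  expect_equal(nrow(tk), 3L)
  expect_true(all(tk$ci_low <= tk$mean_diff & tk$mean_diff <= tk$ci_high))
})

test_that("Tukey-Kramer handles unbalanced groups against TukeyHSD", {
  set.seed(13)
  y <- stats::rnorm(11)
  g <- c(rep("a", 3), rep("b", 4), rep("c", 4))
  tk <- tukey_hsd(y, g)
  ref <- stats::TukeyHSD(stats::aov(y ~ factor(g)))$`factor(g)`
  # TukeyHSD reports b-a etc.; ours reports a-b
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_equal(tk$mean_diff, unname(-ref[, "diff"]), tolerance = 1e-10)
})
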