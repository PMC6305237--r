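#' Per-sample alpha diversity
#'
#' Two within-sample diversity summaries: observed richness (number of
#' taxa with a nonzero count) and Shannon entropy
#' \eqn{H = -\sum_i p_i \log p_i} with \eqn{p_i} the within-sample
#' relative abundances. Shannon uses the natural logarithm by default
#' (diversity in nats); an empty sample or a single-taxon sample has
#' \eqn{H = 0}. Values are computed on the matrix as given — rarefy
#' beforehand if depth standardization is wanted.
#'
#' @param m a [community_matrix()].
#' @param metric `"observed"` or `"shannon"`.
#' @param base logarithm base for Shannon (default `exp(1)`; use 2 for
#'   bits).
#' @return Data frame with columns `sample_id`, `metric`, `value`.
#' @examples
#' demo <- demo_dataset()
#' m <- group_by_taxonomy(scrub_taxon_paths(demo$table))
#' alpha_diversity(m, "shannon")
#' @export
alpha_diversity <- function(m, metric = c("observed", "shannon"),
                            base = exp(1)) {
  stopifnot(inherits(m, "community_matrix"))
  metric <- match.arg(metric)
  vals <- apply(unclass(m), 2L, function(x) {
    if (metric == "observed") {
      sum(x > 0)
    } else {
      tot <- sum(x)
      if (tot == 0) return(0)
      p <- x[x > 0] / tot
      max(0, -sum(p * log(p, base = base)))
    }
  })
  data.frame(sample_id = colnames(m), metric = metric, value = unname(vals),
             stringsAsFactors = FALSE)
}

#' One-way analysis of variance
#'
#' The classical fixed-effects decomposition used by the app's alpha
#' diversity statistics tab: total sum of squares split into a
#' between-group and a within-group term, \eqn{F = MS_B / MS_W} referred
#' to the F distribution on \eqn{(a-1, N-a)} degrees of freedom. If the
#' within-group variance is exactly zero while group means differ, `F`
#' is `Inf` and `p` is 0.
#'
#' @param values numeric response, one value per sample (named, or in
#'   the order of `groups`).
#' @param groups group label per sample.
#' @return An `anova_table` data frame with rows `between`, `within`,
#'   `total` and columns `df`, `sum_sq`, `mean_sq`, `F`, `p`.
#' @examples
#' anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
anova_oneway <- function(values, groups) {
  groups <- align_groups(values, groups)
  values <- as.numeric(values)
  g <- factor(groups)
  a <- nlevels(g)
  N <- length(values)
  if (a < 2L) stop_domain("ANOVA needs >= 2 groups")
  if (all(tabulate(g) < 2L)) stop_domain("ANOVA needs a group with >= 2 samples")
  grand <- mean(values)
  gmeans <- tapply(values, g, mean)
  gn <- tabulate(g)
  ss_between <- sum(gn * (gmeans - grand)^2)
  ss_within <- sum((values - gmeans[as.integer(g)])^2)
  df_b <- a - 1L
  df_w <- N - a
  if (df_w < 1L) stop_domain("no residual degrees of freedom")
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ms_w == 0) {
    f <- if (ms_b == 0) 0 else Inf
    p <- if (ms_b == 0) 1 else 0
  } else {
    f <- ms_b / ms_w
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  out <- data.frame(
    term = c("between", "within", "total"),
    df = c(df_b, df_w, N - 1L),
    sum_sq = c(ss_between, ss_within, ss_between + ss_within),
    mean_sq = c(ms_b, ms_w, NA_real_),
    F = c(f, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group-mean differences after a one-way ANOVA, with
#' family-wise adjusted p-values and simultaneous confidence intervals
#' from the studentized-range distribution. Unbalanced designs use the
#' Tukey-Kramer standard error \eqn{\sqrt{MS_W/2\,(1/n_a + 1/n_b)}}.
#' With two groups the adjusted p equals the ANOVA p (the identity
#' \eqn{q^2 = 2F}).
#'
#' @inheritParams anova_oneway
#' @param conf_level family-wise confidence level (default 0.95).
#' @return Data frame with one row per unordered group pair: `group_a`,
#'   `group_b`, `mean_diff` (a minus b), `ci_low`, `ci_high`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  groups <- align_groups(values, groups)
  values <- as.numeric(values)
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2L) stop_domain("Tukey HSD needs >= 2 groups")
  at <- anova_oneway(values, groups)
  ms_w <- at$mean_sq[at$term == "within"]
  df_w <- at$df[at$term == "within"]
  gmeans <- tapply(values, g, mean)
  gn <- tabulate(g)
  pairs <- utils::combn(levels(g), 2L)
  # k = 2: the studentized range is exactly sqrt(2)|t|, so use the t
  # distribution directly (ptukey's quadrature is only ~1e-6 accurate)
  qcrit <- if (k == 2L) {
    sqrt(2) * stats::qt((1 + conf_level) / 2, df_w)
  } else {
    stats::qtukey(conf_level, k, df_w)
  }
  out <- apply(pairs, 2L, function(pr) {
    ia <- match(pr[1], levels(g)); ib <- match(pr[2], levels(g))
    diff <- gmeans[ia] - gmeans[ib]
    se <- sqrt(ms_w / 2 * (1 / gn[ia] + 1 / gn[ib]))
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
      ci <- c(diff, diff)
    } else {
      q <- abs(diff) / se
      p <- if (k == 2L) {
        2 * stats::pt(q / sqrt(2), df_w, lower.tail = FALSE)
      } else {
        stats::ptukey(q, k, df_w, lower.tail = FALSE)
      }
      ci <- diff + c(-1, 1) * qcrit * se
    }
    data.frame(group_a = pr[1], group_b = pr[2], mean_diff = unname(diff),
               ci_low = ci[1], ci_high = ci[2], p_adj = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Align a per-sample grouping to the order of `values`, matching by
# names when both carry them.
align_groups <- function(values, groups) {
  if (!is.null(names(values)) && !is.null(names(groups))) {
    missing <- setdiff(names(values), names(groups))
    if (length(missing) > 0L) {
      stop_domain("no group label for sample(s): ",
                  paste(missing, collapse = ", "))
    }
    groups <- groups[names(values)]
  }
  if (length(groups) != length(values)) {
    stop_domain("values and groups have different lengths")
  }
  as.character(groups)
}

#' Join an alpha-diversity table with a metadata variable
#'
#' @param alpha output of [alpha_diversity()].
#' @param meta metadata data frame ([read_metadata()]).
#' @param variable name of the metadata column to attach.
#' @return `alpha` with an extra `group` column.
#' @export
alpha_with_groups <- function(alpha, meta, variable) {
  if (!variable %in% metadata_variables(meta)) {
    stop_domain("metadata has no variable '", variable, "'")
  }
  idx <- match(alpha$sample_id, metadata_sample_ids(meta))
  if (anyNA(idx)) {
    stop_domain("metadata is missing sample(s): ",
                paste(alpha$sample_id[is.na(idx)], collapse = ", "))
  }
  alpha$group <- as.character(meta[[variable]][idx])
  alpha
}
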