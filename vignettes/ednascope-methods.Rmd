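---
title: "Methods and design of ednascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ednascope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednascope)
```

## Scope and data model

`ednascope` is a batch toolkit for first-pass exploration of eDNA
metabarcoding results: a taxon-by-sample matrix of read counts (the
tab-separated Anacapa dialect with a semicolon-delimited `sum.taxonomy`
lineage column, or an equivalent BIOM table) plus a per-sample metadata
table whose first column names the samples. Everything downstream
consumes one container, the `community_matrix`: a numeric matrix with
serialized lineages as row names and sample IDs as column names,
constrained to finite nonnegative counts and unique names.

Input scrubbing mirrors what working pipelines actually emit: stray
`*_seq_number` bookkeeping columns are dropped (matched
case-insensitively on the suffix, since pipelines vary in casing);
empty rank fields become `"Unknown"`, with a fully empty lineage
expanded to the table's maximum observed rank depth. We accept tables
that mix rank depths but flag them with a warning, since a mixed-depth
table usually signals an upstream assignment problem rather than a
legitimate structure. Validation collects *all* problems into one
report instead of failing fast — the intended audience includes people
for whom this file is their first contact with sequencing output — and
splits severities: sample-name mismatches, negative or non-finite
counts, and empty identifiers are errors; single-category metadata
variables and non-integer counts are warnings (the former merely
precludes group comparisons, the latter only blocks rarefaction).

## Rarefaction

Rarefaction draws exactly `depth` reads *without replacement* from each
sample's read pool — a multivariate hypergeometric draw — so each
retained sample's total equals the target exactly and the expected
count of taxon $i$ is $n N_i / N$. Sampling with replacement would be
the main alternative; without replacement matches the convention of the
community-ecology toolchain this package interoperates with and makes
the column-sum invariant exact. Samples with fewer reads than the
target cannot supply a draw and are dropped with a warning rather than
passed through at full depth; silently mixing depths would defeat the
purpose of the step. Replicated rarefaction averages per-cell counts
over independent draws and rounds half away from zero, keeping integer
counts while shrinking single-draw noise.

Taxon-accumulation curves use the analytic hypergeometric expectation

$$E[S_n] = \sum_i \left[ 1 - \binom{N - N_i}{n} \Big/ \binom{N}{n} \right],$$

evaluated in log space (`lchoose`) so sequencing-scale totals do not
overflow. The evaluation grid is $1, 1+\mathrm{step}, \dots$ with the
sample total always appended, which forces the curve to terminate
exactly at the observed richness. We chose the analytic form over
resampling because it is deterministic and exact; the test suite
verifies it against Monte-Carlo subsampling.

## Alpha diversity

Observed richness counts nonzero taxa; Shannon diversity is
$H = -\sum_i p_i \log p_i$ on within-sample relative abundances. The
natural logarithm is the default (nats), matching the dominant
convention in community ecology software; a `base` argument covers
bits. Empty and single-taxon samples get $H = 0$. Metrics are computed
on the matrix exactly as supplied — rarefaction is an explicit upstream
step, never implicit — and empty samples are kept (richness 0) so the
sample set stays aligned with the metadata.

Group comparisons use the classical one-way fixed-effects ANOVA with
$F = MS_B / MS_W$ on $(a-1, N-a)$ degrees of freedom. If the
within-group variance is exactly zero while means differ, $F$ is
reported as `Inf` with $p = 0$ rather than `NaN`. Post-hoc pairwise
comparisons use Tukey's HSD on the studentized range with the
Tukey–Kramer harmonic adjustment $\sqrt{MS_W/2\,(1/n_a + 1/n_b)}$ for
unbalanced groups. For exactly two groups the studentized range
satisfies $q = \sqrt{2}\,|t|$ (equivalently $q^2 = 2F$), so we compute
the p-value through the t distribution there: R's `ptukey` quadrature
carries roughly $10^{-6}$ absolute error, while the t route makes the
two-group Tukey p agree with the ANOVA p to machine precision, which is
the behaviour users should be able to rely on when they sanity-check
one against the other.

Continuous metadata can be tertile-categorized into low/medium/high at
the 1/3 and 2/3 empirical quantiles (type-7 linear interpolation,
left-inclusive boundaries). Only the rank order of the input matters;
heavily tied data may leave a level empty, which the grouping checks
then surface.

## Beta diversity

Three dissimilarities are offered: Bray–Curtis
$d = \sum|x_i - y_i| / \sum(x_i + y_i)$; abundance-based Jaccard,
the monotone transform $2B/(1+B)$ of the Bray–Curtis value $B$; and
binary Jaccard on presence/absence. "Jaccard" unqualified means the
abundance-based variant, the default of the vegan-style tools this
package is exchangeable with; the binary form is an explicit option.
A sample with zero reads has no composition: its dissimilarity to any
nonempty sample is defined as 1 (and 0 to another empty sample), with
a warning.

PCoA applies Gower double-centering $B = -\tfrac12 J D^{(2)} J$ and an
eigendecomposition; coordinates are eigenvectors scaled by
$\sqrt{\lambda}$. Semi-metric dissimilarities such as Bray–Curtis
produce negative eigenvalues; we report their count and apply no
Cailliez/Lingoes correction, keeping the ordination a plain metric
embedding. The axes of negative eigenvalues are retained internally
(scaled by $\sqrt{|\lambda|}$) because the dispersion test needs them.

### PERMANOVA

The one-factor decomposition works directly on squared
dissimilarities:
$SS_{total} = \frac1N \sum_{i<j} d_{ij}^2$,
$SS_{within} = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2$, and
pseudo-$F = [SS_B/(a-1)]/[SS_W/(N-a)]$. Significance comes from
permuting group labels. Two conventions coexist and we use both, each
where it is exact: when the number of distinct label arrangements is
at most `min(n_permutations, 10000)` we enumerate them all and report
the exact fraction $\#\{F_{perm} \ge F_{obs}\}/\#\mathrm{perms}$;
otherwise we draw `n_permutations` (default 999) random permutations
and use the add-one estimator $(k+1)/(n+1)$, which cannot return 0 and
is the standard bias-safe choice for sampled permutation tests. The
permutation batch is vectorized through the quadratic form
$z^\top D^{(2)} z$ per group, so exhaustive enumeration is cheap at the
sample sizes where it applies.

One discreteness property is worth knowing: in a balanced two-group
design every arrangement has a label-swapped mirror with identical
$F$, so exhaustive p-values move on a lattice of even multiples of
$1/\#\mathrm{perms}$ and the exactly attainable size at $\alpha = 0.05$
is below $\alpha$ (e.g. $6/126 \approx 0.048$ for two groups of five).
The calibration checks in the test suite account for this rather than
expecting 0.05 on the nose.

Pairwise PERMANOVA subsets the distance matrix per unordered group
pair, reruns the test with a derived seed per pair, and adjusts
p-values with Bonferroni by default (Benjamini–Hochberg optional) —
Bonferroni being the long-standing default of the pairwise wrappers
users migrate from.

### Dispersion homogeneity

The betadisper-style test asks whether groups differ in spread, not
location. Samples are embedded by PCoA with the negative-eigenvalue
axes kept separately; each sample's distance to its group center is
$z_i = \sqrt{\max(0, \|u_i - c_u\|^2 - \|v_i - c_v\|^2)}$, the signed
combination that reproduces the original dissimilarity geometry for
semi-metric inputs. A one-way ANOVA F on the $z_i$ measures the effect,
and the permutation p reassigns labels and *recomputes distances to the
permuted groups' centers* — the full-recomputation scheme, chosen over
permuting residual distances because it re-derives the statistic under
the relabelled design exactly as defined. The group center is the
coordinate centroid by default; a spatial median (Weiszfeld iterative
reweighting on the signed embedding, tolerance $10^{-8}$, at most 200
iterations) is available for outlier-heavy groups.

### Ward.D2 clustering

Agglomeration uses the Lance–Williams Ward.D2 update

$$d(ij,k) = \sqrt{\frac{(n_i+n_k)\,d_{ik}^2 + (n_j+n_k)\,d_{jk}^2 - n_k\,d_{ij}^2}{n_i+n_j+n_k}},$$

with deterministic tie-breaking by the smallest pair of cluster
positions in original sample order (reference implementations differ
silently on ties; we pin one rule so runs are reproducible). The
result is a standard `hclust` object, exportable as Newick.

## The synthetic-community generator

`simulate_community()` provides grouped communities with known truth
for calibration and power checks. A base composition is drawn from a
flat Dirichlet; group $g$ tilts it log-normally,
$p_g \propto p_0 \exp(\sigma Z)$ with $\sigma$ = `effect_size`, so
`effect_size = 0` makes groups exchangeable (the null). Each sample's
composition is a Dirichlet draw around its group composition with
concentration 200 by default — sample-to-sample compositional noise of
a few percent, typical of replicate field samples — divided by
`dispersion_ratio`$^2$ for non-reference groups so `dispersion_ratio`
directly scales within-group spread. Reads are a multinomial draw at a
depth uniform over `depth_range` (default 5000–10000).

The generator emulates compositional structure, uneven sequencing
depth, between-group shifts, and dispersion heterogeneity. It does
*not* emulate taxonomic correlation (co-occurring taxa), contamination
and index-hopping, PCR amplification bias, or the extra zero inflation
of real metabarcoding data. Calibration results obtained with it
therefore validate the statistics' null behaviour under exchangeable
compositional sampling — not robustness to those artefacts.

The calibration checks in the test suite use deliberately small
problems so the whole suite stays quick to run: 1000 null replicates
of a 2 × 5-sample, 20-taxon design at depths 300–600 for the PERMANOVA
type-I rate (exhaustively enumerated, 252 arrangements each), 2000
hypergeometric draws for rarefaction expectations, and 100 random
6-sample matrices against the from-scratch Ward oracle. These sizes
give Monte-Carlo standard errors comfortably below the tolerances
asserted.

## Numerical choices and degenerate inputs

* Binomial coefficients for rarefaction curves in log space; absent
  taxa contribute probability 0, not NaN.
* Eigenvalues within $10^{-9} \cdot \max|\lambda|$ of zero are treated
  as null axes in PCoA (the centering always produces one).
* Permutation comparisons use $F_{perm} \ge F_{obs} - 10^{-12}$ so
  exact ties (including the observed arrangement itself) count as
  extreme; `Inf` compares as equal to `Inf`, which handles
  zero-within-variance designs.
* Zero within-group variance: ANOVA and PERMANOVA report
  $F = \infty, p = 0$ (or $F = 0, p = 1$ if between-variance is also
  zero) instead of NaN.
* TSV writers print integers without decimals and other values with 17
  significant digits, so write→read round-trips are bit-exact.
* Seeds: one user seed drives everything; replicate draws and pairwise
  subtests derive distinct child seeds from it (a fixed linear map into
  the 32-bit range), and RNG state is always restored afterwards.

## Known limitations

* One-factor designs only: no interactions, strata, or covariates in
  ANOVA/PERMANOVA.
* No phylogeny-aware dissimilarities (UniFrac) and no ordinations
  beyond PCoA.
* The dispersion test's permutation scheme recomputes centers per
  relabelling; its p-values are not numerically identical to
  implementations that permute residual distances, though both target
  the same null.
* Rarefaction requires integer counts by construction; fractional BIOM
  abundances must be rounded or rescaled upstream (validation warns).
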