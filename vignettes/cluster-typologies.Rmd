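---
title: "Person-oriented cluster typologies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-oriented cluster typologies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustype)
```

## The problem

Person-oriented research treats individuals' *patterns* of scores — types —
as the unit of analysis, rather than variable-level relations.  The
operational question is always the same: does a case-by-variable table of
quantitative (often Likert-derived) scores contain a small number of
homogeneous, well-separated, replicable types?  `clustype` implements a
repertoire of clustering methods for this question together with the
quality-coefficient and validation machinery needed to decide whether a
solution is worth interpreting at all.

Four fitting families are provided, each returning a classed S3 object:

* `ahca()` — agglomerative hierarchical clustering, eight Lance–Williams
  linkages (average, single, complete, centroid, median, Ward,
  flexible beta, McQuitty) over six case distances (squared Euclidean,
  Euclidean, Manhattan, Canberra, maximum, Minkowski);
* `dhca()` — divisive hierarchical clustering by the Kaufman–Rousseeuw
  DIANA splinter algorithm;
* `kcenter()` — partitioning: k-means (Hartigan–Wong, MacQueen,
  Lloyd–Forgy), PAM k-medoids, and geometric-median k-medians;
* `mbca()` — Gaussian-mixture model-based clustering over the fourteen
  eigen-decomposition covariance families, selected by BIC or ICL.

## Quality coefficients

All solutions are scored on standardized variables (z-scores with the
*n−1* denominator — see "Numerical conventions" below).  The distance unit
throughout is the **ASED**, the squared Euclidean distance divided by the
number of variables *p*; dividing by *p* makes thresholds transferable
across studies with different numbers of input variables.  Two independent
standardized cases have expected ASED of 2, which anchors everything else.

* **HC** (homogeneity coefficient) of cluster *c* is the mean pairwise ASED
  among its members, computable in closed form as
  $HC_c = 2\,\mathrm{WSS}_c / (p\,(n_c - 1))$, with $HC = 0$ for singletons.
  0 means identical members; about 2 means no more coherence than random
  standardized cases.  `HCmean` is the size-weighted average
  $\sum_c n_c HC_c / n$.
* **EESS%** $= 100\,(T - \mathrm{WSS})/T$, where $T$ is the total sum of
  squared deviations from the grand centroid — the multivariate
  generalization of ANOVA's $\eta^2$.  The identity
  $\sum_c (n_c - 1) HC_c \, p/2 = \mathrm{WSS}$ links the two families, and
  for solutions whose clusters all hold at least ~20 cases it forces the
  complementarity $EESS\% \approx 100\,(1 - HC_{mean}/2)$; the test suite
  asserts both.
* **XBmod** is a separation index: the minimum inter-centroid ASED over
  cluster pairs, minus `HCmean`.  It is positive when the closest pair of
  centroids is farther apart than the average within-cluster spread and
  negative for overlapping solutions.  *The exact published formula for
  this coefficient is defined in software documentation we could not
  obtain; the reconstruction used here was chosen because it behaves as the
  reported values do (same sign pattern, same order of magnitude, negative
  under overlap).  It is isolated in one function (`xbmod()`) so it can be
  replaced wholesale if the canonical definition becomes available.*
* **Mean silhouette** — the Rousseeuw silhouette averaged over cases,
  singletons contributing 0.
* **Homogeneity percentages** `Hom10/20/30/50` — the percentage of cases in
  clusters with HC *strictly below* 0.10, 0.20, 0.30, 0.50.  Strictness
  matters: recomputing a printed table from HC values rounded to two
  decimals can flip a cluster sitting exactly on a threshold, which is why
  worked examples pin only the threshold comparisons that are stable under
  printed rounding.
* **Acceptability** — the conventional overall rule EESS% > 70,
  XBmod > 0.50, HCmean < 0.50 (strict), configurable in `acceptability()`.

`pattern_table()` codes standardized cluster means into the conventional
symbols: `.` for $|z| < 0.25$, `(H)`/`(L)` up to 0.5, `H`/`L` up to 1.0,
then one `+` per additional 0.5, capped at `++++` ($|z| \ge 2.5$).  The
bands are configurable; the defaults make published pattern tables
qualitatively reproducible from their printed centroids.

## Validation

**MORI** (measure of relative improvement) asks how much better the
observed solution's QCs are than those obtained by clustering *random data
with the same correlation structure*.  The null generator draws
$x = A z$, $z \sim N(0, I)$, where $A$ is the varimax-rotated full
principal-component loading matrix of the observed variables
(`varimax_loadings()`; since all $p$ components are retained and the
rotation is orthogonal, $AA^\top$ reproduces the observed correlation
matrix exactly).  Each of `reps = 25` replicates (the conventional count)
is re-standardized and clustered with the *identical* configuration, and
each QC's null mean $\bar r$ is compared with the observed value on the
scale of the remaining headroom towards that QC's ideal value:

| QC | ideal | MORI |
|----|-------|------|
| EESS% | 100 | $(obs - \bar r)/(100 - \bar r)$ |
| mean silhouette | 1 | $(obs - \bar r)/(1 - \bar r)$ |
| HCmean | 0 | $(\bar r - obs)/\bar r$ |
| XBmod | 2 | $(obs - \bar r)/(2 - \bar r)$ |

The reference value 2 for XBmod is the expected ASED of independent
standardized cases.  These formulas are reconstructions around the idea of
"relative improvement over random-data clustering" with per-QC ideal
values; like `xbmod()` they live in one function and are documented as
provisional.  A QC whose null mean already sits at its ideal value has no
headroom and its MORI is reported as `NA` rather than a division by zero.
Per-replicate seeds are spawned from the master seed with one
`sample.int()` draw, so runs are bit-reproducible and replicates mutually
independent.  Calibration is tested both ways: data drawn from the null
generator itself produce $|MORI| \le 0.1$ for every defined QC at 25
repetitions, and a strongly separated planted 7-type structure produces
$MORI(EESS\%) > 0.5$.

**Centroid matching** (`centroid_match()`) computes the full
$k_a \times k_b$ ASED matrix between two solutions' centroids and, for
equal $k$, the one-to-one pairing minimizing total ASED.  The pairing is an
exact assignment solved by bitmask dynamic programming (practical to
$k = 20$; the supported model range tops out at 25 but published typology
work lives at $k \le 10$).  How "corresponding" pairs should be chosen is
not specified in the methodology we follow; optimal assignment is the
defensible canonical choice and is symmetric in the two solutions, which
the tests verify.

**Exacon-style CMR** (`exacon_cmr()`): for each cell of the two-partition
contingency table, the cell frequency divided by the harmonic mean of its
row and column totals, $CMR = n_{ab}(r_a + c_b)/(2 r_a c_b)$ — 1 for
perfectly corresponding clusters, 0 for disjoint ones.
`match_solutions()` glues the two: each matched centroid pair is annotated
with its ASED and its CMR.

## Preprocessing pipeline

`likert_items()` bundles an item matrix with a scale map and per-scale
missing-item allowances.  The pipeline mirrors standard practice for
right-skewed Likert scales:

1. `truncate_items()` fuses upper response categories (e.g. anxiety items
   capped at 3 fuse responses 3–5; avoidance items capped at 4 fuse 4–5) —
   the remedy for items whose smallest value is the modal response;
2. `build_scales()` averages the usable items, with the scale set missing
   when more items are missing than the scale's allowance (0 for a 4-item
   scale, 1 for a 6-item scale in the motivating design);
3. `complete_cases_on()` keeps cases complete on the analysis variables;
4. `nn_outliers()` flags cases whose mean ASED to their nearest
   neighbour(s) on the standardized variables exceeds τ = 0.7 — i.e. cases
   a third of the random-pair baseline of 2 away from *everyone*;
   `neighbours` defaults to 1 but is exposed because residual screens
   sometimes average several neighbours;
5. `reliability()` reports Cronbach's alpha (with Feldt's exact
   F-distribution interval) and McDonald's omega-total from a one-factor
   maximum-likelihood fit (with a seeded percentile-bootstrap interval).
   The published table this mirrors does not name its interval methods;
   Feldt and the percentile bootstrap are the standard choices.  A
   non-convergent factor fit degrades gracefully to alpha plus a warning
   record.  One analytic special case: an exactly singular all-duplicate
   item set cannot be fit by `factanal`, but its maximum-likelihood limit
   is $\lambda_j = 1$, $\theta_j = 0$, hence $\omega = 1$, which is what is
   returned.

## The synthetic typology generator

The motivating attachment dataset is available only on request, so the
package carries a seeded generator (`typology_spec()` /
`generate_typology()`) whose defaults emulate that study's published
structure: $n = 800$ cases on four scales, seven planted types whose
centroid signs follow the printed 7-cluster pattern table (band midpoints:
`(H)` → 0.35, `H` → 0.7, `H+` → 1.2, `H+++` → 2.2, `H++++` → 2.7, and the
mirrored negatives), mixing proportions following its printed cluster
sizes, and within-type standard deviation 0.5 — a moderately overlapping
regime in which k-means recovers the truth well but not perfectly, the
qualitative shape of the published result (mean matched CMR in the 0.8–0.9
band, EESS% in the mid-70s).

Optional controls emulate further features of the real data: `skew`
applies a monotone convex map $(e^{s z} - 1)/s$ per variable — with the
default centroids, strength ≈ 0.2 on the anxiety-like variables yields
marginal skewness in the 1.0–2.2 range reported for the real scales — and
`itemize_scales()` expands generated scale scores into noisy, clipped
Likert items so the preprocessing pipeline can be exercised end to end.

What the generator does *not* emulate: floor effects of bounded scales
(Gaussian types are unbounded below), item-level measurement error
correlated across scales, and any dependence of within-type spread on the
type mean.  Passing the planted-recovery tests therefore shows the
machinery is correct and calibrated, not that seven attachment types exist
in any real population.

## Numerical conventions and edge cases

* **Standard deviations** use the $n-1$ denominator everywhere.  This is
  not cosmetic: it makes the mean pairwise ASED of a standardized sample
  exactly 2 (asserted to 1e-9 in the tests), which in turn anchors HC's
  random baseline, the τ = 0.7 outlier threshold, and XBmod's reference
  value.
* **Engines.** Standard algorithms are delegated to the reference
  implementations a practitioner would use — `stats::hclust`,
  `cluster::agnes` (flexible beta, $\alpha_i = (1-\beta)/2$, $\gamma = 0$,
  default $\beta = -0.25$), `cluster::diana`, `stats::kmeans`,
  `cluster::pam`, `cluster::silhouette`, and the mclust EM engine for the
  fourteen-model grid — while everything methodological (QCs, MORI,
  matching, CMR, the generator, k-medians) is implemented here.  The test
  suite holds the delegated engines to independent brute-force oracles:
  single-linkage heights against Prim's MST, every DIANA split re-derived
  by the splinter rule, PAM against exhaustive medoid search, k-means
  best-of-starts against exhaustive 2-partitions, silhouette against an
  $O(n^2)$ double loop.
* **Ward** follows the ward.D convention on the supplied (intended squared
  Euclidean) distances.  Centroid/median linkage may produce height
  inversions; these are counted and reported on the fitted object, not
  treated as errors.  Tie-breaking among equal merge heights follows the
  engine's deterministic order; with continuous data ties have probability
  zero, and the permutation-invariance tests use continuous data for that
  reason.
* **Divisive trees** are re-expressed in the agglomerative merge-table
  form (split height = diameter of the divided cluster), so `cut_tree()`,
  exports and plotting are shared with `ahca()`.  Because DIANA always
  divides the largest-diameter cluster, cutting the merge table at the
  $k-1$ largest heights coincides with the first $k-1$ divisions.
* **k-center initialization** samples $k$ distinct cases uniformly under
  the run seed — matching the convention that iteration "starts with a
  random choice of cluster centers" — with k-means++ available behind a
  flag but off by default.  `n_starts` defaults to 10 for the stochastic
  families and 1 for PAM, whose BUILD phase is deterministic.  An empty
  cluster re-seeds at the case farthest from all current centers.
  Labels are canonicalized by first case appearance, so a fixed seed gives
  bit-identical partitions across runs and case-order permutations.
* **k-medians** alternates nearest-center assignment with within-cluster
  geometric medians computed by Weiszfeld iteration (tolerance 1e-8, max
  200 iterations), with the Vardi–Zhang subgradient correction when an
  iterate lands on a data point.  Well-separated planted structure needs
  more restarts than mildly overlapping structure; the tests use 20 starts
  where exact recovery of seven far-separated types is asserted.
* **Mixtures.** BIC is reported on the larger-is-better scale
  $2\ell - m\log n$; ICL $=$ BIC $- 2\sum_i\sum_c(-z_{ic}\log z_{ic})$, so
  ICL $\le$ BIC with equality exactly for 0/1 posteriors.  The
  free-parameter count $m$ is computed from the volume/shape/orientation
  decomposition and cross-checked against the engine's own count for all
  14 models.  Initialization uses the engine's deterministic model-based
  hierarchical agglomeration (the convention of the software family this
  package follows).  Estimation failures and covariance collapse mark the
  (model, k) cell non-converged — a gap in the BIC table, as in published
  BIC plots — rather than raising.  Classification ties break to the
  lowest cluster index; uncertainty $u_i = 1 - \max_c z_{ic} \in
  [0, 1 - 1/k]$.
* **Degenerate inputs** are rejected with specific messages: constant
  columns at standardization (named), missing values at any distance
  computation (with the instruction to run preprocessing first), $k$
  outside $2 \le k < n$, rank-deficient correlation matrices at the
  loading step, empty clusters in a CMR cross-tabulation.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
oracle checks at $n \le 30$, calibration and recovery checks at $n$ between
300 and 3000, the mixture model-selection check on ten seeded replicates of
a 900-case 3-component mixture over the full 14-model grid at $k = 2..4$,
and the end-to-end pipeline at the generator's default $n = 800$.  These
sizes were chosen to estimate each quantity with comfortable margin over
its assertion tolerance; all stochastic checks fix their seeds.

## Known limitations

* XBmod and the MORI denominators are documented reconstructions (see
  above), isolated behind single functions.
* `Hom20`-style worked examples recomputed from *rounded* printed HC values
  are not asserted, being rounding-sensitive at the strict threshold.
* The k-medians family is batch Weiszfeld; an online/recursive variant
  (averaged stochastic gradients) would scale better to very large n but
  is less reproducible.
* No CLARA-style subsampling for PAM at large n; no fuzzy clustering; no
  "clustering p-values" for mixtures (undefined in the methodology this
  package follows); dendrogram and banner data are exported for plotting
  rather than rendered.
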