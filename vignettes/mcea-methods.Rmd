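---
title: "Confidence-ellipse similarity analysis of weakly correlated data blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-ellipse similarity analysis of weakly correlated data blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcea)
```

## The problem

Two blocks of variables measured on the same samples — say, the climate
of many growing locations and the leaf chemistry of a crop harvested
there — can be related so weakly that every regression of one block on
the other explains almost none of the variance, yet the relationship is
real at a coarser level: locations that resemble each other climatically
also tend to resemble each other chemically.  `mcea` quantifies exactly
that kind of class-level association.  The approach: reduce each block
by PCA, describe every class (location) by a confidence ellipsoid in
score space, count how classes' samples fall into each other's
ellipsoids, and correlate the resulting similarity profiles across
blocks.

## The model, step by step

**Block partition.** The sample table is split into disjoint named
blocks of columns with roles *independent*, *dependent* and
*description*; one description column carries the class label that
partitions the $n$ samples into $|d|$ classes.  Disjointness and
coverage are enforced at construction ([`block_config()`],
[`block_collection()`]).

**Preprocessing** (fixed order, `preprocess()`): rows with any missing
value in an analysis column are deleted; box-plot (Tukey-fence) outlier
rows are removed in a single pass; every analysis column is z-scored.
Because PCA follows the z-scoring, each block's PCA is effectively on
the correlation scale.

**Per-block PCA** (`fit_pca()`): mean-centred SVD, $A = U D V'$, scores
$T = U D$, explained-variance fractions $d_j^2 / \sum d^2$.  The
retained dimension is chosen jointly (`select_k()`): each block needs
the smallest $k_i$ whose cumulative explained variance reaches the
threshold $\sigma$ (default 0.8), the global $k$ is $\max_i k_i$, and a
block of rank lower than $k$ extracts at its own rank.

**Confidence ellipsoids** (`fit_ellipsoid()`): for class $p$ with score
mean $\mu_p$ and covariance $S_p$, the region at level $\alpha$
(default 0.95) is
$$\Theta_p = \{x : (x-\mu_p)' S_p^{-1} (x-\mu_p) \le \chi^2_k(\alpha)\},$$
the set a $k$-variate Gaussian occupies with probability $\alpha$.  The
Gaussian quantile form is used rather than a minimum-volume ellipse
covering a fixed fraction of points: it is closed-form, deterministic,
and coincides with the covering ellipse asymptotically when the class
is approximately Gaussian — which is the working assumption of the
whole analysis.

**Similarity index** (`similarity_matrix()`): for classes $p, q$,
$$S(p,q) = \frac{\#\{x \in \text{class } p : x \in \Theta_p \cap \Theta_q\}}{n_p}.$$
The numerator counts class-$p$ samples inside *both* ellipsoids; the
denominator is class $p$'s size, which makes the index asymmetric.
$S(p,p)$ is the fraction of a class inside its own ellipsoid and
approaches $\alpha$ for Gaussian classes.

**Integration** (`integrate_blocks()`): for two blocks $a, b$ and each
class $p$, the Pearson correlation between the profiles
$S_a(p,\cdot)$ and $S_b(p,\cdot)$ over the other classes; summarised by
the minimum, mean and maximum across classes.  A high mean says the two
blocks group the locations consistently even if no sample-level
regression succeeds.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `sigma` | 0.8 | cumulative explained-variance threshold for retaining PCs (fraction, 0–1] |
| `level` | 0.95 | ellipsoid confidence level (probability) |
| `dims`  | 2 | score dimensions used by the ellipse analysis |
| `fence` | 1.5 | Tukey fence multiplier of the outlier filter |
| `exclude_self` | `TRUE` | drop $S(p,p)$ from profiles before correlating |
| `alpha` | 0.05 | F-to-enter significance level of stepwise regression |

`dims = 2` matches how score-space ellipse analyses are almost always
read (and plotted); any value up to the retained dimension is
supported.  The self entry $S(p,p)$ measures aggregation rather than
cross-class similarity, so it is excluded from profiles by default;
including it (`exclude_self = FALSE`) typically inflates all
integrated correlations because every diagonal is large in every block.

## Numerical choices

* **Quantiles** in the outlier filter use linear interpolation of order
  statistics (R's default type 7); the fences are recorded in the
  report so a run is reproducible from its artifacts.
* **Standard deviations** use the sample ($n-1$) denominator, making
  `c(1, 2, 3)` standardize to `c(-1, 0, 1)` exactly.
* **Sign convention**: each loading column's largest-magnitude element
  is made positive.  Ellipse results are invariant to loading signs;
  the convention only keeps plots stable across runs.
* **Scores are $UD$**, not $U$: covariance-based ellipsoids are
  invariant to this column scaling, so the choice affects only the
  axes of plots.
* **Ridge regularization**: a class covariance with condition number
  above $10^{10}$ receives $10^{-8}\,\mathrm{tr}(S)/k$ on the
  diagonal, so degenerate classes cannot crash the full
  $|d| \times |d|$ sweep; the flag is kept on the ellipsoid object.
* **Boundary points count as inside** ($\le$): a measure-zero choice
  fixed for determinism.
* **Classes with fewer than `dims + 2` samples** cannot support a
  covariance estimate and are dropped from rows *and* columns with a
  warning; they are listed in the result rather than imputed.
* **Ties in stepwise entry** are broken by column order; the entry path
  with each partial-F and critical value is reported.

## The synthetic generator

The real motivating data (171,516 field records from 35
counties/districts, with 14 climate, 4 altitude and 5 leaf-chemistry
variables) are not redistributable, so the package ships a generator
(`synth_config()`, `generate_blocks()`) that emulates their structure:
35 classes, blocks of 14/4/5 variables, per-class Gaussian clusters.

Between-class structure is deliberately **low-rank**: each class
carries a latent coordinate $u_b(c) \in \mathbb{R}^L$ per block
(default $L = 2$), class means are $u_b(c) A_b$ through a fixed
unit-column loading map, and coupling acts in latent space,
$$u_{\text{target}}(c) = \textstyle\sum_l \rho_l R_l u_{\text{source},l}(c)
  + \sqrt{1 - \sum_l \rho_l^2}\; \eta(c),$$
with $R_l$ a fixed random rotation.  Each $\rho_l$ is then exactly the
correlation between the source's and target's latent class structures.
The low rank matters: if class means were isotropic in all 14 (or 5)
dimensions, the two blocks' leading principal components would span
almost unrelated mean-structure directions and a 2-D ellipse analysis
could not see even a strong coupling.  Rank-2 means mimic what the
method assumes about real data — that a few latent environmental
gradients drive the between-location differences — and make the
leading PCs of every block recover the same structure.

Defaults: `between_sd = 1`, `within_sd = 1`, coupling 0.35 from each
independent block into the chemicals block.  The noise ratio was fixed
once so that ordinary regression of one chemical on all 18 independent
variables sits in the weak regime (leave-one-out $R^2 \approx$
0.1–0.2) at the default coupling — the regime the method is designed
for.  The generator does **not** attempt realistic climate units,
covariance structure between climate variables, seasonal effects, or
non-Gaussian within-class shapes; passing tests on it demonstrate the
machinery's statistical correctness, not field validity on any real
data set.

`inject_artifacts()` blanks random cells and plants rows far outside
the Tukey fences, returning the ground truth so the preprocessing chain
can be tested against known corruption.

## Baselines and problem sizes

The three conventional comparisons — forward stepwise with F-to-enter,
PLS1, and linear $\varepsilon$-insensitive SVR — are validated by
leave-one-out $R^2$ ($1 - SSE_{\text{pred}}/SST$).  Stepwise is
forward-only (no elimination phase).  For PLS the component count is
chosen by a LOO grid on the full data and held fixed across the outer
LOO splits; a fully nested grid would square the cost for a
second-order change in the estimate.  Baseline experiments in the test
suite run at $n = 700$ (35 classes × 20 samples) and the ellipse
analyses at $n = 3{,}500$ (35 × 100) — sizes at which every
distributional check has comfortable precision while the whole suite
stays quick on one core.

## Known limitations

* The ellipsoids assume approximate within-class Gaussianity; heavily
  skewed or multimodal classes make $S(p,p)$ drift from the nominal
  level.
* With small classes the covariance estimate is noisy and the $\chi^2$
  radius is only asymptotically calibrated; a Hotelling-$T^2$/F radius
  would be exact under Gaussianity and is a natural extension.
* The integrated correlation is reported without a significance test,
  and profiles with many exact zeros (well-separated classes) make it
  coarse; the class-separation dial of the generator shows both
  regimes.
* Whether outlier filtering should be global or within-class is
  context-dependent; the global default matches the package's
  preprocessing contract, and `per_class = TRUE` is available.
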