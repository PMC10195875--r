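---
title: "Assortative mixing in annotated connectomes: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assortative mixing in annotated connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotmix)
```

## The problem

Brain regions differ in their biology — gene expression, receptor
densities, laminar architecture, myelination — and a central question in
network neuroscience is whether regions with similar attributes are
preferentially wired to one another. The confound is geometry: nearby
regions tend both to share attributes (spatial autocorrelation) and to be
connected (distance-dependent wiring), so raw attribute assortativity is
inflated by spatial embedding alone. `annotmix` quantifies annotation
mixing on weighted networks and standardizes every statistic against
surrogate annotation maps that preserve the empirical map's spatial
autocorrelation, so that significance reflects wiring *beyond* geometry.

## The statistics

**Assortativity.** For adjacency $A = (a_{ij})$ with total ordered weight
$2m = \sum_{ij} a_{ij}$ and annotation $x$, the assortativity is

$$r_x = \sum_{ij} \frac{a_{ij}}{2m}\,\tilde x_i\,\tilde x_j,
\qquad
\tilde x_i = \frac{x_i - \bar{x}}{\sigma_x},$$

with strength-weighted moments $\bar x = \frac{1}{2m}\sum_i k_i x_i$ and
$\sigma_x^2 = \frac{1}{2m}\sum_i k_i (x_i-\bar x)^2$ ($k_i$ = node
strength). Equivalently, $r_x$ is the weighted Pearson correlation of the
edge-endpoint vectors $x^{(i)}, x^{(j)}$ with the connection weights as
weights; the package computes it by matrix contraction and its test suite
checks the equivalence against an independent edge-enumeration oracle to
1e-12. Note that $r_x$ is invariant under *any* affine transform of $x$
(both endpoints carry the sign), while the heterophilic coefficient below
flips sign when exactly one map is negated.

**Variants.** `rank_assortativity()` ranks the endpoint vectors separately
(average ranks for ties) before the weighted correlation — a weighted
Spearman correlation, invariant to monotone transforms.
`partial_assortativity()` regresses the target's endpoint vectors on a
covariate's by weighted least squares and correlates the residuals; the
default `"literal"` mode regresses both $y^{(i)}$ and $y^{(j)}$ on
$x^{(i)}$, which is how the method is usually written, and a `"symmetric"`
mode ($y^{(j)}$ on $x^{(j)}$) is exposed because the literal reading may
be a typo in the method's common description; the chosen mode is recorded
on the result. `heterophilic_assortativity()` generalizes to two maps,
$r_{x,y} = \sum_{ij}\frac{a_{ij}}{2m}\tilde x_i \tilde y_j$. For directed
graphs, endpoint-$i$ moments use out-strengths and endpoint-$j$ moments
in-strengths, with $2m$ the total arc weight — the natural directed
generalization, chosen here because the underlying equations are stated
only for the undirected case.

**Local measures.** The homophilic ratio of node $i$,

$$h_x(i) = \frac{\sum_j \frac{a_{ij}}{k_i}\,|x_i-x_j|}
                {\frac{1}{n}\sum_j |x_i-x_j|},$$

compares a node's weighted mean attribute difference with its neighbors to
its mean difference with all $n$ nodes; the denominator keeps the zero
self term and divides by $n$, exactly as the formula is typeset, which is
why a complete graph gives $h = n/(n-1)$ for every node and any
non-constant map. Values below 1 are assortative neighborhoods, above 1
disassortative. Undefined values (isolated nodes; nodes identical to all
others) are `NA`, never 0, and are excluded pairwise downstream. The mean
connection distance defaults to the global normalization
$MCD(i)=\frac{1}{2m}\sum_j d_{ij}a_{ij}$ (`as_printed`), even though the
verbal definition of the measure is the per-node weighted average
(`per_node`); both are first class because downstream nodal correlations
can differ between them.

## Null models

All inference compares an empirical statistic to the same statistic over
surrogate annotation maps; the graph is never randomized.

* **Spin nulls** (`spin_nulls()`): random 3-D rotations of parcel
  centroids on a sphere, mirrored onto the other hemisphere by the
  reflection `M Q M`, `M = diag(-1, 1, 1)` (so the anterior-posterior axis
  is preserved), with nearest-centroid reassignment. Surrogate values are
  a permutation-with-repetition of the empirical values, and one rotation
  serves all maps in a draw — spin ensembles are always *joint*, which is
  what `heterophilic_matrix()` requires (the null must preserve inter-map
  correlations).
* **Moran nulls** (`moran_nulls()`): the weight matrix is the inverse
  distance matrix; surrogates are built by random sign flips of the
  empirical map's loadings on the eigenvectors of the doubly centered
  weight matrix. The family of Moran spectral randomization schemes is
  broader; the sign-flip ("singleton") scheme was chosen because it makes
  the preservation contract exact: Moran's I under the same weight matrix,
  the mean, and the variance of every surrogate equal the empirical values
  to machine precision on a single spatial domain. With two hemispheres,
  generation is per hemisphere with a shared random stream, preserving
  homotopy; whole-map Moran's I is then preserved approximately (the
  cross-hemisphere terms are randomized), which is the documented
  tolerance behind the ±10% diagnostic in the acceptance suite.
* **Burt nulls** (`burt_nulls()`): permute, smooth, rescale:
  $y = |\beta|^{1/2} x' + |\alpha|^{1/2} z$ with $x'$ the smoothed
  permuted map and $z$ fresh Gaussian noise. $\alpha,\beta$ are fitted per
  draw by least squares between binned variograms (half mean squared
  difference per equal-count distance bin, capped at the 25th percentile
  of pairwise distances). A *scan* over smoothing neighbor fractions
  (`deltas = 0.1 … 0.9`, exponential kernel with bandwidth at the k-th
  neighbor) keeps the best-fitting candidate per draw: a fixed small
  fraction cannot reproduce long-range structure and was measured here to
  reject 94% of the time on unrelated autocorrelated maps, while the scan
  is well behaved. After the transform each surrogate is rescaled to the
  empirical mean and standard deviation (a linear map, so the variogram
  shape is preserved), making the moment contract exact. Homotopy is
  preserved by reusing the identical permutation and noise stream on
  equal-sized hemispheres.
* **Naive nulls** (`naive_nulls()`): uniform value permutation — the
  spatially ignorant reference whose inflated false-positive rate
  motivates everything above.

**Inference.** `z_score()` standardizes with the sample SD of the null
values; `perm_pvalue()` is two-sided with extremeness measured as absolute
deviation from the null mean (add-one corrected, so
$p \ge 1/(n_{nulls}+1)$); a tail-doubling alternative sits behind
`method = "doubled"`. Multiple testing uses the Benjamini–Yekutieli
step-up with the harmonic penalty $c(K)=\sum_k 1/k$, valid under arbitrary
dependence; FDR families are: annotations within a connectome for
`standardized_mixing()`, unique pairs for `heterophilic_matrix()`,
categories for `decode_categories()`. Surrogate draws on which a statistic
is undefined are dropped and counted; more than 1% drops aborts the
analysis. In `distance_threshold_profile()` the surrogate maps are *not*
regenerated per threshold — the nulls are annotations, and the graph is
the quantity being varied.

## Regression and communities

`wls_fit()` fits the edge-level model $y^{(j)} = b_0 + \sum_p b_p
x_p^{(i)}$ by weighted least squares with connection weights; predictors
are standardized with their edge-weighted moments by default so
coefficients are comparable across annotations (the raw scale is one flag
away; the underlying method description does not state a scaling).
For undirected graphs both orientations enter, which doubles rows but
leaves weighted estimates unchanged. `dominance()` decomposes the full
model's weighted $R^2$ into per-predictor total dominances (mean
incremental $R^2$ over all submodels, averaged within subset sizes);
conservation $\sum$ dominance $= R^2_{full}$ is enforced to 1e-8.

`modularity_q()` evaluates
$Q=\frac{1}{2m}\sum_{ij}[A_{ij}-\gamma\,s_i s_j/2m]\,\delta(c_i,c_j)$
exactly; `louvain()` delegates the greedy optimization to igraph's Louvain
implementation (with the resolution parameter) under a seeded vertex
permutation, then recomputes $Q$ with the package's own evaluator — the
two routes keep the quality contract independent of the optimizer.
Directed graphs are clustered on the symmetrized adjacency; a
$s^{out}_i s^{in}_j$ null-model option exists for directed $Q$ without any
claim that it matches other software. `consensus_partition()` thresholds
the co-assignment matrix at `tau` (default 0.5 — a value the method's
literature leaves open) and re-clusters until block-diagonal, with an
iteration cap of 50. `zrand()` implements the pair-counting z-score of the
Rand index with the permutation-null variance of Traud and colleagues'
formulation; under independent random partitions it is approximately
standard normal, which the acceptance suite verifies empirically.
`gamma_scan()` runs seeded restarts per resolution and returns consensus
partitions plus their z-Rand similarity matrix; *selecting* "the"
partition from a stretch of stable resolutions is deliberately left to the
user, because the selection criterion (high mutual similarity persisting
over a range) is qualitative.

## The synthetic world

The generators emulate the features of real annotated connectomes that
matter for this methodology, with defaults chosen once:

* **Geometry**: two mirror-symmetric spherical "hemispheres" (radius 50,
  centers ±60 on the left-right axis; Fibonacci lattice under a random
  rotation), or a 100-unit cube. Units are arbitrary but mm-like.
* **Network**: undirected, edge probability $\propto e^{-d/\lambda}$ with
  $\lambda = 30$ — roughly a third of the structure size, mimicking the
  strong exponential distance decay of cortico-cortical connectivity —
  rescaled to a target density of 0.1; weights decay mildly with distance
  with log-normal noise; connectedness is enforced by bridging the
  shortest inter-component gaps.
* **Annotations**: a smooth field built from the leading Moran
  eigenvectors of the inverse-distance matrix (top $\max(3, n/10)$,
  eigenvalue-proportional coefficients, i.e. a 1/f-like spatial spectrum)
  mixed with white noise as $x=(\alpha f + z)/\sqrt{\alpha^2+1}$; the
  default $\alpha = 3$ gives fields with Moran's I around 0.15 at
  $n = 200$ under the inverse-distance weight matrix. A note on
  calibration: the leading eigenvector of that weight matrix caps Moran's
  I near 0.39 for this geometry (≈0.28 for the cube), so any field mixing
  several eigenvectors lands near 0.15–0.3 — "large-I" fields above ~0.3
  are not expressible in this construction, and the generator's
  documented calibration asserts what the construction actually achieves
  (I > 0.15 at large $\alpha$, white-noise limit $-1/(n-1)$ at
  $\alpha = 0$). Hemispheric homotopy is emulated by mirroring the smooth
  component before adding independent noise.
* **Planted effects are topological**: degree-preserving double edge
  swaps (weights travel with edges) accepted only when they move endpoint
  similarity in the requested direction, until the assortativity has
  shifted by the requested amount. Because annotation values and node
  positions are untouched, the map's spatial autocorrelation is unchanged
  and spatial-null calibration remains meaningful — the planted signal
  lives in the wiring, which is exactly the alternative hypothesis the
  nulls are designed to detect. The long-range variant restricts swaps to
  edges above the median length, producing networks whose standardized
  assortativity falls as short connections are thresholded away. Binary
  degrees and edge counts are preserved exactly; strengths can drift
  because weights move with edges.

**What a green test establishes — and what it does not.** The synthetic
world reproduces distance-decay wiring, autocorrelated homotopic maps, and
plantable mixing structure. It does not reproduce the value distributions
of any particular empirical annotation, directed ordinal tract-tracing
weights, measurement noise structure, or parcellation artifacts. Green
calibration/power tests therefore validate the machinery on the stated
world, not any empirical claim about real connectomes.

## Measured behavior of the stated world

All numbers below are computed by the test suite and
`scripts/acceptance.R` at run time; none are asserted from outside
sources. On the fixed world (n = 200, density 0.1, α = 3), with two-sided
permutation tests at α = 0.05 on annotations unrelated to the wiring:
spin and Moran nulls reject at a few percent (within the 5% ± 3%
calibration band), the naive value-permutation null rejects essentially
always (mean z-assortativity near +17 — the inflation the spatial nulls
exist to remove), and the Burt model is *conservative* (below 2%): its
fitted noise admixture over-disperses the null distribution on these
fields. That conservativeness is reported as a red acceptance expectation
rather than hidden, since the calibration band is symmetric; the
anti-inflation claim itself holds for all three spatial nulls. Planted
assortative rewiring (shift 0.1) is detected with z > 2 in ≥ 90% of
seeds, and planted long-range disassortativity yields falling z-profiles
in ≥ 80%.

## Numerical and degenerate-input conventions

* Edge-distance percentiles use linear interpolation on the sorted
  unordered edge distances; removal is strict (`<`), so percentile 0 is
  the identity and ties at the cutoff survive.
* Constant annotations (zero strength-weighted variance) are errors, as
  are graphs with no edges; undefined per-node values are `NA` flags.
* Negative weights are rejected unless `allow_negative = TRUE`, in which
  case they enter the assortativity family as signed sums (the treatment
  of signed functional connectivity is not standardized in the
  literature; this choice is recorded here).
* Missing annotation entries propagate: statistics fail loudly until
  `drop_missing_nodes()` removes the nodes and their edges.
* All stochastic functions take a `seed` and restore the caller's RNG
  state; every generator is a pure function of its spec.

## Known limitations

* Spin nulls operate on parcel centroids, not vertex-resolution surfaces;
  duplicate assignments are permitted, as in the centroid-based variant
  they implement.
* The Moran scheme here is one member of the spectral-randomization
  family; its exactness claims are properties of this implementation, not
  of the family.
* Burt surrogates are conservative on very smooth fields (see above).
* Geodesic distances must be supplied by the user; the package computes
  Euclidean distances from coordinates only.
* The directed generalizations (moments, modularity null model) are
  reasonable conventions, stated and tested, but no claim is made that
  they match any particular prior software.
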