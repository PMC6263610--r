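---
title: "Facet-based leaf segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facet-based leaf segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaffacet)
```

## The segmentation model

`leaffacet` segments individual leaves from a dense, unorganized plant
point cloud in four stages. The guiding idea is *over-segment, then
merge*: instead of trying to delineate leaves directly in a 10⁴–10⁵ point
cloud, the cloud is first shattered into small, locally coplanar clusters
("facets"), and leaves are then assembled by merging facets. Merging
coarse structures is far more robust than clustering raw points, because
a facet carries an averaged geometry (a fitted plane and a center) that
individual noisy points do not.

The method assumes:

* leaves are locally smooth surfaces, well approximated by planes at the
  facet scale (1–5 cm);
* sampling is dense and roughly uniform (millimeter-scale spacing), so
  point counts can proxy for surface area and K-nearest neighborhoods are
  compact;
* distinct leaves are separated by gaps larger than the sampling spacing
  — except where they genuinely touch, which is the method's documented
  failure mode (see *Limitations*).

### Per-point features: iterative PCA

For each point $x_i$, the $K$ nearest neighbors (the point itself
included) are collected once. A plane through $x_i$ is estimated by
eigendecomposition of the centered neighborhood covariance
$C = \tfrac{1}{K} X X^{\mathsf T}$; the normal $n_i$ is the eigenvector
of the smallest eigenvalue $\lambda_3$, and the *smoothness*
$s_i = \lambda_2 / \lambda_3$ measures how plate-like the neighborhood is.
Neighbors whose point-to-plane distance
$d(i,j) = |n_i^{\mathsf T}(x_j - x_i)| / \lVert n_i \rVert$
exceeds $\sigma_1$ are removed, and the fit repeats on the surviving
inliers until the set stops changing. Because iterations only ever remove
points from a finite set, termination is guaranteed; the iteration cap
(default 50) exists purely as a guard against pathological floating-point
behavior, and is never reached on real fixtures. The iterative refit is
what lets a point that sits near a leaf boundary anchor its plane on *its
own* leaf: neighbors that leaked in from an adjacent surface fall outside
the $\sigma_1$ band after the first fit and are expelled.

### Facet over-segmentation

Points are visited in a random order fixed by `rng_seed`. For each
not-yet-used point, the unused point with the greatest smoothness in its
$K$-neighborhood becomes a seed — seeds sit on the flattest spots, so
their planes are trustworthy anchors. The seed's facet then absorbs every
unused point $x_k$ that passes all three coplanarity gates:

1. $\lVert x_k - x_{seed} \rVert \le r_1$ (locality),
2. $\angle(n_k, n_{seed}) \le \theta$ (consistent orientation),
3. $d(seed, k) \le \sigma_1$ (on the seed's plane).

A local K-means pass then regularizes the ragged boundaries this
one-shot growth leaves behind: each iteration, every point inside the
sphere of radius $r_2$ around a seed is claimed by the closest seed,
stragglers caught by no sphere go to their globally nearest seed, and
each seed moves to its members' mean. The refined facets partition the
cloud by construction.

### Facet region growing

Leaves are connected unions of coplanar facets. Starting from each unused
facet in ascending id order, a breadth-first search pops a facet $f_i$
and merges every unused facet $f_j$ that is (a) *adjacent* to $f_i$ —
their closest member points lie within `adjacency_eps` — and (b)
*coplanar* with it — the distance from $f_j$'s center to $f_i$'s fitted
plane is at most $\sigma_2$. Merged facets are enqueued, so the leaf
grows in waves. Structures that end up with fewer than `min_leaf_points`
points (stray facets on stems, petioles, or surviving noise) are moved to
an unassigned pool and reported, never silently dropped.

### Evaluation

Predicted segments are scored against per-point ground truth at the leaf
level. A real leaf is a **TP** when some segment covers strictly more
than 70% of its points; a segment under which two real leaves are each
majority-covered records one **FP** per merged pair (and credits neither
leaf); a leaf with more than 70% of its points in no segment is an
**FN**. Recall, precision and F-measure follow as
$TP/(TP+FN)$, $TP/(TP+FP)$ and $2TP/(2TP+FP+FN)$, reported as
percentages. Cover rate — the fraction of a leaf's points captured by
its best segment — uses point count as an area proxy, which is adequate
under the near-uniform sampling the method assumes.

## Parameters

| Parameter | Stage | Units | Default | Role |
|---|---|---|---|---|
| `z_min` | filter | m | 0.2 | ground cut; a scene property, always tune |
| `greenness` | filter | — | 0.1 | ExG = 2G−R−B threshold for vegetation |
| `radius` (r) | filter | m | 0.015 | radius-outlier search sphere |
| `min_neighbors` (n₁) | filter | count | 85 | minimum neighbors in the sphere |
| `k` | filter | count | 40 | statistical-filter neighborhood |
| `std_mult` (n₂) | filter | — | 1 | spacing bound μ + n₂σ |
| `K` | features | count | 20 | IPCA neighborhood; ~5% of a leaf's points |
| `sigma1` (σ₁) | features/overseg | m | 0.025 | point-to-plane inlier band |
| `r1` | overseg | m | 0.03 | coarse facet radius ≈ seed spacing |
| `theta` (θ) | overseg | deg | 23 | normal-angle gate |
| `r2` | overseg | m | 0.1 | local K-means search sphere (≥ r1) |
| `sigma2` (σ₂) | growing | m | 0.0055 | facet coplanarity gate |
| `adjacency_eps` | growing | m | auto | facet adjacency; 1.5× median NN spacing |
| `min_leaf_points` | growing | count | 50 | minimum size of a reported leaf |

The defaults are the dense small-curved-leaf regime; `pipeline_profile()`
ships it as `"epipremnum"` together with the two broad-leaf regimes
(`"monstera"`: no radius filter, `k = 25`, `n₂ = 0.1`, `K = 40`,
`σ₂ = 0.0025`; `"makoyana"`: no statistical filter, `n₁ = 50`, `K = 40`).
The distance thresholds scale with the scanner's point spacing (about
2 mm dense, 3–6 mm sparse, for the sensors these regimes target); the
count thresholds scale with per-leaf point counts (400–500). `K` is the
main granularity control: smaller `K` (with smaller `r1`) produces more,
smaller facets — necessary for small leaves, wasteful for large ones.
Facet granularity interacts with `σ₂`: smaller facets have closer
centers, so they merge more readily at a fixed `σ₂`; if you change the
granularity, retune `σ₂`.

`z_min` and the ExG threshold deserve a note: the cleaning recipe calls
for a ground cut and a greenness cut but fixes neither number, since both
depend on the scene's coordinate frame and color calibration. The package
exposes them as ordinary parameters with declared-convention defaults
(0.2 m, 0.1) chosen to fit the synthetic scenes; they are not
reconstructions of anything.

## The synthetic generator

`synthetic_canopy()` emulates the conditions the pipeline is designed
for: `n_leaves` bent elliptical patches (height field
$h = c\,(u^2+v^2)$, analytic normals returned for validating the feature
stage) sampled at ~2 mm spacing with ~450 points each, arranged in a ring
with a guaranteed surface gap (default 0.03 m); a jittered ground plane;
a pot cylinder; and sparse outliers placed at least 5 cm from the
structure and 3.5 cm from each other, so they are removable by a radius
filter exactly as intended. Setting `occlusion_fraction > 0` instead
places leaf pairs *coplanar and adjacent* (flat, same plane, ~1 mm edge
gap, with a few interpolation-blended boundary points tagged `"noise"`) —
the hard case where coplanarity-based merging must fail, generated
deliberately so tests can assert the failure rather than hide it.

What the generator does **not** emulate: realistic leaf shapes (lobes,
serration, petioles and stems), anisotropic sensor noise, depth-dependent
spacing, specular dropout, and partial self-occlusion from a single
viewpoint. Passing the synthetic suite therefore demonstrates the
pipeline's correctness and its behavior under controlled geometry — not
its end-to-end accuracy on scanned plants, which depends on scene
properties the generator idealizes.

## Numerical choices

* **Smoothness floor.** $s = \lambda_2/\lambda_3$ is undefined on an
  exact plane ($\lambda_3 = 0$); the package computes
  $\lambda_2 / \max(\lambda_3,\ 10^{-9}\lambda_1,\ \epsilon)$, so a
  noiseless plane scores as maximally smooth instead of dividing by zero.
* **Normal sign.** Eigenvectors are sign-ambiguous; every reported normal
  is canonicalized to $n_z \ge 0$ (ties: $n_y \ge 0$, then $n_x \ge 0$),
  and all angle tests use the acute angle $\arccos|n_a \cdot n_b|$, so no
  decision ever depends on the arbitrary sign.
* **Boundary conventions.** The radius filter counts a neighbor at
  exactly distance $r$ as inside (closed ball) and never counts the query
  point itself; the z cut keeps $z = z_{min}$; the coverage rules are
  strict (`> 70%`). All inequality comparisons on squared distances carry
  a $1+10^{-12}$ relative guard so exact geometric boundaries are not
  lost to float rounding.
* **K-means ties and stability.** Seeds are processed in ascending facet
  id with a `<=` update, so an exact tie goes to the later seed,
  deterministically. "Seeds stable" means a maximum displacement below
  $10^{-7}$ m. A seed that loses all members is dropped with a warning,
  not respawned.
* **Degenerate facets.** A facet with fewer than three members cannot fix
  a plane; its center-to-center distance is used in the coplanarity test
  and the result is flagged.
* **Determinism.** The only randomness in the whole pipeline is the
  point-visiting order of seed selection, driven by `rng_seed` (default
  0); two runs with the same inputs and seed are bit-identical.

## Open design points and how they were resolved

Several steps of the procedure are underdetermined by its description;
the package fixes one reading of each and documents it:

* **Removal uses the just-updated normal.** Within an IPCA iteration the
  plane is refit first and neighbors are tested against the *new* plane,
  matching the step order of the iteration as written. The query point is
  never removed — it anchors the plane even when re-centering moves the
  neighborhood mean off it.
* **Seed-anchored (non-chaining) growth.** Coarse facet growth compares
  every candidate to the *seed*, not to previously accepted members, so
  facets cannot snake along a curved surface past $r_1$.
* **Seed selection under exhaustion.** If the smoothest neighbor of the
  visited point is already used, the smoothest *unused* neighbor is
  taken, and in the worst case the point itself — guaranteeing progress.
  Points never captured by any facet become singleton facets, so the
  coarse stage always outputs a partition.
* **One-directional coplanarity.** Region growing tests $d(i,j)$ with
  $i$ the popped facet and $j$ the candidate, as the procedure states; a
  `symmetric = TRUE` option adds the reverse test. Consequently the
  result is starting-order dependent in general; it is provably
  order-invariant within components whose every adjacent pair passes the
  test, and the starting order (ascending facet id) is fixed for
  reproducibility.
* **Facet adjacency.** "Adjacent" is undefined at the facet level; the
  package uses minimum point-pair distance ≤ `adjacency_eps`, defaulting
  to 1.5× the median nearest-neighbor spacing so the criterion adapts to
  cloud density.
* **FP accounting.** The evaluation rules can in principle fire together
  on overlapping configurations; the package counts one FP per merged
  pair (a segment majority-covering $m \ge 2$ leaves yields $m-1$ FPs),
  merged leaves are not creditable through that segment, and a leaf can
  be TP only via a segment that is not merged. This reading reproduces
  the published count combinations on reconstructed toy labelings and is
  label-permutation invariant.

## Problem sizes

The test suite and acceptance script run entirely on generated data:
the end-to-end canopy is 8 leaves × ~450 points plus ground, pot and
outliers (~5,700 points, ~2,600 after cleaning); oracle-equivalence
checks use 500–1,000-point random clouds; the granularity sweep runs the
over-segmentation at $K \in \{20, 40, 100\}$ × $r_1 \in \{0.03, 0.05\}$
on the fixed canopy. These sizes exercise every code path at the
method's intended point density while keeping the whole suite fast; the
implementation's neighbor searches are exact (chunked brute force), so
complexity is $O(N^2)$ in cloud size and clouds much beyond 10⁵ points
would need a spatial index.

## Limitations

* Leaves that genuinely touch *and* lie in the same plane merge into one
  segment — by design the adjacency + coplanarity tests cannot separate
  them, and the evaluator scores each such pair as one FP. This is the
  documented failure mode; the synthetic hard-case generator produces it
  on demand.
* Stems and petioles are not modeled; their facets typically fail the
  size cut and land in the unassigned pool.
* The greenness filter presumes green foliage and RGB color; disable it
  for colorless clouds or non-green plants.
* Cover rate uses point counts, so strongly non-uniform sampling biases
  it toward densely scanned regions.
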