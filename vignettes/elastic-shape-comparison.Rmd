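---
title: "Elastic shape comparison of protein backbones: model and design notes"
author: "esaprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic shape comparison of protein backbones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esaprot)
```

## The model

A protein chain is represented as an open curve. Each residue contributes
one (or, for the full-backbone criterion, three) column(s) to a matrix
$P \in \mathbb{R}^{(3+k) \times n}$: the first three rows are atomic
coordinates in Å, the remaining $k$ rows are residue-level auxiliary
channels carried along as extra curve dimensions. The curve is
parameterized by normalized cumulative **spatial** arc length
$T \in [0,1]$ (auxiliary rows do not influence the parameterization) and
transformed to its square-root velocity function (SRVF)

$$ q(t) \;=\; \frac{\dot{P}(t)}{\sqrt{\lVert \dot{P}(t)\rVert}} . $$

Under the SRVF the elastic metric on curves — which charges both bending
and local stretching — becomes the ordinary $L^2$ metric. Translation
vanishes because only derivatives enter; overall scale is removed by
dividing each SRVF by its $L^2$ norm. Rotation and reparameterization are
then removed by explicit optimization:

1. **Rotation.** The proper rotation maximizing
   $\langle q_1, R\,q_2\rangle$ is the classical orthogonal-Procrustes
   solution: with the weighted spatial cross-covariance
   $A = Q_1 W Q_2^\top$ and SVD $A = U S V^\top$,
   $R = U\,\mathrm{diag}(1,1,\det(UV^\top))\,V^\top$. The determinant
   correction forbids improper rotations, so mirror images are *not*
   collapsed. Only the spatial block rotates; auxiliary rows are physically
   orientation-free and pass through an identity block.
2. **Reparameterization.** The monotone warp $\gamma$ minimizing
   $\int \lVert q_1(t) - \sqrt{\dot\gamma(t)}\, q_2(\gamma(t))\rVert^2 dt$
   is found by dynamic programming on the $n \times n$ grid graph of the
   common parameter grid: vertices are index pairs, edges are strictly
   increasing jumps of at most `window` steps in each direction, and an
   edge's weight is the exact elastic cost of linearly matching the two
   grid segments. Because the graph is a DAG with non-negative weights, a
   single topological-order pass attains the all-pairs-shortest-path
   optimum at $O(n^2 w^2)$ edge evaluations; the kernel is implemented in
   C++.

The dissimilarity reported is the geodesic distance on the unit sphere of
normalized SRVFs, $\theta = \arccos\langle q_1, q_2^{*}\rangle \in [0,\pi]$,
where $q_2^{*}$ is the rotated and warped second curve. $\theta = 0$ means
the two structures have identical shape modulo translation, scale, rotation
and reparameterization. By default rotation and matching each run once, in
that order; `max_iter > 1` alternates them until $\theta$ changes by less
than `tol`. A single pass is cheap and already exact for rigidly moved or
rescaled copies; alternation rarely changed $\theta$ appreciably on our
fixtures, so it is an opt-in refinement.

## Geometry criteria and auxiliary channels

Three geometric readings of a chain are supported: `ESA-BB` interleaves the
N, Cα, C backbone atoms (three points per residue, finest resolution and
cost), `ESA-CA` keeps the Cα trace, and `ESA-MC-BB` the unweighted centroid
of N, Cα, C per residue. For the two single-point-per-residue criteria the
backbone dihedral angles (φ, ψ, ω) are always appended as channels: they
recover, in compressed form, the local backbone geometry the single point
discards. Property channels (Kyte–Doolittle hydrophobicity, Grantham
polarity, monoisotopic residue mass, a 4-level functional-group class,
heavy side-chain atom count) can be added under any criterion and are
looked up per residue from an overridable table; under `ESA-BB` a residue's
value is repeated across its three atom columns. Glycine takes its table
values like any residue, with a side-chain count of 0 — no side-chain
geometry is used anywhere.

**Dihedral encoding.** An angle lives on a circle, and any single-number
encoding is discontinuous somewhere. The discontinuity of raw radians sits
at $\pm\pi$ — exactly the trans-peptide ω value — so two numerically
identical conformations can differ by $2\pi$ in a raw channel, which is
amplified catastrophically by standardization. The default therefore embeds
each angle as a $(\cos, \sin)$ pair, which is continuous, bounded and
invariant under rigid motion and scaling of the coordinates; undefined
angles (first/last residue, degenerate quadruples) map to $(0,0)$, the
circle centre. A `dihedral_encoding = "raw"` switch retains single
radians-per-π rows for users who want the smaller matrix. Degeneracy of a
torsion quadruple is judged *relative* to its bond lengths
($\lVert b_i \times b_j\rVert < 10^{-7}\,\lVert b_i\rVert\,\lVert b_j\rVert$),
so the defined/undefined decision is itself invariant to rigid motion and
scaling.

**Unit balancing.** Coordinates are in Å; properties are in Kyte–Doolittle
units, Da, or counts. Mixed unscaled, mass would dominate everything. Each
property row is standardized (mean 0, sd 1; a constant row — e.g.
hydrophobicity of poly-ALA — becomes 0, correctly carrying no shape
information) and multiplied by $w_c \cdot \texttt{aux\_scale} \cdot L / n$,
where $L$ is the total spatial arc length and $n$ the number of columns.
The factor $L$ makes the composite curve homogeneous under coordinate
scaling, which is what makes $\theta$ *exactly* scale invariant; the factor
$1/n$ keeps the channel's share of squared velocity roughly
$\texttt{aux\_scale}^2$ regardless of chain length, because a standardized
channel changes by $O(1)$ per grid step of width $1/n$. Dihedral rows are
already dimensionless in $[-1,1]$ and are given the same amplitude without
standardization (z-scoring a near-constant ω channel would amplify noise by
the reciprocal of its tiny sd). The default `aux_scale = 0.2` makes each
auxiliary channel a clearly subordinate perturbation of the geometry
(~4 % of the squared velocity norm); per-channel `weights` rescale
individual channels on top of this.

## Numerical choices

* **Derivative estimator**: three-point finite differences on the
  non-uniform grid (exact for quadratics), one-sided at the ends. This
  keeps $Q$ at $n$ columns. Zero-derivative columns map to zero columns.
* **Inner product**: trapezoidal cell weights from the grid,
  $\langle Q_1, Q_2\rangle = \sum_i \langle q_1(t_i), q_2(t_i)\rangle\,
  \Delta_i$ — a discrete $L^2$ product on $[0,1]$.
* **Grid merging**: sorted union with duplicates collapsed under
  $10^{-12}$; the merged length always lies in
  $[\max(n_1,n_2),\, n_1+n_2-2]$.
* **Zero-length segments** (duplicate atoms in PDB files) are dropped, with
  a log, before parameterization; a totally degenerate (zero-length) curve
  is an error.
* **Normalization order matters**: both SRVFs are normalized to unit norm
  on the common grid *before* rotation and matching. If norms are left
  unequal, the warp's $\sqrt{\dot\gamma}$ factor absorbs part of the norm
  mismatch and the matching degenerates into a scale-chasing distortion.
* **Clamping**: the final inner product is clamped to $[-1,1]$ before
  $\arccos$; excursions beyond $10^{-6}$ are logged as numerical warnings.
* **Edge-weight quadrature**: segment costs integrate by the trapezoid rule
  on the union of the segment's grid points and the warp preimages of the
  target segment's grid points, making costs exactly reproducible by hand
  on toy cases.
* The default DP jump `window` is 5 grid steps per move: wide enough to
  skip small insertions, narrow enough to forbid pathological warps;
  it is a tunable.

## Asymmetry

The warp is applied to the second curve only, so $\theta(A,B)$ and
$\theta(B,A)$ differ slightly (the continuum problem is symmetric; the
discrete one is not). On related shapes the difference is below 0.02 rad;
on very distant pairs we observed up to ~0.05 rad. `esa_distance_matrix()`
can average both directions (`both_directions = TRUE`); the default runs
one direction per pair for speed and mirrors it.

## The synthetic generator

`make_chain()` builds stylized backbones: helices with Cα on a cylinder of
radius 2.3 Å, rise 1.5 Å and 100°/residue; strands with 3.5 Å axial spacing
and a ±1 Å zigzag; smoothed random-walk coils with 3.8 Å steps. N and C are
placed ±0.75 Å along the local tangent from each Cα, Gaussian noise is
added per coordinate, and everything is deterministic given the seed. This
emulates what the algorithm actually consumes — coordinates at realistic
spacing plus residue identities — and deliberately not more: within-residue
backbone triples are collinear (so φ/ψ are degenerate on fixtures, logged
and encoded as the undefined sentinel; on real PDB input they are
well-defined), there are no side-chain atoms, and the geometry is not
Ramachandran-accurate. Passing tests on these fixtures therefore
demonstrates the transform, alignment, invariance and clustering machinery,
not biological realism of any particular scale choice.

Test and benchmark sizes were chosen to keep the whole suite interactive:
chains of 20–60 residues for invariance properties, grids of ≤ 7 points for
exhaustive path enumeration against the DP, a 2-family × 5-variant dataset
(40 residues, σ ∈ {0.05, 0.5, 2} Å) for the clustering harness, and one
300-residue pair as a scale check (a few seconds in the C++ kernel).

## Evaluation harness

The clustering evaluation is deliberately off-the-shelf: classical MDS to
$\min(N-1, 10)$ dimensions feeds `stats::kmeans` and `e1071::cmeans`;
spectral k-means builds the sigmoid affinity $s = 2/(1+e^{\alpha\theta})$,
normalizes its Laplacian and k-means the leading eigenvector rows. Clusters
are mapped to classes by maximum-agreement assignment (exhaustive over
permutations for ≤ 8 classes, hence exact there) before the confusion
matrix is formed — without a principled mapping, per-class precision and
recall would be ill-defined. Two overall Rand-index readings are reported
side by side: the accuracy form $\sum_i M_{ii} / \sum_{ij} M_{ij}$ and the
standard pair-counting Rand index; they answer slightly different questions
and coincide only in the perfect case.

## Known limitations

* Global alignment only: no partial, local or non-sequential matching, and
  no multiple (> 2) structure alignment.
* The DP warp granularity is the merged grid; warps needing jumps longer
  than `window` grid steps are unreachable.
* θ is not exactly symmetric (see above) and the triangle inequality is
  not enforced by construction.
* PDB parsing covers `ATOM` records of standard single-conformer use
  (highest-occupancy altLoc retained); mmCIF, assemblies and symmetry
  operations are out of scope.
* Chain breaks are warned about but the curve runs continuously through
  them, which charges the gap as stretch rather than treating it as a
  discontinuity.
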