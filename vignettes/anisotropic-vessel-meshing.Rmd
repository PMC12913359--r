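---
title: "Anisotropic image-to-mesh conversion for vascular geometries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic image-to-mesh conversion for vascular geometries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vesselmesh` converts a segmented 3-D image of a blood vessel into a
tetrahedral mesh whose element sizes and orientations follow a
prescribed metric tensor field. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the numerical
choices made where the design was open, and what the synthetic phantom
does and does not establish about behavior on clinical images.

## The metric-based model of a "good" mesh

All sizing decisions are expressed through a field of symmetric
positive-definite (SPD) 3×3 tensors $M(x)$ (units mm$^{-2}$). An edge
with vector $v_e$ has metric length $L = \sqrt{v_e^\top M v_e}$, and the
goal of adaptation is a *unit grid*: every edge at metric length 1,
every element metric-equilateral. Two scalar diagnostics quantify the
distance from that ideal:

* the **metric edge length** of an edge with endpoint lengths
  $L_a = (v_e^\top M_a v_e)^{1/2}$ and $L_b$:
  $$L_e = \frac{L_a - L_b}{\log(L_a / L_b)} \quad \text{if } |L_a - L_b| > 0.001,
  \qquad L_e = \tfrac12 (L_a + L_b) \text{ otherwise,}$$
  the logarithmic mean accounting for the metric varying along the edge
  (the two branches agree to first order at $L_a = L_b$; the switch at
  $10^{-3}$ is continuous to about one part in $10^3$, which the test
  suite verifies numerically);
* the **mean-ratio shape quality** of tet $k$ with volume $|k|$ and
  the vertex-tensor average $M_\text{mean}$ (the interpolated tensor at
  the element centroid):
  $$Q_k = \frac{36}{3^{1/3}}
  \frac{\left(|k| \sqrt{\det M_\text{mean}}\right)^{2/3}}
       {\sum_{e} v_e^\top M_\text{mean} v_e} \in [0, 1],$$
  normalized so the metric-equilateral element scores exactly 1;
  degenerate elements score 0.

The **complexity** of a field, $C(M) = \sum_i \sqrt{\det M_i}\, V_i$,
uses the dual volume $V_i$ of each vertex. The construction of the dual
is a design choice here: we use the *barycentric* dual ($1/4$ of each
incident tet's volume) because it makes $\sum_i V_i$ equal the mesh
volume exactly, which in turn makes the discrete complexity of the
identity metric exactly the domain volume — an anchor the tests rely
on. $C$ is proportional to the number of elements a conforming mesh
needs, and multiplying every tensor by $(C_r / C)^{2/3}$ retargets the
field to complexity $C_r$ exactly (determinants scale by the cube of the
factor; the rescaling is exact to rounding, not approximate).

## Building anisotropic fields

**Centerline ellipsoids.** For each mesh vertex we compute the
minimum-volume enclosing ellipsoid (MVEE) of the vertex together with
its $k$ nearest centerline points ($k = 8$ by default) by Khachiyan's
dual-update iteration (tolerance $10^{-7}$ on the dual optimality gap,
cover enforced exactly afterwards). The ellipsoid's shape matrix *is*
the tensor: its half-axes map directly to allowed edge lengths, so a
vertex surrounded by collinear centerline points gets a needle-shaped
ellipsoid — long along the vessel, thin across it. Affinely degenerate
point sets are regularized by flooring the half-axes at
$\varepsilon_\text{reg} = 10^{-6}\times$ the bounding-box diagonal.
Eigenvalues are then clamped into $[1/h_\max^2, 1/h_\min^2]$. The
map from ellipsoid to metric magnitude is exposed as a scalar `alpha`
(default 1) since no canonical scaling exists; the complexity rescaling
step makes the absolute magnitude immaterial in the pipeline.

**Velocity gradients.** With streamline samples $(x_j, u_j)$, each
vertex takes its 3 nearest samples, forms the ridge-regularized
least-squares velocity gradient $G$ from the centered positions and
velocities (3 samples underdetermine a 3×3 gradient, hence the ridge,
$\lambda = 10^{-8}$ at position scale — a documented completion), and
uses $\lambda_\max$, the largest absolute eigenvalue of the symmetric
part of $G$, as the local shear rate. The tensor allows edge length
$h_0 s$ along the mean flow direction and $h_0$ transversally, with the
stretching factor $s = \min(1 + c\,\lambda_\max / \lambda_\text{ref},
s_\max)$, $\lambda_\text{ref}$ defaulting to the median shear over all
vertices. Vertices with zero mean velocity (stagnant regions) fall back
to the isotropic tensor $(1/h_0^2) I$.

**Parameters that matter.** `h_min` (mm) bounds the smallest allowed
edge and defaults to the image spacing: the image cannot localize a
boundary below one voxel, so demanding sub-voxel elements buys no
fidelity and inflates the element count. `h_max` (8 mm default) bounds
coarseness. `k` (8) trades locality against stability of the ellipsoids.
The adaptation band $[L_\min, L_\max] = [1/\sqrt2, \sqrt2]$ is the
standard symmetric band around the unit-length ideal: splitting a
length-$\sqrt2$ edge produces two legal length-$\tfrac{1}{\sqrt2}$
edges.

## The BCC stage and surface snapping

The body-centered-cubic lattice places nodes at cell corners and
centers and builds four congruent tetrahedra per interior cube face;
every dihedral angle is 60° or 90°, which is why the BCC tessellation is
the canonical high-quality starting point. Tets are kept when their
centroid samples the selected label (a majority-of-samples variant is
deliberately omitted as it did not change phantom results at the cell
sizes used). Fidelity is then recovered by moving boundary vertices
down the gradient of the signed Euclidean distance field of the label
(exact distance transform on the grid, trilinear interpolation off it),
a fraction `snap_step = 0.5` of the local distance per iteration for up
to 20 iterations. A move is rejected if an incident element would
invert or its identity-metric mean ratio would fall below
`min_quality_accept = 0.1`; the result is watertight but only $C^0$ —
sharp creases may remain. This gradient-descent snap is a simplified
stand-in for finite-element mesh deformation: it keeps the same
contract (fidelity improves, quality guarded, interior untouched) with
far less machinery.

Voxel-derived shapes can contain *pinched* boundary edges (an edge
shared by four boundary faces where two parts of the surface touch).
The validator therefore defines "boundary closed" as every boundary
edge bounding an even number ≥ 2 of boundary faces; strict 2-manifold
checks would reject legitimate thin geometries.

## Two-phase adaptation

The mesh-adaptation (MA) phase interleaves, per iteration: one
*bisection sweep* (a maximal tet-disjoint set of edges with $L_e >
L_\max$, processed in descending length, split at their geometric
midpoints, the new vertex receiving the average of the endpoint
tensors), an *edge-collapse* pass (ascending length, merging the
interior endpoint, guarded by the vertex link condition, inversion
checks, duplicate-tet checks and a local quality tolerance `q_accept`),
a *local reconnection* pass, and a *smoothing* pass. One sweep per
iteration — rather than refining to exhaustion — is essential in
strongly anisotropic metrics: pure midpoint bisection creates new edges
that inherit neighbor lengths and does not converge on its own; the
interleaved flips and collapses are what let the process settle near
the complexity-predicted element count. MA stops when an iteration
inserts fewer than `point_tol` (1%) of the vertex count, or after
`max_ma_iters` (15; sized for single-sweep iterations).

The quality-improvement (QI) phase repeats reconnection and smoothing
until the mean $Q_k$ improves by less than `qi_tol` ($10^{-3}$) or
`max_qi_iters` (10). Flips are 2-3 (face flip) and 3-2 (edge flip
around a 3-tet interior edge); richer 4-4/edge-removal operations are
out of scope. A flip is applied only if the minimum $Q_k$ over the
replaced set increases by more than `q_accept` ($10^{-4}$ — a strict
margin that prevents flip cycling) and no element inverts. Smoothing
proposes each interior vertex at the metric-length-weighted average of
its edge neighbors and keeps the move only if the star's minimum
quality does not decrease.

**Change tracking.** The optimized reconnection mode keeps, per
element, an attempted flag and the mesh version at the last attempt.
Every modification — flip, split, collapse, vertex move — bumps the
version of all elements incident to the touched vertices. An element is
skipped when it was attempted, no speculative lock failure is recorded,
and neither it nor any face neighbor has a newer version than its
stamp. Because a 3-tet edge ring is mutually face-adjacent, face
neighbors cover all flip dependencies, so with one worker the optimized
and naive modes produce *identical* meshes; the saving is in attempts,
not in outcome. `lock_failed` only arises under concurrent execution
through the scheduler's speculative cavity locks.

The boundary surface is frozen throughout (`freeze_surface = TRUE`):
boundary edges are never split or collapsed and boundary vertices never
move, so the snapped surface survives bit-identically.

## Scheduling model

Tetrahedra are chunked into contiguous buckets of 256 (a value chosen to
give phantom-scale meshes tens of buckets per worker; configurable)
dealt round-robin to workers. A busy worker donates
$\lceil \text{fraction} \times |\text{queue}| \rceil$ buckets (fraction
0.5, FIFO idle list — both unstated upstream and therefore explicit,
configurable choices here) to either the first idle worker (original
policy) or the idle worker at the smallest memory-node distance
(hierarchical policy), ties keeping the earliest idle entry so the two
policies coincide on uniform-distance topologies. Workers are portable
execution lanes; CPU pinning and memory-node system calls are out of
scope, and topologies are supplied as matrices. The deterministic
simulator shows the hierarchical policy reduces the total donation
distance *on average* over skewed workloads (mean ratio ≈ 0.8 on a
2-node topology) — not on every trace, since the greedy per-donation
argmin is not globally optimal; the per-choice argmin property itself is
exact and is tested against brute force.

## The phantom, and what passing tests show

`make_vessel_image` voxelizes a tube of radius 4 mm around an analytic
cubic centerline (40 mm long, straight by default) with a 6 mm saccular
bulge attached at mid-length, at 1 mm spacing — dimensions in the range
of cerebral arteries and saccular aneurysms. `make_streamlines` samples
uniform interior positions with a Poiseuille profile
$u(\rho) = u_\max (1 - \rho^2/r^2)$ ($u_\max = 500$ mm/s, a typical
systolic peak) along the local tangent, stagnant in the bulge except an
optional recirculation fraction, with optional Gaussian velocity noise
(default 0). Everything is seeded and regeneration is bit-identical.

The phantom emulates the *geometry and sampling structure* of a
clinical case: a curved tubular label, a medial axis, velocity samples.
It does not emulate segmentation noise, topology defects, multi-vessel
branching, or realistic recirculating flow. Tests passing on the
phantom therefore establish the correctness of the algorithms and their
invariants (validity, conservation, determinism, scaling behavior), not
clinical-grade fidelity numbers; the Hausdorff values reported by the
acceptance script are phantom-specific.

Problem sizes used by the test suite and the acceptance script: the
adaptation study runs at target complexity 1750 (≈ 20,000 tets after
adaptation, from the measured ≈ 11 tets per unit complexity of this
pipeline on the phantom) and doubles it to check the linear
complexity-to-element-count relationship; quality checks on canonical
tets, MVEE oracles, the 1,000-topology scheduler comparison, and the
200-point exact Hausdorff oracle complete the set.

## Numerical choices and degenerate inputs

* Tensors are stored packed (xx, xy, xz, yy, yz, zz); all per-element
  kernels (volumes, qualities, edge lengths, flips, smoothing, distance
  transforms, Hausdorff) are compiled C++.
* Face keys are sorted vertex triples and edge keys sorted pairs, making
  adjacency and all pass orderings deterministic; with a fixed seed a
  single-worker run is bit-reproducible.
* Zero-volume tets score $Q_k = 0$; a tet whose four vertices coincide
  (all edges null) is an error.
* Tensor interpolation is the arithmetic mean (SPD by convexity);
  log-Euclidean interpolation exists behind a flag but is never the
  default.
* Collapse rejects any edge whose removal would break the vertex link
  condition or duplicate an element — the conformity guarantee does not
  rely on post-hoc repair.
* MVEE on fewer than 4 affinely independent points returns the
  regularized thin ellipsoid rather than failing.

## Known limitations

* Midpoint insertion (not metric-geodesic placement) and the 2-3/3-2
  flip set limit how closely extreme anisotropies (beyond ~10:1) can be
  matched; the residual shows up as edges below the unit band that
  cannot be collapsed without quality loss.
* The frozen surface means surface-dominated metrics adapt only the
  interior; long boundary edges simply persist.
* Multi-label images are meshed one label at a time; conformal
  multi-material interfaces are not supported.
* The scheduler models donation cost, not cache behavior; its
  distance proxy is a qualitative, not quantitative, stand-in for
  remote-memory-access counts.
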