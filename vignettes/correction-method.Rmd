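---
title: "Deformation-based correction of 3D segmentations: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-based correction of 3D segmentations: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmffd)
```

## The problem

Automatic segmentation of anatomy from 3D images (MR, CT) is rarely perfect:
model-based segmenters typically deliver surfaces in the Dice 0.8 range that
a human then corrects slice by slice. Painting voxels with a brush is slow
because every slice must be touched. `dmffd` implements the alternative this
package is built around: treat the correction as a *shape deformation*
problem. The segmentation surface is embedded in a coarse control lattice;
one drag of a 2D contour on one slice becomes a single 3D vertex constraint,
and solving an inverse deformation problem turns it into a smooth 3D
correction that also fixes the neighbouring slices.

## Forward model: trivariate Bernstein free-form deformation

A control grid is a parallelepiped with origin $X_0$ and edge vectors
$S, T, U$, carrying $(l{+}1)(m{+}1)(n{+}1)$ control points
$P_{ijk} = X_0 + \tfrac{i}{l}S + \tfrac{j}{m}T + \tfrac{k}{n}U$. A mesh
vertex $x$ has local coordinates $(s,t,u)$ solving
$x = X_0 + sS + tT + uU$ (an exact $3\times3$ linear solve, valid for any
non-degenerate, possibly sheared frame). Its deformed position is the
Bernstein tensor-product blend

$$
x_{\mathrm{ffd}} \;=\; \sum_{i=0}^{l}\sum_{j=0}^{m}\sum_{k=0}^{n}
\binom{l}{i}(1-s)^{l-i}s^i \,
\binom{m}{j}(1-t)^{m-j}t^j \,
\binom{n}{k}(1-u)^{n-k}u^k \,\bigl(P_{ijk} + \Delta P_{ijk}\bigr),
$$

where $\Delta P_{ijk}$ are control-point displacements. The weights form a
partition of unity, and Bernstein polynomials reproduce affine functions,
so the undisplaced lattice is the identity and a constant $\Delta P$ is an
exact translation; both facts are asserted to near machine precision in the
test suite. Internally the update is evaluated in the equivalent
displacement form $x_{\mathrm{ffd}} = x + W\,\Delta P$, which leaves
vertices bit-identical when no displacement acts — important because the
local-grid contract below is *bitwise*.

## Inverse model: direct manipulation

Users do not think in control points. A drag gives the desired displacement
$\Delta X$ of one surface vertex; the row vector $B$ of that vertex's
Bernstein weights links the two: $B\,\Delta P = \Delta X$. The package
solves this underdetermined system in the minimum-norm least-squares sense
(Moore–Penrose pseudoinverse), independently per spatial component. For a
single constraint the closed form
$\Delta P_{ijk} = w_{ijk}\,\Delta X / \sum w^2$ holds and the dragged
vertex reaches its target exactly; multi-constraint systems are solved with
the pseudoinverse and verified in tests against an independent
KKT (Lagrange) quadratic-minimization oracle. No additional regularization
is applied: minimum norm keeps each drag parameter-free, which is the
design point of the interaction model — the tool exposes no solver knobs.

One caveat the implementation documents deliberately: the displacement of a
*non*-dragged vertex is $|\Delta X| \, (w_x \cdot w_c)/\lVert w_c\rVert^2$,
bounded by $|\Delta X|\,\lVert w_x\rVert/\lVert w_c\rVert$. This can
slightly exceed $|\Delta X|$ when another vertex sits closer to a lattice
corner than the dragged one (ratios around 1.01 in practice). The suite
asserts the correct bound and the strictly smaller antipodal displacement,
not the folk claim that the dragged vertex always moves farthest.

## Global and local grids

* **Global grid**: axis-aligned box around the mesh, expanded by a padding
  fraction (default 0.05 of each extent per side). Padding keeps boundary
  vertices strictly inside the lattice: a vertex exactly at $s=0$ receives
  deformation only from face control points, and outward drags need room.
* **Local grid**: same degrees — hence the same control-point count and
  per-drag cost — but re-sized and re-centred on a region of interest.
  Vertices outside the local parallelepiped are excluded from embedding and
  returned bitwise unchanged (not clamped): the point of local mode is to
  protect regions that are already correct. Resolution concentrates where
  the lattice shrinks.

Default degrees are $(5,5,5)$, i.e. 216 control points, the configuration
whose per-drag cost is small enough for interactive use; degrees are
configurable. Grids are axis-aligned in world coordinates; sheared frames
are supported by the core (and tested) but not exposed on the command line.

Each drag is *stateless*: the current mesh is re-embedded in a fresh
zero-displacement grid, the solve fills $\Delta P$, the mesh is deformed,
and the displacements are discarded. Accumulating $\Delta P$ across drags
would make later drags act through stale embeddings of a surface that no
longer exists.

## From a 2D drag to a 3D constraint

Contours are plane–mesh intersections: every triangle crossing the slice
plane contributes a segment by linear interpolation along its two crossing
edges, and segments are chained into polylines via shared mesh edges
(endpoints merged within $10^{-6}$ mm). A watertight mesh yields only
closed polylines. Canonical planes (axial/coronal/sagittal) use the two
remaining world axes, in $(x,y,z)$ order, as the in-plane basis, so 2D
coordinates are plain world coordinates along those axes; arbitrary planes
get a deterministic orthonormal basis built from the normal (smallest
component axis crossed with the normal). Both bases are isometric, so drag
lengths are preserved and the lifted displacement lies exactly in the
plane.

The drag constrains the mesh *vertex* nearest to the contour point nearest
the cursor (ties to the lowest index), not an interpolated edge point: the
constraint row is then exactly the Bernstein weight row of an existing
embedded vertex. The alternative — constraining the interpolated contour
point itself — would need virtual vertices with composite weight rows; it
is noted here as the rejected option.

## Voxel conventions, rasterization, iso-surfacing

Voxel $(i,j,k)$ (0-based) has its *center* at
`origin + c(i,j,k) * spacing`; orientation is identity only, and volumes
with any other orientation are rejected at load time rather than silently
reinterpreted. Rasterization marks a voxel foreground iff its center is
inside the closed surface, decided by ray-crossing parity along $+z$
columns; rays carry a fixed sub-voxel offset so they never pass through
mesh vertices or edges, which keeps the parity test exact and the result
deterministic and translation-consistent. Non-watertight meshes are
rejected with the boundary-edge count.

Label volumes are surfaced by marching tetrahedra (each cell split into the
six Kuhn tetrahedra, level 0.5), which is crack-free across cells and
therefore watertight by construction; the volume is zero-padded so objects
touching the border still close. On binary data every surface vertex is a
grid-edge midpoint, so the surface sits within half a voxel of the true
boundary everywhere.

## Evaluation metrics

* **Dice** $2|A\cap B|/(|A|+|B|)$ on voxel counts, requiring identical
  grids (shape, spacing, origin) — mismatches are errors, never silent
  resampling. Two empty masks score 1 by convention; meshes are compared by
  rasterizing both onto a caller-supplied geometry, never a hidden default.
* **Hausdorff**: symmetric, surface-based — point samples on one mesh (all
  vertices plus up to 1000 area-uniform face samples, seeded) against the
  *exact* nearest point on the other mesh's triangles, accelerated by an
  exact nearest-vertex pruning bound. A mask-based surface-voxel variant is
  provided as a cross-check. Surface-based is the tighter, mesh-native
  choice; the voxel variant quantizes at the spacing scale.

## The synthetic-data generator

Fixtures emulate what a model-based segmenter hands to a human corrector:

* **ground truth**: an ellipsoid, rasterized analytically (voxel-center
  test) and meshed as a subdivided icosphere (level 4, 2562 vertices — a
  typical interactive surface resolution);
* **initial segmentation**: the ground-truth mesh systematically degraded —
  `global_scale` (uniform over/under-segmentation), `smooth_bump`
  (a cosine-windowed radial bump at a seeded direction: a localized error),
  or `random_ffd` (seeded jitter of a degree-2 lattice: smooth spatially
  correlated error). Magnitude guards reject perturbations that could
  self-intersect a star-shaped surface.

The default study case is a 16 mm sphere in a $64^3$, 0.8 mm isotropic
volume, inflated by 10%: the nested-ball closed form gives an initial Dice
of $2/(1+1.1^3) \approx 0.859$, the quality regime where interactive
correction is worthwhile. All fixtures are bitwise reproducible from their
spec and seed.

What the generator does **not** emulate: image intensities (the method
never reads them — only geometry matters), anisotropic spacing in the
default case, true anatomical shape complexity (muscle attachments, thin
bone ridges), or human error in locating the worst slice. Passing tests
therefore demonstrate the correctness and convergence of the machinery on
smooth and locally-perturbed geometry, not clinical performance.

## The scripted user

A deterministic stand-in for the human protocol: scan a fixed
axis-interleaved set of slices (every 8th slice per axis by default);
on each, extract current and ground-truth contours; pick the contour point
with the largest in-plane error; drag it to its nearest ground-truth
contour point; stop at a Dice target (default 0.95), an interaction cap
(default 150), or when the largest remaining error drops below 0.1 mm.
One drag per interaction, largest error first — a pragmatic user, not an
optimal one. A drag that lowers Dice is kept but flagged, as a human would
sometimes overshoot. In local mode the grid is centred on the drag point
and sized at $3\times$ the local error per axis, floored at 4 voxels — a
deterministic replacement for the human's manual box.

Two behaviours worth knowing, both exercised by the tests: on a localized
bump, the *global* grid policy spreads every correction over the whole
surface and can cycle without converging, while the *local* policy fixes
the bump in a handful of drags and leaves the far hemisphere bitwise
untouched — this asymmetry is precisely why the local mode exists. And the
greedy single-vertex policy optimizes overlap, not worst-case error: Dice
rises monotonically in aggregate while the Hausdorff distance can grow
slightly from residual local spikes the drags leave behind.

## Numerical choices

| choice | value | why |
|---|---|---|
| embedding inside-test slack | $10^{-9}$ | absorb float jitter at lattice faces |
| segment linking tolerance | $10^{-6}$ mm | merge interpolated endpoints |
| on-plane vertex nudge | $10^{-9}$ mm | make all plane crossings transversal |
| rasterization ray offset | fixed, $\sim0.03$ voxel | avoid vertex/edge hits, stay deterministic |
| pseudoinverse | `MASS::ginv` / closed form | minimum-norm; single-constraint exact |
| degenerate inputs | errors, not guesses | zero-extent meshes, singular frames, mixed mask grids, open surfaces all raise |

## Problem sizes and runtime envelope

The shipped configuration uses 2562-vertex meshes, 216 control points and
$64^3$ volumes: one drag (embed, solve, deform, re-contour, re-rasterize,
Dice) costs well under a second in pure R, and a full scripted correction
of the default fixture runs in a few seconds. Deformation cost is
$O(V \cdot (l{+}1)(m{+}1)(n{+}1))$; the suite checks empirically that
doubling either factor at most doubles the work (with generous slack for
timer noise).

## Known limitations

* Orientation matrices other than identity are rejected; oblique
  acquisitions must be resampled upstream.
* The drag constrains exactly one vertex; sub-edge accuracy is bounded by
  mesh resolution.
* Minimum-norm solutions are smooth but not volume- or
  self-intersection-aware; aggressive drags can fold the surface.
* The scripted user is a protocol emulator for testing and benchmarking,
  not a model of human behaviour; its interaction counts are comparable in
  scale, not in kind, to human counts.
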