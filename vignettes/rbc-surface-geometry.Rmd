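---
title: "Discocyte surface geometry: model, meshing and curvature under strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discocyte surface geometry: model, meshing and curvature under strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcmesh)
```

## The model

`rbcmesh` models the human red blood cell (RBC) membrane as the zero set of
a degree-4 polynomial in Cartesian coordinates,

$$F(x,y,z) = (x^2+y^2+z^2)^2 + P\,(x^2+y^2) + Q\,z^2 + R = 0,$$

whose coefficients are fixed by three micro-anatomical distances of the
biconcave disc: the main diameter $d$, the thickness at the centre of the
dimples $b$, and the maximum height near the rim $h$:

$$P = -\frac{d^2}{2} + \frac{h^2}{2}\Big(\frac{d^2}{b^2}-1\Big)
      \Big(1 - \sqrt{1 - b^2/h^2}\Big),\qquad
  Q = P\frac{d^2}{b^2} + \frac{b^2}{4}\Big(\frac{d^4}{b^4}-1\Big),\qquad
  R = -P\frac{d^2}{4} - \frac{d^4}{16}.$$

All lengths are in micrometres throughout the package, so $F$ carries units
of $\mu m^4$, volumes are in $\mu m^3$ ($1\,\mu m^3 = 1$ fL) and areas in
$\mu m^2$. The construction places the rim points $(\pm d/2, 0, 0)$ on the
surface exactly and the dimple centres $(0,0,\pm b/2)$ on it to rounding
error, and $F \to +\infty$ away from the cell, so $\nabla F$ on the zero
set points outward.

The defaults $d = 8$, $b = 1$, $h = 2.12\ \mu m$ are the canonical healthy
human discocyte: they reproduce the textbook mean cell volume of 86 fL
together with a surface area of 128 $\mu m^2$. The literature area of a
real RBC is larger (about 137--143 $\mu m^2$); within this one-parameter
family of quartic shapes the correct volume takes precedence, and no
reconciliation of the area is attempted.

```{r}
co <- shape_coefficients(rbc_geometry())
co
```

## Strain fields

Mechanical distortion, as imposed on cells suspended in a stretched gel,
is modelled by a volume-preserving affine map applied to the whole cell: a
rotation about the $x$-axis by $\theta$ (degrees) followed by a uniaxial
stretch along $z$,

$$M = S_\xi R_\theta, \qquad
  S_\xi = \mathrm{diag}(1/\sqrt{\xi},\, 1/\sqrt{\xi},\, \xi),$$

with $\det M = 1$ exactly. Because the relaxed cell is rotationally
symmetric about $z$, a rotation about any axis in the disc plane is
equivalent to the $x$-axis rotation, so a single Euler angle spans all
physically distinct orientations of the cell relative to the strain axis.
The deformed surface is evaluated by pre-composing the implicit function
with the inverse map, $F_M(p) = F(M^{-1}p)$, whose zero set is exactly the
affine image of the original; its gradient and Hessian follow by the chain
rule in closed form ($\nabla F_M = M^{-T}\nabla F$,
$H_M = M^{-T} H M^{-1}$). Derivatives are never taken numerically in the
production path; central finite differences appear only as test oracles.

$\theta$ is exposed in degrees because the study grid is
$\theta \in \{0^\circ, 45^\circ, 90^\circ\}$,
$\xi \in \{1, 1.25, 1.5, 1.75\}$; $\xi < 1$ (compression) is permitted.
Continuous-$\theta$ population averaging is deliberately not built in: the
sweep (`strain_sweep()`) exposes the grid instead.

## Triangularization

A representation of the spectrin cytoskeleton needs a closed triangle mesh
with a *controllable* number of edges: the membrane skeleton has roughly
121,000 spectrin tetramer struts, so the mesher targets a requested edge
count rather than a geometric tolerance. `mesh_implicit()` is a fully
deterministic pipeline:

1. sample $F$ on a regular grid over a conservative bounding box
   (half-extent $\sum_j |M_{ij}|\,hw_j$ per axis, inflated 8%, where $hw$
   bounds the relaxed shape; the default grid resolves the smallest base
   feature with ~9 cells, shrunk by the smallest singular value of $M$);
2. extract the zero isosurface by marching tetrahedra on the Kuhn 6-tet
   cube subdivision (adjacent cubes share face diagonals, so the result is
   watertight by construction, and zero-crossing vertices are welded by
   grid-edge identity);
3. iteratively remesh isotropically — split edges longer than $4/3$ of the
   target length, collapse edges shorter than $4/5$ (guarded by the link
   condition), flip edges toward valence 6, tangentially smooth
   ($\lambda = 0.5$) — Newton-projecting every vertex onto the zero set
   along $\nabla F$ after each sweep;
4. adjust the target edge length by $L \leftarrow L\sqrt{E/E_\mathrm{target}}$
   until the achieved edge count is within 0.5% of the request (2% is the
   hard acceptance band).

The on-surface tolerance is $|F| < 10^{-9} d^4$ (the quartic's units grow
as length$^4$). Outward orientation is fixed by the sign of $\nabla F$ and
a final signed-volume check. No step uses random numbers, so identical
inputs give byte-identical meshes; the `seed` field recorded in run
configurations is provenance only.

At the full scale of 121,000 edges the pipeline yields
$V \approx 40{,}200$, $F \approx 80{,}400$, $\chi = F - E + V = 2$, volume
within 0.1% of 86 fL, area within 0.1% of 128 $\mu m^2$, mean edge
$\approx 61$ nm and mean triangle area $\approx 1590$ nm$^2$, in 10--15 s
on one CPU. Meshes down-scaled to ~12,000 edges (used for sweeps and most
tests) stay within 0.3% on volume and area.

## Curvature

Four curvature fields are evaluated analytically from the implicit
function at any surface point:

$$K_G = \frac{\nabla F\, H^*[F]\, \nabla F^{T}}{|\nabla F|^4}, \qquad
  K_M = \frac{\nabla F\, H[F]\, \nabla F^{T} - |\nabla F|^2\,
        \mathrm{tr}\,H}{2\,|\nabla F|^3},$$

with $H^*$ the adjugate (cofactor matrix) of the Hessian, and

$$k_1 = K_M + \sqrt{K_M^2 - K_G}, \qquad k_2 = K_M - \sqrt{K_M^2 - K_G}.$$

Two conventions deserve attention:

* **Mean-curvature numerator.** The second term must be
  $|\nabla F|^2\,\mathrm{tr}\,H$. A variant sometimes quoted with
  $|F|^2\,\mathrm{tr}\,H$ would annihilate that term on the surface (where
  $F = 0$) and contradict the sphere closed form; the form used here is
  the standard implicit-surface expression and is forced by the identity
  $K_M = (k_1+k_2)/2$ together with $k_1 = k_2$ on a sphere.
* **Sign.** The normal is $\nabla F/|\nabla F|$ (outward), under which a
  convex body has $K_M < 0$: a sphere of radius $r$ gives exactly
  $K_G = 1/r^2$, $K_M = -1/r$. Comparisons against parametric
  fundamental-form oracles therefore check $K_G$ and $|K_M|$.

$K_M^2 - K_G = ((k_1-k_2)/2)^2$ is mathematically non-negative; numerical
noise down to $-10^{-12}$ is clamped to zero and anything more negative is
treated as an input error.

Per-triangle values (`per_triangle_curvature()`) are either the average of
the three vertex values (default, `vertex_mean`) or the value at the
centroid. The flat-triangle centroid sits $O(\mathrm{edge}^2)$ off the
curved surface, so by default it is Newton-projected onto the zero set
before evaluation; the raw-centroid variant is available
(`project_centroid = FALSE`) for comparison. Both modes are consistent
estimators of the same smooth field: at $\ge 10^4$ faces their
area-weighted means differ by well under 1%.

Aggregation uses the area-weighted mean, and the discrete Gauss--Bonnet
sum $\sum_i K_{G,i}\,\mathrm{area}_i$ serves as a global validity check:
it must approach $2\pi\chi = 4\pi$ for every closed genus-0 mesh,
deformed or not. The suite verifies this to better than 1% on relaxed and
strained full-scale meshes, and to 0.5% across an order of magnitude in
mesh resolution.

## Analyses

* `bin_curvature()` divides a field's value range linearly into `n_bins`
  sub-domains (last bin right-inclusive) and reports per-bin mean value,
  area and area fraction; fractions sum to 1 exactly. A constant field
  degenerates to a single occupied bin by design.
* `strain_sweep()` re-meshes the transformed implicit surface per grid
  cell — the remesh-per-state workflow — and tabulates area, volume and
  mean edge length. Under the default grid the computed response is:
  area decreases monotonically with $\xi$ at $\theta = 0^\circ$ (cell
  across the strain axis, to about $-17\%$ at $\xi = 1.75$) and increases
  monotonically at $\theta = 90^\circ$ (disc plane along the strain axis,
  to $+22.8\%$ at $\xi = 1.75$ — the exact affine-image value, confirmed
  against an independent surface-of-revolution push-forward integral),
  while volume stays within 0.4% of 86 fL everywhere, as $\det M = 1$
  demands.
* `area_change_partition()` and `curvature_difference_map()` use the
  *other* workflow: mesh the relaxed cell once and push vertices forward
  through $M$, so each triangle keeps its identity between states. The
  partition threshold for "unchanged" is a relative area change below
  $10^{-12}$ — effectively sign-only, since a det-1 anisotropic strain
  leaves almost no triangle exactly unchanged. Connected components of the
  expanded/diminished face sets are counted by shared-edge flood fill;
  their exact topology is mesh-dependent and not asserted.
* `cytoskeleton_report()` is closed-form arithmetic linking the mesh to
  spectrin biology: 121,000 edges imply $2/3 \times 121{,}000 = 80{,}667$
  triangles; fully extended 200-nm struts would tessellate
  $80{,}667 \times 0.0173\,\mu m^2 \approx 1397\,\mu m^2$, 10.9 times the
  real membrane area, whereas the real area implies a mean triangle of
  $128/80{,}667 \approx 0.0016\,\mu m^2$ and hence a ~60.8 nm internodal
  spacing (the side length is back-computed from the mean *rounded to four
  decimals* in $\mu m^2$, matching how such estimates are customarily
  quoted); a 0.79 $\mu m^2$ patch-clamp dome spans ~500 triangles.

## What the defaults emulate, and what they do not

The default configuration *is* the study condition set: canonical
geometry, 121,000 edges, 10 linear bins, the
$3 \times 4$ $(\theta,\xi)$ grid. The isotropic remesher produces a
unimodal, fairly tight edge-length distribution with modal valence 6 and
a few 5/7-valence vertices — statistically like a spectrin network, but it
is *not* a physical model of one: triangle-quality details (multi-modal
fine-binned edge histograms, spatial patterns of irregular vertices) are
artifacts of whichever mesher is used and are deliberately not targets.
Likewise the affine strain field is the simplest possible distortion;
non-uniaxial, nonlinear or time-dependent strain, cytoskeletal
rearrangement kinetics, and mechanosensitive-channel (Piezo1) gating are
out of scope.

## Numerical choices and limitations

* On-surface tolerance $10^{-9}\,d^4$; Newton projection capped at 30--50
  iterations (it converges quadratically in practice).
* Edge-count control: inner convergence at 0.5% of the target, hard
  failure beyond 2%; up to 16 remesh rounds.
* Degenerate inputs: $b > h$ (imaginary square root), non-positive
  dimensions, $\xi \le 0$, sub-500-edge targets, non-watertight meshes and
  singular-gradient evaluation points are all rejected with explicit
  errors rather than propagated.
* Problem sizes in the shipped tests: full-scale meshes (121,000 edges)
  are built once and shared; sweeps and push-forward analyses run at
  12,000 edges, where volume/area are still within a few tenths of a
  percent — these sizes are the package's own accuracy/runtime trade-off.
* The piecewise-linear mesh slightly underestimates area and volume
  (inscribed-polyhedron bias, $O(L^2)$); at full scale the bias is ~0.05%.
* Exact reproduction of statistics that depend on another mesher's
  triangle-quality profile is a non-goal; only mesher-independent
  quantities (volume, area, Euler characteristic, total curvature,
  mean edge/triangle scale, strain responses) are asserted.
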