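# rbcmesh

Geometry of the human red blood cell surface under mechanical strain.

The healthy red blood cell (RBC) is a biconcave disc whose membrane and
spectrin cytoskeleton deform when the cell is stretched — for instance when
cells suspended in a gelatin gel are elongated inside an NMR magnet, a
protocol used to study strain-activated cation channels (Piezo1) and
metabolic responses. `rbcmesh` provides the computational geometry for such
studies:

* **Shape model.** The cell surface is the zero set of a quartic,
  `(x² + y² + z²)² + P(x² + y²) + Q z² + R = 0`, with `P, Q, R` fixed by the
  main diameter `d`, dimple thickness `b` and rim height `h`. The default
  `d = 8, b = 1, h = 2.12 µm` gives the canonical 86 fL cell with 128 µm²
  of membrane.
* **Strain.** A volume-preserving affine field `M = S_ξ R_θ` (Euler rotation
  about x by θ, then uniaxial stretch along z by ξ with
  `S_ξ = diag(ξ^-1/2, ξ^-1/2, ξ)`, det M = 1). The deformed surface is
  `F(M⁻¹p) = 0`.
* **Triangularization.** A deterministic marching-tetrahedra + isotropic
  remeshing + Newton projection pipeline produces watertight meshes with a
  controllable edge count — 121,000 edges to mirror the spectrin tetramer
  count — validated by Euler's formula `F − E + V = 2` and the
  Gauss–Bonnet sum `Σ K_G · area ≈ 4π`.
* **Curvature.** Gaussian, mean and both principal curvatures evaluated in
  closed form from the gradient, Hessian and Hessian adjugate of the
  implicit function:
  `K_G = ∇F H*[F] ∇Fᵀ / |∇F|⁴`,
  `K_M = (∇F H[F] ∇Fᵀ − |∇F|² tr H) / (2|∇F|³)`,
  `k₁,₂ = K_M ± √(K_M² − K_G)`.
* **Analyses.** Curvature binning into linear value bins with area
  fractions, (θ, ξ) strain sweeps, per-triangle area-change partitions
  under push-forward, curvature difference maps, edge/area histograms, and
  closed-form cytoskeleton arithmetic; PLY/OFF/STL export with per-face
  fields.

## Worked example

```r
library(rbcmesh)

geom <- rbc_geometry()            # d = 8, b = 1, h = 2.12 um
shape_coefficients(geom)
#> Quartic coefficients: P = -15.260353 um^2, Q = 47.087409 um^2, R = -11.834352 um^4

surf <- implicit_rbc(geom)
mesh <- mesh_implicit(surf, target_edges = 12000)
mesh
#> Triangle mesh: 3999 vertices, 7994 faces, 11991 edges (chi = 2)
mesh_volume(mesh)                 # 85.78252  (fL; 86 at full resolution)
mesh_area(mesh)                   # 127.8758  (um^2)

# curvature of the stretched cell, disc plane along the strain axis
def  <- affine_deformation(theta = 90, xi = 1.75)
sdef <- deform_surface(surf, def)
mdef <- mesh_implicit(sdef, target_edges = 12000)
mesh_area(mdef)                   # 156.9146 -> +22.7% membrane area
fld <- per_triangle_curvature(mdef, sdef)
total_gaussian_curvature(fld) / (4 * pi)   # ~0.9995: Gauss-Bonnet check

cytoskeleton_report(patch_area_um2 = 0.79)
#> Cytoskeleton tessellation (121000 edges -> 80667 triangles):
#>   fully extended strut 200 nm -> triangle area 0.0173 um^2
#>   implied tessellation area 1397 um^2 (10.9 x the real 128 um^2)
#>   mean triangle area 0.00159 um^2 (rounded 0.0016) -> side 60.8 nm
#>   498 triangles spanned by a 0.79 um^2 patch
```

The numbers mean: a 12,000-edge mesh already reproduces the cell volume and
area to ~0.3%; stretching the cell by 75% along its disc plane expands the
membrane by ~23% while the volume is untouched (det M = 1); and if the
121,000 spectrin struts were fully extended (200 nm) they would tessellate
an area 10.9× the real membrane — the network must be strongly coiled, with
~61 nm between nodes.

A command-line wrapper ships in `exec/rbcmesh` with subcommands `build`,
`sweep`, `curvature`, `partition` and `report`, driven by `--key value`
flags or a flat `key = value` config file.

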