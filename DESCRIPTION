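Package: rbcmesh
Title: Discocyte Surface Meshing and Membrane Curvature Under Strain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the human red blood cell as a quartic implicit discocyte
    surface, deforms it with volume-preserving affine strain fields (Euler
    rotation about the x-axis composed with uniaxial stretch along z),
    triangularizes the surface to spectrin-cytoskeleton scale with a
    deterministic marching-tetrahedra plus isotropic-remeshing pipeline, and
    evaluates Gaussian, mean and principal curvatures analytically from the
    gradient, Hessian and adjugate of the implicit function. Includes mesh
    validation (Euler characteristic, Gauss-Bonnet), curvature binning and
    strain sweeps, per-triangle area-change partitions under push-forward,
    cytoskeleton-geometry reports, and PLY/OFF/STL export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
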