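test_that("sphere curvatures match closed forms at random surface points", {
  for (r in c(1, 2.5)) {
    sph <- implicit_sphere(r)
    p <- random_on_surface(sph, 100, seed = 1)
    expect_equal(gaussian_curvature(sph, p), rep(1 / r^2, 100), tolerance = 1e-9)
    # outward-gradient convention: convex body has negative mean curvature
    expect_equal(mean_curvature(sph, p), rep(-1 / r, 100), tolerance = 1e-9)
    expect_equal(sph$KG_closed(p), rep(1 / r^2, 100), tolerance = 1e-9)
    expect_equal(sph$KM_closed(p), rep(1 / r, 100), tolerance = 1e-9)
  }
})

test_that("implicit-route curvatures match the parametric fundamental forms on ellipsoids", {
  for (axes in list(c(2, 1, 1), c(1.7, 1.1, 0.6))) {
    ell <- implicit_ellipsoid(axes)
    set.seed(17)
    u <- runif(100, 0, 2 * pi)
    v <- runif(100, -1.2, 1.2)
    oracle <- ellipsoid_param_curvature(axes, u, v)
    KG <- gaussian_curvature(ell, oracle$points)
    KM <- mean_curvature(ell, oracle$points)
    expect_lt(max(abs(KG - oracle$KG) / abs(oracle$KG)), 1e-6)
    expect_lt(max(abs(abs(KM) - abs(oracle$KM)) / abs(oracle$KM)), 1e-6)
    # fixture's own closed-form accessors agree with both routes
    expect_lt(max(abs(ell$KG_closed(oracle$points) - KG) / KG), 1e-6)
  }
  # pole of the (2,1,1) ellipsoid: K_G = a^2/(b^2 c^2) = 4
  ell <- implicit_ellipsoid(c(2, 1, 1))
  expect_equal(gaussian_curvature(ell, c(2, 0, 0)), 4, tolerance = 1e-10)
  expect_equal(ell$KG_closed(c(2, 0, 0)), 4, tolerance = 1e-12)
})

test_that("principal curvatures obey their defining identities", {
  surf <- rbc_surface()
  p <- random_on_surface(surf, 100, seed = 2)
  KG <- gaussian_curvature(surf, p)
  KM <- mean_curvature(surf, p)
  pk <- principal_curvatures(KM, KG)
  expect_equal(pk$k1 * pk$k2, KG, tolerance = 1e-8)
  expect_equal((pk$k1 + pk$k2) / 2, KM, tolerance = 1e-8)
  expect_true(all(pk$k1 >= pk$k2))
  expect_true(all(KM^2 - KG >= -1e-12))
  # direct substitution case
  pk2 <- principal_curvatures(0, -1)
  expect_equal(pk2$k1, 1)
  expect_equal(pk2$k2, -1)
  expect_error(principal_curvatures(0, 1), "inconsistent")
})

test_that("the dimple centre is an umbilic and the rim matches the profile-curve oracle", {
  surf <- rbc_surface()
  co <- shape_coefficients(rbc_geometry())
  dimple <- c(0, 0, 0.5)
  KG <- gaussian_curvature(surf, dimple)
  KM <- mean_curvature(surf, dimple)
  pk <- principal_curvatures(KM, KG)
  expect_lt(abs(pk$k1 - pk$k2), 1e-8)          # rotational symmetry on the axis
  rimKG <- gaussian_curvature(surf, c(4, 0, 0))
  expect_gt(rimKG, 0)
  expect_equal(rimKG, rim_KG_profile_oracle(co), tolerance = 1e-4)
  # saddle ring between dimple and rim has negative Gaussian curvature
  ring <- project_to_surface(surf, cbind(seq(1, 3, 0.25), 0, 0.7))
  expect_true(any(gaussian_curvature(surf, ring) < 0))
})

test_that("curvatures obey the similarity scaling law", {
  s <- 2
  surf1 <- rbc_surface()
  surf2 <- implicit_rbc(rbc_geometry(8 * s, 1 * s, 2.12 * s))
  p <- random_on_surface(surf1, 50, seed = 3)
  expect_equal(gaussian_curvature(surf2, s * p), gaussian_curvature(surf1, p) / s^2,
               tolerance = 1e-9)
  expect_equal(mean_curvature(surf2, s * p), mean_curvature(surf1, p) / s,
               tolerance = 1e-9)
})

test_that("per-triangle fields are constant on the sphere in both modes", {
  m <- sphere_mesh()
  sph <- implicit_sphere(1)
  for (mode in c("vertex_mean", "centroid")) {
    fld <- per_triangle_curvature(m, sph, mode = mode)
    expect_lt(max(abs(fld$KG_um_2 - 1)), 1e-6)
    expect_lt(max(abs(fld$KM_um_1 + 1)), 1e-6)
  }
  expect_identical(attr(per_triangle_curvature(m, sph), "mode"), "vertex_mean")
  expect_identical(attr(per_triangle_curvature(m, sph, mode = "centroid"), "mode"),
                   "centroid_projected")
  expect_identical(attr(per_triangle_curvature(m, sph, mode = "centroid",
                                               project_centroid = FALSE), "mode"),
                   "centroid_raw")
})

test_that("vertex-average and centroid modes agree in the area-weighted mean", {
  m <- rbc_mesh(24000)        # 16,000 faces
  surf <- rbc_surface()
  f1 <- per_triangle_curvature(m, surf, mode = "vertex_mean")
  f2 <- per_triangle_curvature(m, surf, mode = "centroid")
  w1 <- weighted_average_curvature(f1$KG_um_2, f1$area_um2)
  w2 <- weighted_average_curvature(f2$KG_um_2, f2$area_um2)
  expect_lt(abs(w1 - w2) / abs(w1), 0.01)
})

test_that("weighted averages reduce to the obvious special cases", {
  expect_equal(weighted_average_curvature(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_average_curvature(c(0, 4), c(1, 3)), 3)
  expect_equal(weighted_average_curvature(5, 2), 5)
  expect_error(weighted_average_curvature(c(1, 2), c(0, 0)), "positive")
})

test_that("total Gaussian curvature approximates 4 pi on closed genus-0 meshes", {
  m <- sphere_mesh()
  fld <- per_triangle_curvature(m, implicit_sphere(1))
  expect_lt(abs(total_gaussian_curvature(fld) - 4 * pi) / (4 * pi), 0.01)
  m2 <- rbc_mesh(12000)
  fld2 <- per_triangle_curvature(m2, rbc_surface())
  expect_lt(abs(total_gaussian_curvature(fld2) - 4 * pi) / (4 * pi), 0.01)
})

test_that("total curvature is independent of mesh resolution", {
  t1 <- total_gaussian_curvature(per_triangle_curvature(rbc_mesh(12000), rbc_surface()))
  t2 <- total_gaussian_curvature(per_triangle_curvature(rbc_mesh_full(), rbc_surface()))
  expect_lt(abs(t1 - t2) / abs(t2), 0.005)
})

test_that("singular gradients are reported, not silently propagated", {
  expect_error(gaussian_curvature(rbc_surface(), c(0, 0, 0)), "singular")
})
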