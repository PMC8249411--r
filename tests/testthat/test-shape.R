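test_that("quartic coefficients match independent arithmetic and their identities", {
  co <- shape_coefficients(rbc_geometry(8, 1, 2.12))
  # frozen values computed independently from the coefficient formulas
  expect_equal(co$P, -15.260352981390, tolerance = 1e-12)
  expect_equal(co$Q, 47.087409191012, tolerance = 1e-12)
  expect_equal(co$R, -11.834352297753, tolerance = 1e-12)
  # with d = 8, R = -16 P - 256 algebraically
  expect_equal(co$R, -16 * co$P - 256, tolerance = 1e-14)
  # b = h: the square-root term vanishes
  co2 <- shape_coefficients(rbc_geometry(8, 2.12, 2.12))
  expect_equal(co2$P, -8^2 / 2 + 2.12^2 / 2 * (8^2 / 2.12^2 - 1), tolerance = 1e-14)
})

test_that("degenerate geometries are rejected", {
  expect_error(rbc_geometry(8, 2.2, 2.12), "b must not exceed h")
  expect_error(rbc_geometry(-8, 1, 2.12), "positive")
  expect_error(rbc_geometry(8, 0, 2.12), "positive")
  expect_error(rbc_geometry(2, 1, 2.12), "smaller than d")
})

test_that("rim and dimple-centre points lie on the surface, origin is inside", {
  surf <- rbc_surface()
  co <- shape_coefficients(rbc_geometry())
  expect_identical(implicit_value(surf, c(4, 0, 0)), 0)       # forced exactly
  expect_identical(implicit_value(surf, c(-4, 0, 0)), 0)
  expect_lt(abs(implicit_value(surf, c(0, 0, 0.5))), 1e-9 * 8^4)
  expect_lt(abs(implicit_value(surf, c(0, 0, -0.5))), 1e-9 * 8^4)
  expect_equal(implicit_value(surf, c(0, 0, 0)), co$R)
  expect_lt(co$R, 0)
  # F grows to +Inf away from the cell
  expect_gt(implicit_value(surf, c(10, 0, 0)), 0)
})

test_that("analytic derivatives agree with central finite differences", {
  surf <- rbc_surface()
  set.seed(7)
  pts <- cbind(runif(100, -4.4, 4.4), runif(100, -4.4, 4.4), runif(100, -1.2, 1.2))
  der <- implicit_derivatives(surf, pts)
  for (i in seq_len(nrow(pts))) {
    g_fd <- fd_gradient(surf, pts[i, ])
    scale <- max(abs(g_fd), 1)
    expect_lt(max(abs(der$gradient[i, ] - g_fd)) / scale, 1e-5)
    H_fd <- fd_hessian(surf, pts[i, ])
    expect_lt(max(abs(der$hessian[i, , ] - H_fd)) / max(abs(H_fd), 1), 1e-5)
  }
})

test_that("gradient vanishes at the origin and the Hessian is diag(2P, 2P, 2Q)", {
  surf <- rbc_surface()
  co <- shape_coefficients(rbc_geometry())
  der <- implicit_derivatives(surf, c(0, 0, 0))
  expect_equal(as.numeric(der$gradient), c(0, 0, 0))
  expect_equal(der$hessian[1, , ], diag(c(2 * co$P, 2 * co$P, 2 * co$Q)))
})

test_that("Hessian is symmetric and the adjugate satisfies H H* = det(H) I", {
  surf <- rbc_surface()
  set.seed(11)
  pts <- cbind(runif(20, -4, 4), runif(20, -4, 4), runif(20, -1, 1))
  der <- implicit_derivatives(surf, pts)
  for (i in seq_len(nrow(pts))) {
    H <- der$hessian[i, , ]
    A <- der$adjugate[i, , ]
    expect_equal(H, t(H))
    lhs <- H %*% A
    rhs <- det(H) * diag(3)
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs), 1), 1e-8)
  }
})

test_that("the untransformed quartic has mirror and axial rotational symmetry", {
  surf <- rbc_surface()
  set.seed(3)
  pts <- cbind(runif(50, -4, 4), runif(50, -4, 4), runif(50, -1.2, 1.2))
  F0 <- implicit_value(surf, pts)
  expect_equal(implicit_value(surf, pts * matrix(c(-1, 1, 1), 50, 3, byrow = TRUE)), F0)
  expect_equal(implicit_value(surf, pts * matrix(c(1, -1, 1), 50, 3, byrow = TRUE)), F0)
  expect_equal(implicit_value(surf, pts * matrix(c(1, 1, -1), 50, 3, byrow = TRUE)), F0)
  # rotation about z: F depends on x^2 + y^2 only
  phi <- runif(50, 0, 2 * pi)
  rot <- cbind(pts[, 1] * cos(phi) - pts[, 2] * sin(phi),
               pts[, 1] * sin(phi) + pts[, 2] * cos(phi),
               pts[, 3])
  expect_equal(implicit_value(surf, rot), F0, tolerance = 1e-10)
})

test_that("sphere fixture has the closed-form derivative bundle at the pole", {
  # with r = 1 the normalized quadric is x^2 + y^2 + z^2 - 1
  sph <- implicit_sphere(1)
  der <- implicit_derivatives(sph, c(1, 0, 0))
  expect_equal(as.numeric(der$gradient), c(2, 0, 0))
  expect_equal(der$hessian[1, , ], 2 * diag(3))
  expect_equal(der$adjugate[1, , ], 4 * diag(3))
  expect_equal(der$trace, 6)
})

test_that("Newton projection lands on the zero set", {
  surf <- rbc_surface()
  set.seed(21)
  raw <- cbind(runif(50, -4.4, 4.4), runif(50, -4.4, 4.4), runif(50, -1.3, 1.3))
  proj <- project_to_surface(surf, raw)
  expect_true(all(abs(implicit_value(surf, proj)) < surface_tolerance(surf)))
})
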