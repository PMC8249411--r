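#' Discocyte geometry
#'
#' The biconcave-disc shape of a human red blood cell is fixed by three
#' principal distances: the main diameter `d`, the thickness at the centre of
#' the dimples `b`, and the maximum thickness (height) near the rim `h`, all
#' in micrometres. The defaults (d = 8, b = 1, h = 2.12) give the canonical
#' cell with volume 86 um^3 (= 86 fL) and surface area 128 um^2.
#'
#' @param d main diameter, um.
#' @param b dimple (centre) thickness, um.
#' @param h maximum rim height, um.
#' @return An object of class `rbc_geometry`.
#' @examples
#' geom <- rbc_geometry()
#' shape_coefficients(geom)
#' @export
rbc_geometry <- function(d = 8, b = 1, h = 2.12) {
  if (!is.numeric(d) || !is.numeric(b) || !is.numeric(h) ||
      length(d) != 1 || length(b) != 1 || length(h) != 1)
    stop("d, b, h must be single numeric values")
  if (d <= 0 || b <= 0 || h <= 0)
    stop("dimensions d, b, h must be positive")
  if (b > h)
    stop("b must not exceed h (the square root (1 - b^2/h^2)^(1/2) would be imaginary)")
  if (h >= d)
    stop("h must be smaller than d for a biconcave disc")
  structure(list(d = d, b = b, h = h), class = "rbc_geometry")
}

#' @export
print.rbc_geometry <- function(x, ...) {
  cat(sprintf("Discocyte geometry: d = %g um, b = %g um, h = %g um\n",
              x$d, x$b, x$h))
  invisible(x)
}

#' Quartic shape coefficients of the discocyte
#'
#' Computes the coefficients P (um^2), Q (um^2) and R (um^4) of the implicit
#' quartic \deqn{(x^2+y^2+z^2)^2 + P (x^2+y^2) + Q z^2 + R = 0.}
#' The construction forces the rim points (+-d/2, 0, 0) onto the surface
#' exactly and the dimple-centre points (0, 0, +-b/2) onto it to rounding
#' error.
#'
#' @param geom an [rbc_geometry()].
#' @return A list with components `P`, `Q`, `R` (class `shape_coefficients`).
#' @export
shape_coefficients <- function(geom) {
  stopifnot(inherits(geom, "rbc_geometry"))
  d <- geom$d; b <- geom$b; h <- geom$h
  P <- -d^2 / 2 + h^2 / 2 * (d^2 / b^2 - 1) * (1 - sqrt(1 - b^2 / h^2))
  Q <- P * d^2 / b^2 + b^2 / 4 * (d^4 / b^4 - 1)
  R <- -P * d^2 / 4 - d^4 / 16
  structure(list(P = P, Q = Q, R = R), class = "shape_coefficients")
}

#' @export
print.shape_coefficients <- function(x, ...) {
  cat(sprintf("Quartic coefficients: P = %.6f um^2, Q = %.6f um^2, R = %.6f um^4\n",
              x$P, x$Q, x$R))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Implicit surface objects.
##
## An implicit_surface bundles the evaluators F, grad F, Hessian and adjugate
## of a scalar field whose zero set is the surface, optionally pre-composed
## with the inverse of an affine map M (so the zero set is the image under M
## of the base zero set). `kind` is 0 for the RBC quartic (params P, Q, R)
## and 1 for an axis-aligned ellipsoid (params a, b, c). `halfwidths` is a
## bounding half-extent of the *base* (untransformed) zero set, used to build
## conservative meshing boxes.
## ---------------------------------------------------------------------------

new_implicit_surface <- function(kind, params, halfwidths, scale,
                                 M = diag(3), minv = diag(3), label = "surface") {
  structure(list(kind = kind, params = as.numeric(params),
                 halfwidths = halfwidths, scale = scale,
                 M = M, minv = minv, label = label),
            class = "implicit_surface")
}

#' Implicit discocyte surface
#'
#' Builds the evaluator bundle for the quartic discocyte: the scalar field F
#' (um^4), its gradient (um^3), Hessian (um^2) and Hessian adjugate. F tends
#' to +Inf away from the cell, so the gradient on the zero set points
#' outward.
#'
#' @param geom an [rbc_geometry()], or a `shape_coefficients` object.
#' @return An `implicit_surface`.
#' @examples
#' surf <- implicit_rbc(rbc_geometry())
#' implicit_value(surf, c(4, 0, 0))   # rim point, exactly 0
#' @export
implicit_rbc <- function(geom = rbc_geometry()) {
  if (inherits(geom, "rbc_geometry")) {
    co <- shape_coefficients(geom)
    hw <- c(geom$d / 2, geom$d / 2, geom$h / 2)
    scale <- geom$d
  } else if (inherits(geom, "shape_coefficients")) {
    co <- geom
    ## quartic zero set lies within |x| <= sqrt(-P + sqrt(P^2 - 4R))... use a
    ## generous ball bound from the rim radius d/2 = (-P/4 ... ) fall back:
    r <- sqrt(sqrt(pmax(co$P^2 / 4 - co$R, 0)) + abs(co$P))
    hw <- rep(r, 3)
    scale <- 2 * r
  } else stop("geom must be an rbc_geometry or shape_coefficients object")
  new_implicit_surface(0L, c(co$P, co$Q, co$R), hw, scale, label = "rbc")
}

#' @export
print.implicit_surface <- function(x, ...) {
  kind <- if (x$kind == 0L) "quartic discocyte" else "ellipsoid"
  tr <- if (all(x$M == diag(3))) "untransformed" else "affine-transformed"
  cat(sprintf("Implicit surface (%s, %s)\n", kind, tr))
  invisible(x)
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3)
    points <- matrix(points, 1, 3)
  }
  stopifnot(ncol(points) == 3)
  points
}

## map world points to the base frame of the surface
to_local <- function(surface, pts) pts %*% t(surface$minv)

#' Evaluate the implicit function
#'
#' @param surface an `implicit_surface`.
#' @param points a 3-vector or an n x 3 matrix of points (um).
#' @return Numeric vector of F values (um^4 for the quartic); zero within
#'   tolerance iff the point is on the surface, negative inside.
#' @export
implicit_value <- function(surface, points) {
  pts <- to_local(surface, as_point_matrix(points))
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (surface$kind == 0L) {
    p <- surface$params
    s <- x^2 + y^2 + z^2
    s^2 + p[1] * (x^2 + y^2) + p[2] * z^2 + p[3]
  } else {
    p <- surface$params
    x^2 / p[1]^2 + y^2 / p[2]^2 + z^2 / p[3]^2 - 1
  }
}

#' Analytic derivatives of the implicit function
#'
#' Returns the exact closed-form gradient, Hessian, Hessian adjugate and
#' Laplacian (Hessian trace) of the possibly affine-composed implicit
#' function at each point. With an inverse affine map A attached,
#' grad = A^T grad F(Ax) and Hessian = A^T H(Ax) A.
#'
#' @inheritParams implicit_value
#' @return A list with `gradient` (n x 3), `hessian` (n x 3 x 3 array),
#'   `adjugate` (n x 3 x 3), `trace` (length n).
#' @export
implicit_derivatives <- function(surface, points) {
  P0 <- as_point_matrix(points)
  n <- nrow(P0)
  pts <- to_local(surface, P0)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (surface$kind == 0L) {
    p <- surface$params
    s <- x^2 + y^2 + z^2
    g <- cbind(4 * s * x + 2 * p[1] * x,
               4 * s * y + 2 * p[1] * y,
               4 * s * z + 2 * p[2] * z)
    ## H = 4 s I + 8 q q^T + diag(2P, 2P, 2Q)
    hxx <- 4 * s + 8 * x^2 + 2 * p[1]
    hyy <- 4 * s + 8 * y^2 + 2 * p[1]
    hzz <- 4 * s + 8 * z^2 + 2 * p[2]
    hxy <- 8 * x * y; hxz <- 8 * x * z; hyz <- 8 * y * z
  } else {
    p <- surface$params
    g <- cbind(2 * x / p[1]^2, 2 * y / p[2]^2, 2 * z / p[3]^2)
    hxx <- rep(2 / p[1]^2, n); hyy <- rep(2 / p[2]^2, n); hzz <- rep(2 / p[3]^2, n)
    hxy <- hxz <- hyz <- rep(0, n)
  }
  A <- surface$minv
  if (!all(A == diag(3))) {
    g <- g %*% A    # (A^T g)^T rows
    H <- array(0, c(n, 3, 3))
    Hl <- array(c(hxx, hxy, hxz, hxy, hyy, hyz, hxz, hyz, hzz), c(n, 3, 3))
    for (i in 1:3) for (j in 1:3) {
      acc <- 0
      for (k in 1:3) for (l in 1:3)
        acc <- acc + A[k, i] * Hl[, k, l] * A[l, j]
      H[, i, j] <- acc
    }
    hxx <- H[, 1, 1]; hyy <- H[, 2, 2]; hzz <- H[, 3, 3]
    hxy <- H[, 1, 2]; hxz <- H[, 1, 3]; hyz <- H[, 2, 3]
  }
  hess <- array(c(hxx, hxy, hxz, hxy, hyy, hyz, hxz, hyz, hzz), c(n, 3, 3))
  ## adjugate of a symmetric 3x3, componentwise
  a11 <- hyy * hzz - hyz^2
  a22 <- hxx * hzz - hxz^2
  a33 <- hxx * hyy - hxy^2
  a12 <- hxz * hyz - hxy * hzz
  a13 <- hxy * hyz - hxz * hyy
  a23 <- hxy * hxz - hxx * hyz
  adj <- array(c(a11, a12, a13, a12, a22, a23, a13, a23, a33), c(n, 3, 3))
  list(gradient = g, hessian = hess, adjugate = adj, trace = hxx + hyy + hzz)
}

#' On-surface tolerance
#'
#' Absolute tolerance on |F| used to decide whether a point lies on the zero
#' set: 1e-9 * scale^4 for the quartic (whose units grow as length^4), and
#' 1e-9 for the dimensionless quadric of the ellipsoid fixtures.
#'
#' @param surface an `implicit_surface`.
#' @export
surface_tolerance <- function(surface) {
  if (surface$kind == 0L) 1e-9 * surface$scale^4 else 1e-9
}

## serialize for the C++ mesher
surface_spec <- function(surface) {
  list(kind = surface$kind, params = surface$params, minv = surface$minv)
}

#' Project points onto the implicit surface
#'
#' Newton iteration along the gradient, `p <- p - F(p) grad F / |grad F|^2`,
#' until |F| falls below the on-surface tolerance.
#'
#' @inheritParams implicit_value
#' @param tol absolute tolerance on |F|; default [surface_tolerance()].
#' @param maxit maximum Newton iterations.
#' @return Matrix of projected points (same shape as the input matrix).
#' @export
project_to_surface <- function(surface, points, tol = surface_tolerance(surface),
                               maxit = 50L) {
  pts <- as_point_matrix(points)
  cpp_project(surface_spec(surface), pts, tol, as.integer(maxit))
}
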