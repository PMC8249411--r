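#' Sphere and ellipsoid test fixtures
#'
#' Quadric implicit surfaces with closed-form curvature accessors, used as
#' oracles for the implicit-function curvature formulas. The sphere of
#' radius r has K_G = 1/r^2 and |K_M| = 1/r everywhere; the axis-aligned
#' ellipsoid x^2/a^2 + y^2/b^2 + z^2/c^2 = 1 has
#' \deqn{K_G = \frac{1}{a^2 b^2 c^2 w^4}, \qquad
#'       |K_M| = \frac{T w^2 - u}{2 w^3},}
#' with w^2 = x^2/a^4 + y^2/b^4 + z^2/c^4, u = x^2/a^6 + y^2/b^6 + z^2/c^6
#' and T = 1/a^2 + 1/b^2 + 1/c^2. The accessors return the convex-body
#' convention with positive mean curvature; the implicit-function route with
#' the outward-gradient normal yields K_M of opposite sign.
#'
#' @param name fixture name, `"sphere"` or `"ellipsoid"`.
#' @param params for the sphere a single radius `r`; for the ellipsoid the
#'   semi-axes `c(a, b, c)`.
#' @return An `implicit_surface` with additional closed-form accessors
#'   `KG_closed(points)` and `KM_closed(points)` (the latter unsigned).
#' @examples
#' sph <- make_fixture("sphere", 2)
#' sph$KG_closed(c(2, 0, 0))   # 1/4
#' @export
make_fixture <- function(name = c("sphere", "ellipsoid"), params) {
  name <- match.arg(name)
  if (name == "sphere") {
    stopifnot(is.numeric(params), length(params) == 1, params > 0)
    axes <- rep(params, 3)
  } else {
    stopifnot(is.numeric(params), length(params) == 3, all(params > 0))
    axes <- as.numeric(params)
  }
  surf <- new_implicit_surface(1L, axes, halfwidths = axes,
                               scale = 2 * max(axes), label = name)
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  surf$KG_closed <- function(points) {
    p <- as_point_matrix(points)
    w2 <- p[, 1]^2 / a^4 + p[, 2]^2 / b^4 + p[, 3]^2 / c^4
    1 / (a^2 * b^2 * c^2 * w2^2)
  }
  surf$KM_closed <- function(points) {
    p <- as_point_matrix(points)
    w2 <- p[, 1]^2 / a^4 + p[, 2]^2 / b^4 + p[, 3]^2 / c^4
    u <- p[, 1]^2 / a^6 + p[, 2]^2 / b^6 + p[, 3]^2 / c^6
    Tc <- 1 / a^2 + 1 / b^2 + 1 / c^2
    (Tc * w2 - u) / (2 * w2^1.5)
  }
  surf
}

#' @rdname make_fixture
#' @param r sphere radius.
#' @export
implicit_sphere <- function(r = 1) make_fixture("sphere", r)

#' @rdname make_fixture
#' @param axes semi-axes `c(a, b, c)` of the ellipsoid.
#' @export
implicit_ellipsoid <- function(axes = c(2, 1, 1)) make_fixture("ellipsoid", axes)
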