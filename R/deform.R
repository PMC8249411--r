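#' Euler rotation matrix about the x-axis
#'
#' \deqn{R_\theta = \begin{pmatrix} 1 & 0 & 0 \\ 0 & \cos\theta & -\sin\theta
#'   \\ 0 & \sin\theta & \cos\theta \end{pmatrix}}
#' theta = 0 is the original orientation. By the rotational symmetry of the
#' relaxed discocyte about z, rotation about any in-plane axis is equivalent
#' to this one.
#'
#' @param theta rotation angle in degrees.
#' @return A 3 x 3 rotation matrix (orthogonal, determinant 1).
#' @export
rotation_matrix <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1, is.finite(theta))
  t <- theta * pi / 180
  matrix(c(1, 0, 0,
           0, cos(t), -sin(t),
           0, sin(t),  cos(t)), 3, 3, byrow = TRUE)
}

#' Volume-preserving strain tensor along z
#'
#' \deqn{S_\xi = \mathrm{diag}(1/\sqrt\xi,\; 1/\sqrt\xi,\; \xi)}
#' elongates a body along z by the factor xi while shrinking x and y so that
#' the determinant is exactly 1 (volume preservation). xi = 1 is the relaxed
#' shape; xi < 1 describes compression.
#'
#' @param xi strain factor, dimensionless, > 0.
#' @return A 3 x 3 diagonal matrix with determinant 1.
#' @export
strain_matrix <- function(xi) {
  stopifnot(is.numeric(xi), length(xi) == 1)
  if (!is.finite(xi) || xi <= 0) stop("strain factor xi must be > 0")
  diag(c(1 / sqrt(xi), 1 / sqrt(xi), xi))
}

#' Affine deformation: rotate, then strain
#'
#' Bundles the rotation R_theta, the strain S_xi, their composition
#' M = S_xi R_theta (rotate first, then strain) and its inverse. det(M) = 1,
#' so any enclosed volume is preserved exactly under the map.
#'
#' @param theta rotation about the x-axis, degrees.
#' @param xi strain factor along z, > 0.
#' @return An object of class `affine_deformation` with elements `theta`,
#'   `xi`, `R`, `S`, `M`, `Minv`.
#' @examples
#' def <- affine_deformation(theta = 45, xi = 1.75)
#' det(def$M)   # exactly 1
#' @export
affine_deformation <- function(theta = 0, xi = 1) {
  R <- rotation_matrix(theta)
  S <- strain_matrix(xi)
  M <- S %*% R
  ## closed-form inverse: R^T S^{-1}
  Minv <- t(R) %*% diag(c(sqrt(xi), sqrt(xi), 1 / xi))
  structure(list(theta = theta, xi = xi, R = R, S = S, M = M, Minv = Minv),
            class = "affine_deformation")
}

#' @export
print.affine_deformation <- function(x, ...) {
  cat(sprintf("Affine deformation: theta = %g deg (about x), xi = %g (along z), det(M) = %g\n",
              x$theta, x$xi, det(x$M)))
  invisible(x)
}

#' Transformed implicit surface
#'
#' Pre-composes the surface's implicit function with the inverse affine map,
#' F_def(p) = F(M^-1 p), whose zero set is exactly the image under M of the
#' original zero set.
#'
#' @param surface an `implicit_surface` (untransformed).
#' @param deformation an [affine_deformation()].
#' @return A new `implicit_surface` carrying the composed evaluators.
#' @export
deform_surface <- function(surface, deformation) {
  stopifnot(inherits(surface, "implicit_surface"),
            inherits(deformation, "affine_deformation"))
  if (!all(surface$M == diag(3)))
    stop("surface already carries an affine map; deform the base surface")
  out <- surface
  out$M <- deformation$M
  out$minv <- deformation$Minv
  out
}

#' Push mesh vertices forward through an affine map
#'
#' Applies M to every vertex while keeping the face list, preserving
#' triangle identity (the operation behind relaxed-vs-stretched
#' correspondences). Because det(M) = 1 the enclosed volume is unchanged.
#'
#' @param mesh a [trimesh] object.
#' @param deformation an [affine_deformation()] (or any 3 x 3 matrix).
#' @return A `trimesh` with transformed vertices.
#' @export
push_forward <- function(mesh, deformation) {
  M <- if (inherits(deformation, "affine_deformation")) deformation$M else deformation
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)))
  out <- mesh
  out$vertices <- mesh$vertices %*% t(M)
  out
}
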