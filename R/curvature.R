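#' Gaussian curvature from the implicit function
#'
#' \deqn{K_G = \frac{\nabla F \cdot H^*[F] \cdot \nabla F^T}{|\nabla F|^4}}
#' where H* is the adjugate (cofactor matrix) of the Hessian. Units um^-2.
#'
#' @param surface an `implicit_surface`.
#' @param points on-surface points, 3-vector or n x 3 matrix.
#' @return Numeric vector of K_G values.
#' @export
gaussian_curvature <- function(surface, points) {
  curvature_pointwise(surface, points)$KG
}

#' Mean curvature from the implicit function
#'
#' \deqn{K_M = \frac{\nabla F \cdot H[F] \cdot \nabla F^T -
#'   |\nabla F|^2\,\mathrm{tr}(H)}{2 |\nabla F|^3}}
#' Units um^-1. Under the outward-gradient normal convention a convex body
#' has K_M < 0 (a sphere of radius r gives exactly -1/r).
#'
#' @inheritParams gaussian_curvature
#' @export
mean_curvature <- function(surface, points) {
  curvature_pointwise(surface, points)$KM
}

## K_G, K_M, k1, k2 at arbitrary points, vectorized
curvature_pointwise <- function(surface, points) {
  pts <- as_point_matrix(points)
  der <- implicit_derivatives(surface, pts)
  g <- der$gradient
  g2 <- rowSums(g^2)
  gn <- sqrt(g2)
  singular <- gn < 1e-10 * (surface$scale / 2)^3
  if (any(singular))
    stop(sprintf("singular gradient (|grad F| ~ 0) at point row(s) %s",
                 paste(utils::head(which(singular), 5), collapse = ", ")))
  qf <- function(A) {
    g[, 1]^2 * A[, 1, 1] + g[, 2]^2 * A[, 2, 2] + g[, 3]^2 * A[, 3, 3] +
      2 * (g[, 1] * g[, 2] * A[, 1, 2] + g[, 1] * g[, 3] * A[, 1, 3] +
           g[, 2] * g[, 3] * A[, 2, 3])
  }
  KG <- qf(der$adjugate) / g2^2
  KM <- (qf(der$hessian) - g2 * der$trace) / (2 * gn^3)
  pk <- principal_curvatures(KM, KG)
  list(KG = KG, KM = KM, k1 = pk$k1, k2 = pk$k2)
}

#' Principal curvatures from mean and Gaussian curvature
#'
#' k1 = K_M + sqrt(K_M^2 - K_G), k2 = K_M - sqrt(K_M^2 - K_G), so that
#' k1 >= k2, K_G = k1 k2 and K_M = (k1 + k2)/2. The discriminant is
#' non-negative for any real surface point; values above -1e-12 are clamped
#' to zero, more negative ones signal inconsistent inputs.
#'
#' @param KM mean curvature(s), um^-1.
#' @param KG Gaussian curvature(s), um^-2.
#' @return List with vectors `k1` and `k2` (um^-1).
#' @export
principal_curvatures <- function(KM, KG) {
  disc <- KM^2 - KG
  if (any(disc < -1e-12))
    stop("K_M^2 - K_G is significantly negative: inconsistent curvature inputs")
  s <- sqrt(pmax(disc, 0))
  list(k1 = KM + s, k2 = KM - s)
}

#' Per-triangle curvature field
#'
#' Assigns the four curvature types to every mesh triangle, either as the
#' average of the values at the three vertices (`"vertex_mean"`, the
#' default) or evaluated at the triangle centroid (`"centroid"`). The flat
#' centroid lies slightly off the curved surface; by default it is
#' Newton-projected onto the zero set before evaluation
#' (`project_centroid = FALSE` evaluates at the raw centroid).
#'
#' @param mesh a [trimesh] whose vertices lie on `surface`.
#' @param surface the `implicit_surface` the mesh discretizes.
#' @param mode `"vertex_mean"` or `"centroid"`.
#' @param project_centroid project centroids onto the surface first
#'   (centroid mode only).
#' @return A data frame of class `curvature_field` with columns `face`,
#'   `area_um2`, `KG_um_2`, `KM_um_1`, `k1_um_1`, `k2_um_1`; the evaluation
#'   mode is recorded in `attr(, "mode")`.
#' @export
per_triangle_curvature <- function(mesh, surface,
                                   mode = c("vertex_mean", "centroid"),
                                   project_centroid = TRUE) {
  mode <- match.arg(mode)
  f <- mesh$faces
  if (mode == "vertex_mean") {
    cv <- curvature_pointwise(surface, mesh$vertices)
    avg <- function(x) (x[f[, 1]] + x[f[, 2]] + x[f[, 3]]) / 3
    KG <- avg(cv$KG); KM <- avg(cv$KM); k1 <- avg(cv$k1); k2 <- avg(cv$k2)
    tag <- mode
  } else {
    cen <- (mesh$vertices[f[, 1], , drop = FALSE] +
            mesh$vertices[f[, 2], , drop = FALSE] +
            mesh$vertices[f[, 3], , drop = FALSE]) / 3
    if (project_centroid) cen <- project_to_surface(surface, cen)
    cv <- curvature_pointwise(surface, cen)
    KG <- cv$KG; KM <- cv$KM; k1 <- cv$k1; k2 <- cv$k2
    tag <- if (project_centroid) "centroid_projected" else "centroid_raw"
  }
  out <- data.frame(face = seq_len(nrow(f)), area_um2 = face_areas(mesh),
                    KG_um_2 = KG, KM_um_1 = KM, k1_um_1 = k1, k2_um_1 = k2)
  attr(out, "mode") <- tag
  class(out) <- c("curvature_field", class(out))
  out
}

#' Area-weighted average of a per-triangle field
#'
#' \deqn{\bar\kappa = \frac{\sum_i \mathrm{area}_i\,\kappa_i}
#'   {\sum_i \mathrm{area}_i}}
#'
#' @param values per-triangle values.
#' @param areas per-triangle areas (um^2), non-negative with positive total.
#' @export
weighted_average_curvature <- function(values, areas) {
  stopifnot(length(values) == length(areas), all(areas >= 0))
  tot <- sum(areas)
  if (tot <= 0) stop("total area must be positive")
  sum(areas * values) / tot
}

#' Total Gaussian curvature (Gauss-Bonnet check)
#'
#' Sum of K_G x area over all triangles; for any closed genus-0 surface the
#' exact integral is 2 pi chi = 4 pi steradians, independent of deformation.
#'
#' @param KG per-triangle Gaussian curvature (um^-2), or a `curvature_field`.
#' @param areas per-triangle areas (um^2); ignored when `KG` is a field.
#' @export
total_gaussian_curvature <- function(KG, areas = NULL) {
  if (inherits(KG, "curvature_field")) {
    areas <- KG$area_um2
    KG <- KG$KG_um_2
  }
  sum(KG * areas)
}
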