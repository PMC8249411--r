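# Independent oracles used across the suite. These never call the
# implicit-function curvature path they are checking.

# central finite differences of the implicit function
fd_gradient <- function(surface, p, h = 1e-5) {
  vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (implicit_value(surface, p + e) - implicit_value(surface, p - e)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(surface, p, h = 1e-4) {
  H <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    ei <- numeric(3); ei[i] <- h
    ej <- numeric(3); ej[j] <- h
    H[i, j] <- (implicit_value(surface, p + ei + ej) -
                implicit_value(surface, p + ei - ej) -
                implicit_value(surface, p - ei + ej) +
                implicit_value(surface, p - ei - ej)) / (4 * h^2)
  }
  H
}

# Parametric differential geometry of the ellipsoid (first and second
# fundamental forms with exact parametric derivatives). Normal is r_u x r_v,
# which points outward for this parametrization, so the mean curvature sign
# matches the outward-gradient convention (convex => negative).
ellipsoid_param_curvature <- function(axes, u, v) {
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  cu <- cos(u); su <- sin(u); cv <- cos(v); sv <- sin(v)
  r   <- cbind(a * cu * cv, b * su * cv, c * sv)
  ru  <- cbind(-a * su * cv, b * cu * cv, 0)
  rv  <- cbind(-a * cu * sv, -b * su * sv, c * cv)
  ruu <- cbind(-a * cu * cv, -b * su * cv, 0)
  ruv <- cbind(a * su * sv, -b * cu * sv, 0)
  rvv <- cbind(-a * cu * cv, -b * su * cv, -c * sv)
  cross <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                                p[, 3] * q[, 1] - p[, 1] * q[, 3],
                                p[, 1] * q[, 2] - p[, 2] * q[, 1])
  E <- rowSums(ru * ru); Ff <- rowSums(ru * rv); G <- rowSums(rv * rv)
  n <- cross(ru, rv)
  n <- n / sqrt(rowSums(n^2))
  L <- rowSums(ruu * n); M <- rowSums(ruv * n); N <- rowSums(rvv * n)
  den <- E * G - Ff^2
  list(points = r,
       KG = (L * N - M^2) / den,
       KM = (E * N - 2 * Ff * M + G * L) / (2 * den))
}

# random points on an implicit surface: seeded box samples Newton-projected
# onto the zero set
random_on_surface <- function(surface, n, seed = 42) {
  set.seed(seed)
  hw <- surface$halfwidths
  raw <- cbind(runif(3 * n, -hw[1], hw[1]),
               runif(3 * n, -hw[2], hw[2]),
               runif(3 * n, -hw[3], hw[3]))
  pts <- project_to_surface(surface, raw)
  ok <- abs(implicit_value(surface, pts)) < surface_tolerance(surface)
  pts <- pts[ok, , drop = FALSE]
  stopifnot(nrow(pts) >= n)
  pts[seq_len(n), , drop = FALSE]
}

# Gaussian curvature at the discocyte rim from the profile curve of
# revolution: meridional curvature -rho''(z) at z = 0 times the parallel
# curvature 1/rho(0) (both principal directions curve the same way there).
rim_KG_profile_oracle <- function(coeffs, h = 1e-4) {
  P <- coeffs$P; Q <- coeffs$Q; R <- coeffs$R
  rho <- function(z) {
    u <- (-(2 * z^2 + P) + sqrt((2 * z^2 + P)^2 - 4 * (z^4 + Q * z^2 + R))) / 2
    sqrt(u)
  }
  rpp <- (rho(h) - 2 * rho(0) + rho(-h)) / h^2
  (-rpp) * (1 / rho(0))
}
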