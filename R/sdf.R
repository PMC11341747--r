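## Signed-distance primitives used to build implicit lumen models.
## All functions take an n x 3 matrix of points (mm) and return a numeric
## vector: negative inside, positive outside, ~distance in mm near the surface.

#' Signed distance to a capsule (cylinder with spherical ends)
#'
#' @param p n x 3 matrix of query points (mm).
#' @param a,b segment end points (length-3 vectors, mm).
#' @param r capsule radius (mm).
#' @return numeric vector of signed distances (mm).
#' @keywords internal
sdfCapsule <- function(p, a, b, r) {
  ab <- b - a
  ap <- sweep(p, 2, a)
  denom <- sum(ab * ab)
  t <- if (denom > 0) pmin(1, pmax(0, (ap %*% ab)[, 1] / denom)) else 0
  dx <- ap[, 1] - t * ab[1]
  dy <- ap[, 2] - t * ab[2]
  dz <- ap[, 3] - t * ab[3]
  sqrt(dx * dx + dy * dy + dz * dz) - r
}

#' Approximate signed distance to an axis-aligned spheroid
#'
#' Equatorial semi-axis `req` in x/y, polar semi-axis `rz` along z, after
#' shifting by `center`. Uses the scaled-gradient approximation, accurate
#' near the surface (where the isosurfacer samples it).
#'
#' @keywords internal
sdfSpheroid <- function(p, center, req, rz) {
  q <- sweep(p, 2, center)
  k1 <- sqrt((q[, 1] / req)^2 + (q[, 2] / req)^2 + (q[, 3] / rz)^2)
  k2 <- sqrt((q[, 1] / req^2)^2 + (q[, 2] / req^2)^2 + (q[, 3] / rz^2)^2)
  out <- k1 * (k1 - 1) / pmax(k2, .Machine$double.eps)
  ## at the exact center k1 = k2 = 0; fall back to -min semi-axis
  out[k1 == 0] <- -min(req, rz)
  out
}

## Spheroid with its polar axis along coordinate `axis_dim`.
sdfSpheroidAxis <- function(p, center, req, rpol, axis_dim = 3L) {
  if (axis_dim == 3L) return(sdfSpheroid(p, center, req, rpol))
  perm <- if (axis_dim == 1L) c(3L, 2L, 1L) else c(1L, 3L, 2L)
  sdfSpheroid(p[, perm, drop = FALSE], center[perm], req, rpol)
}

#' Signed distance to a half-space
#'
#' Negative on the side the normal points away from: f = (p - origin) . n.
#' @keywords internal
sdfHalfspace <- function(p, origin, normal) {
  sweep(p, 2, origin) %*% normal
}

## Numerical gradient of an sdf closure, central differences, vectorized
## over points. Used for contact projection and contour refinement.
sdfGradient <- function(f, p, eps = 1e-4) {
  n <- nrow(p)
  g <- matrix(0, n, 3)
  for (d in 1:3) {
    pp <- p; pp[, d] <- pp[, d] + eps
    pm <- p; pm[, d] <- pm[, d] - eps
    g[, d] <- (f(pp) - f(pm)) / (2 * eps)
  }
  g
}
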