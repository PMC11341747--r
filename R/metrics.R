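## Hemodynamic metrics: plane fluxes, wall shear stress, and the
## treated-versus-untreated comparison statistics.

#' Define a sampling plane
#'
#' A disk of given radius around `origin`, oriented by `normal`, clipped
#' to the lumen at integration time.
#'
#' @param origin plane origin (mm). @param normal plane normal (unit
#'   vector; for a neck plane, oriented into the sac; for a daughter
#'   plane, along the flow direction).
#' @param radius bounding disk radius (mm).
#' @param role `"neck"` or `"daughter"`.
#' @return a `samplingPlane`.
#' @export
samplingPlane <- function(origin, normal, radius,
                          role = c("neck", "daughter")) {
  role <- match.arg(role)
  n <- normal / sqrt(sum(normal^2))
  stopifnot(radius > 0)
  structure(list(origin = origin, normal = n, radius = radius, role = role),
            class = "samplingPlane")
}

#' Directional influx through a sampling plane
#'
#' Integrates `max(0, u . n)` (mode `"influx"`, the default reading of
#' "total flow entering") or the signed net flux (mode `"net"`) over the
#' plane clipped to the lumen, by midpoint quadrature at sub-cell
#' resolution with trilinear velocity interpolation.
#'
#' @param field a `flowField`. @param plane a `samplingPlane`.
#' @param mode `"influx"` or `"net"`.
#' @return flux in ml/min.
#' @export
integrateInflux <- function(field, plane, mode = c("influx", "net")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "flowField"), inherits(plane, "samplingPlane"))
  if (!isTRUE(field$converged))
    stop("flow field is not converged")
  mesh <- field$mesh
  dq <- mesh$h / 3
  n <- plane$normal
  e1 <- if (abs(n[3]) < 0.9) .cross3(n, c(0, 0, 1)) else .cross3(n, c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(n, e1)
  g <- seq(-plane$radius + dq / 2, plane$radius, by = dq)
  uv <- as.matrix(expand.grid(u = g, v = g))
  uv <- uv[uv[, 1]^2 + uv[, 2]^2 <= plane$radius^2, , drop = FALSE]
  pts <- sweep(outer(uv[, 1], e1) + outer(uv[, 2], e2), 2, plane$origin, "+")
  sdf <- mesh$geom$sdf_open
  inside <- sdf(pts) < 0
  if (!any(inside))
    stop("sampling plane lies outside the flow domain")
  pts <- pts[inside, , drop = FALSE]
  vel <- interpolateVelocity(field, pts)
  un <- as.numeric(vel %*% n)
  if (mode == "influx") un <- pmax(0, un)
  mm3sToMlMin(sum(un) * dq^2)
}

#' Interpolate the velocity field at arbitrary points
#'
#' Component-wise trilinear interpolation on the staggered grids.
#'
#' @param field a `flowField`. @param pts n x 3 matrix (mm).
#' @return n x 3 matrix of velocities (mm/s).
#' @export
interpolateVelocity <- function(field, pts) {
  mesh <- field$mesh
  out <- matrix(0, nrow(pts), 3)
  arrs <- list(field$U, field$V, field$W)
  for (d in 1:3) {
    A <- arrs[[d]]
    fd <- dim(A)
    off <- rep(0.5, 3); off[d] <- 0
    ## fractional index of each point in this face grid
    fi <- sweep(sweep(pts, 2, mesh$origin), 2, rep(mesh$h, 3), "/")
    fi <- sweep(fi, 2, off - 1, "-")         # 1-based fractional index
    i0 <- pmin(pmax(floor(fi), 1), matrix(rep(fd - 1L, each = nrow(fi)),
                                          ncol = 3))
    t <- fi - i0
    t <- pmin(pmax(t, 0), 1)
    acc <- numeric(nrow(pts))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (dx * t[, 1] + (1 - dx) * (1 - t[, 1])) *
           (dy * t[, 2] + (1 - dy) * (1 - t[, 2])) *
           (dz * t[, 3] + (1 - dz) * (1 - t[, 3]))
      idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
      acc <- acc + w * A[idx]
    }
    out[, d] <- acc
  }
  out
}

#' Interpolate the pressure field at arbitrary points
#' @param field a `flowField`. @param pts n x 3 matrix (mm).
#' @return pressures (Pa).
#' @export
interpolatePressure <- function(field, pts) {
  mesh <- field$mesh
  A <- field$P
  fi <- sweep(sweep(pts, 2, mesh$origin), 2, rep(mesh$h, 3), "/") + 0.5
  i0 <- pmin(pmax(floor(fi), 1),
             matrix(rep(mesh$nc - 1L, each = nrow(fi)), ncol = 3))
  t <- pmin(pmax(fi - i0, 0), 1)
  acc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * t[, 1] + (1 - dx) * (1 - t[, 1])) *
         (dy * t[, 2] + (1 - dy) * (1 - t[, 2])) *
         (dz * t[, 3] + (1 - dz) * (1 - t[, 3]))
    acc <- acc + w * A[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  acc
}

#' Wall shear stress over a named wall region
#'
#' WSS is the viscosity times the magnitude of the wall-tangential
#' velocity gradient, evaluated by two-point extrapolation along the
#' inward wall normal (second-order accurate near the wall). Wall sample
#' points are the lumen surface triangle centroids of the named region;
#' cap triangles are excluded.
#'
#' @param field a `flowField`.
#' @param region `"wall"` (whole lumen), `"sac"`, `"neck"`,
#'   `"daughter1"`, `"daughter2"` or `"parent"`.
#' @param neck_plane optional `list(origin, normal)` used for the
#'   `"neck"` region (defaults to the geometry's measured neck plane).
#' @param probe probe depth for the near-wall fit, in grid spacings
#'   (samples at `probe * h` and `2 * probe * h`; default 2.5 keeps the
#'   fit clear of the immersed-boundary interpolation layer).
#' @return list with `samples` (points, wss values in Pa), `wss_max`
#'   (field maximum over the region) and `wss_p99` (99th percentile,
#'   robust variant, reported alongside, never substituted).
#' @export
wallShearStress <- function(field, region = "wall", neck_plane = NULL,
                            probe = 2.5) {
  stopifnot(inherits(field, "flowField"))
  if (!isTRUE(field$converged)) stop("flow field is not converged")
  geom <- field$mesh$geom
  ctr <- meshCentroids(geom$vertices, geom$triangles)
  capids <- c(geom$cap_labels$inlet, unlist(geom$cap_labels$outlets))
  iswall <- rep(TRUE, nrow(ctr))
  if (length(capids)) iswall[capids] <- FALSE
  keep <- iswall & .regionMask(geom, ctr, region, neck_plane)
  if (!any(keep))
    stop("region '", region, "' has no wall faces")
  P <- ctr[keep, , drop = FALSE]
  sdf <- geom$sdf_open
  g <- sdfGradient(sdf, P)
  nrm <- g / pmax(sqrt(rowSums(g * g)), 1e-12)    # outward
  h <- field$mesh$h
  d1 <- probe * h
  u1 <- interpolateVelocity(field, P - nrm * d1)
  u2 <- interpolateVelocity(field, P - nrm * 2 * d1)
  ## tangential parts
  u1t <- u1 - nrm * rowSums(u1 * nrm)
  u2t <- u2 - nrm * rowSums(u2 * nrm)
  ## u(d) = a d + b d^2  =>  a = (4 u1 - u2) / (2 d1)
  a <- (4 * u1t - u2t) / (2 * d1)
  wss <- field$fluid$dynamic_viscosity * sqrt(rowSums(a * a))
  list(samples = data.frame(x = P[, 1], y = P[, 2], z = P[, 3], wss = wss),
       wss_max = max(wss),
       wss_p99 = as.numeric(stats::quantile(wss, 0.99, names = FALSE)))
}

.regionMask <- function(geom, ctr, region, neck_plane = NULL) {
  if (region == "wall") return(rep(TRUE, nrow(ctr)))
  e <- if (is.finite(geom$edge_length)) geom$edge_length else 0.3
  if (region == "sac") {
    if (is.null(geom$sdf_dome)) stop("geometry has no sac")
    ax <- geom$dome$axis
    m <- abs(geom$sdf_dome(ctr)) < 0.35 * e &
      as.numeric(ctr %*% ax) > geom$dome$neck_s + 0.35 * e
    if (!is.null(geom$sdf_vessel)) m <- m & geom$sdf_vessel(ctr) > 0.3 * e
    return(m)
  }
  if (region == "neck") {
    np <- neck_plane
    if (is.null(np)) {
      if (is.null(geom$dome)) stop("geometry has no neck")
      ax <- geom$dome$axis
      np <- list(origin = geom$dome$center +
                   (geom$dome$neck_s - sum(geom$dome$center * ax)) * ax,
                 normal = ax)
    }
    s <- as.numeric(sweep(ctr, 2, np$origin) %*% np$normal)
    return(abs(s) < 2 * e)
  }
  if (region %in% c("daughter1", "daughter2", "parent")) {
    cl <- geom$centerlines[[region]]
    if (is.null(cl)) stop("no centerline for region ", region)
    a <- cl[1, ]; b <- cl[nrow(cl), ]
    ab <- b - a
    t <- pmin(1, pmax(0, sweep(ctr, 2, a) %*% ab / sum(ab^2)))
    dvec <- sweep(ctr, 2, a) - outer(as.numeric(t), ab)
    rad <- if (region == "parent") geom$parent_diameter / 2
           else geom$daughter_diameters[as.integer(substr(region, 9, 9))] / 2
    return(sqrt(rowSums(dvec^2)) < rad + 0.5 * e & t > 0.05 & t < 0.98)
  }
  stop("unknown region: ", region)
}

#' Percentage reduction of a flow metric
#'
#' `100 * (1 - Q_treated / Q_untreated)`, reported to one decimal place
#' (half away from zero).
#' @param q_untreated,q_treated flows (ml/min), untreated > 0.
#' @export
percentReduction <- function(q_untreated, q_treated) {
  if (any(q_untreated <= 0)) stop("untreated flow must be positive")
  if (any(q_treated < 0)) stop("flows must be non-negative")
  roundHalfAway(100 * (1 - q_treated / q_untreated), 1)
}

#' Signed relative change of a flow metric
#'
#' `100 * (Q_device - Q_baseline) / Q_baseline`, reported to two decimal
#' places (half away from zero).
#' @param q_baseline,q_device flows (ml/min), baseline > 0.
#' @export
relativeChange <- function(q_baseline, q_device) {
  if (any(q_baseline <= 0)) stop("baseline flow must be positive")
  roundHalfAway(100 * (q_device - q_baseline) / q_baseline, 2)
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 -> 1, -0.5 -> -1), the convention used for
#' the reported comparison tables (base R `round` rounds half to even).
#' @param x numeric. @param digits decimal places.
#' @export
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Treated-versus-untreated comparison report
#'
#' Builds the per-case device comparison: percentage reductions in
#' aneurysm inflow per device, signed relative changes in
#' daughter-vessel inflow, and cross-case arithmetic means of the
#' (rounded, table-style) per-case values.
#'
#' @param cases a list; each element is a list with `id` and two named
#'   numeric vectors, `Q_in` and `Q_in_DV`, each with an `nd` (no
#'   device) entry plus one entry per device arm (e.g. `stent`,
#'   `contour`), in ml/min.
#' @return list with data frames `inflow` (id, device, Q_in, reduction)
#'   and `daughter` (id, device, Q_in_DV, relative_change), and
#'   `averages` (mean reduction and mean relative change per device).
#' @export
comparisonReport <- function(cases) {
  if (length(cases) < 1) stop("at least one case is required")
  inflow <- daughter <- NULL
  for (cs in cases) {
    if (is.null(cs$Q_in) || !("nd" %in% names(cs$Q_in)))
      stop("mismatched case pairing: each case needs Q_in['nd'] plus ",
           "device arms")
    devs <- setdiff(names(cs$Q_in), "nd")
    for (dv in devs)
      inflow <- rbind(inflow, data.frame(
        id = cs$id, device = dv, Q_in = cs$Q_in[[dv]],
        reduction = percentReduction(cs$Q_in[["nd"]], cs$Q_in[[dv]])))
    if (!is.null(cs$Q_in_DV)) {
      if (!("nd" %in% names(cs$Q_in_DV)))
        stop("mismatched case pairing: Q_in_DV without an 'nd' baseline")
      for (dv in setdiff(names(cs$Q_in_DV), "nd"))
        daughter <- rbind(daughter, data.frame(
          id = cs$id, device = dv, Q_in_DV = cs$Q_in_DV[[dv]],
          relative_change = relativeChange(cs$Q_in_DV[["nd"]],
                                           cs$Q_in_DV[[dv]])))
    }
  }
  avg <- list()
  for (dv in unique(inflow$device))
    avg[[paste0("reduction_", dv)]] <-
      roundHalfAway(mean(inflow$reduction[inflow$device == dv]), 2)
  if (!is.null(daughter))
    for (dv in unique(daughter$device))
      avg[[paste0("dv_change_", dv)]] <-
        roundHalfAway(mean(daughter$relative_change[daughter$device == dv]),
                      2)
  list(inflow = inflow, daughter = daughter, averages = avg)
}
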