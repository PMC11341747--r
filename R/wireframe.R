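## Strut-level device wireframes.
##
## A wireframe is the geometric realization of a device: node positions
## (mm), struts as node-index pairs, a wire id per strut, and the
## stress-free reference node positions. The braided flow-diverter is two
## counter-rotating helix families on a cylinder; the Contour is a
## dual-layer braided bowl (truncated spherical cap) with its largest
## diameter at the open rim and an inert marker node at the pole.

#' Build a braided flow-diverter (stent) wireframe
#'
#' @param diameter nominal (free-expansion) diameter, mm.
#' @param length nominal device length, mm.
#' @param wires total wire count (even, >= 4); half per helix family.
#' @param braid_angle angle (degrees) between each wire and the device
#'   axis, strictly between 0 and 90.
#' @param strut_radius wire radius, mm. The default is calibrated so the
#'   deployed-cylinder porosity of the default braid is ~60%.
#' @param node_spacing target strut length, mm.
#' @return object of class `wireframe`; the reference (stress-free) state
#'   equals the construction state.
#' @export
buildBraidedStent <- function(diameter, length, wires = 48,
                              braid_angle = 45, strut_radius = 0.022,
                              node_spacing = 0.6) {
  stopifnot(diameter > 0, length > 0, strut_radius > 0)
  if (wires %% 2 != 0 || wires < 4)
    stop("wires must be even and >= 4")
  if (braid_angle <= 0 || braid_angle >= 90)
    stop("braid_angle must lie strictly in (0, 90) degrees")
  R <- diameter / 2
  tanb <- tan(braid_angle * pi / 180)
  pitch <- 2 * pi * R / tanb        # axial length of one full turn
  if (pitch > length)
    stop("geometric infeasibility: helix pitch ", round(pitch, 2),
         " mm exceeds device length ", length, " mm")
  dz <- node_spacing * cos(braid_angle * pi / 180)
  nseg <- max(4L, round(length / dz))
  z <- seq(0, length, length.out = nseg + 1)
  m <- wires / 2
  nodes <- NULL; struts <- NULL; wid <- NULL
  wcount <- 0L
  for (fam in c(1, -1)) {
    off <- if (fam == 1) 0 else pi / m
    for (w in seq_len(m)) {
      th <- 2 * pi * (w - 1) / m + off + fam * z * tanb / R
      P <- cbind(z, R * cos(th), R * sin(th))
      base <- if (is.null(nodes)) 0L else nrow(nodes)
      nodes <- rbind(nodes, P)
      wcount <- wcount + 1L
      struts <- rbind(struts, cbind(base + seq_len(nseg),
                                    base + seq_len(nseg) + 1L))
      wid <- c(wid, rep(wcount, nseg))
    }
  }
  .newWireframe(nodes, struts, wid, strut_radius,
                family = "braided_stent",
                nominal_diameter = diameter, nominal_length = length,
                params = list(wires = wires, braid_angle = braid_angle,
                              node_spacing = node_spacing))
}

#' Build a Contour-style dual-layer braided bowl wireframe
#'
#' The stress-free shape is the lower half of a sphere: a truncated
#' spherical cap whose open rim (the equator, largest diameter) has the
#' nominal diameter. Wires run as spherical spirals from a small polar
#' opening to the rim, in two counter-rotating families per layer; the
#' second layer is a concentric bowl offset inwards by
#' `2.5 * strut_radius`. The proximal platinum marker is a single inert
#' node at the pole (no struts).
#'
#' @param diameter nominal rim diameter, mm; must be one of the
#'   catalogued sizes {5, 7, 9, 11, 14} unless `allow_any = TRUE`.
#' @param wires_per_layer wires per layer (catalogue: 72).
#' @param layers braid layers (catalogue: 2).
#' @param strut_radius wire radius, mm.
#' @param spiral_turns azimuthal advance (fraction of a turn) of each
#'   wire from pole to rim.
#' @param nodes_per_wire nodes per wire.
#' @param allow_any allow non-catalogue diameters.
#' @return a `wireframe` with the device axis along +x (pole at the
#'   origin, rim in the plane x = diameter/2).
#' @export
buildContour <- function(diameter, wires_per_layer = 72, layers = 2,
                         strut_radius = 0.015, spiral_turns = 0.35,
                         nodes_per_wire = 16, allow_any = FALSE) {
  if (!allow_any && !(diameter %in% c(5, 7, 9, 11, 14)))
    stop("unsupported Contour diameter ", diameter,
         " mm (catalogue sizes: 5, 7, 9, 11, 14; use allow_any = TRUE ",
         "to override)")
  stopifnot(diameter > 0, wires_per_layer >= 2, layers >= 1,
            strut_radius > 0, nodes_per_wire >= 4)
  R <- diameter / 2
  gap <- 2.5 * strut_radius
  alpha <- seq(0.12, pi / 2, length.out = nodes_per_wire)  # pole -> rim
  nodes <- matrix(c(0, 0, 0), 1, 3)                        # marker node
  struts <- NULL; wid <- NULL
  wcount <- 0L
  for (l in seq_len(layers)) {
    Rl <- R - (l - 1) * gap
    for (fam in c(1, -1)) {
      nw <- ceiling(wires_per_layer / 2)
      if (fam == -1) nw <- wires_per_layer - nw
      for (w in seq_len(nw)) {
        th0 <- 2 * pi * (w - 1) / nw + (if (fam == -1) pi / nw else 0) +
          (l - 1) * pi / wires_per_layer
        th <- th0 + fam * spiral_turns * 2 * pi * (alpha / (pi / 2))
        P <- cbind(Rl * (1 - cos(alpha)),
                   Rl * sin(alpha) * cos(th),
                   Rl * sin(alpha) * sin(th))
        base <- nrow(nodes)
        nodes <- rbind(nodes, P)
        wcount <- wcount + 1L
        n <- length(alpha)
        struts <- rbind(struts, cbind(base + seq_len(n - 1),
                                      base + seq_len(n - 1) + 1L))
        wid <- c(wid, rep(wcount, n - 1))
      }
    }
  }
  .newWireframe(nodes, struts, wid, strut_radius, family = "contour",
                nominal_diameter = diameter, nominal_length = R,
                params = list(wires_per_layer = wires_per_layer,
                              layers = layers, spiral_turns = spiral_turns,
                              layer_gap = gap, marker_node = 1L))
}

.newWireframe <- function(nodes, struts, wire_id, strut_radius, family,
                          nominal_diameter, nominal_length, params) {
  storage.mode(struts) <- "integer"
  len <- sqrt(rowSums((nodes[struts[, 1], , drop = FALSE] -
                       nodes[struts[, 2], , drop = FALSE])^2))
  if (any(len <= 0)) stop("degenerate wireframe: zero-length strut")
  structure(list(nodes = nodes, struts = struts, wire_id = wire_id,
                 reference_nodes = nodes, strut_radius = strut_radius,
                 rest_lengths = len, family = family,
                 nominal_diameter = nominal_diameter,
                 nominal_length = nominal_length, params = params),
            class = "wireframe")
}

#' @export
print.wireframe <- function(x, ...) {
  cat("wireframe (", x$family, "): ", nrow(x$nodes), " nodes, ",
      nrow(x$struts), " struts, ", length(unique(x$wire_id)), " wires\n",
      sep = "")
  cat("  nominal diameter ", x$nominal_diameter, " mm, strut radius ",
      x$strut_radius, " mm\n", sep = "")
  invisible(x)
}

#' Porosity of a wireframe on its reference surface
#'
#' Porosity = 1 - (metal area projected onto the reference surface) /
#' (reference surface area). The metal footprint is rasterized on a
#' surface parameterization at sub-strut-width resolution, which accounts
#' for strut overlap at crossings exactly (overlapping cells are counted
#' once).
#'
#' @param frame a `wireframe`.
#' @param reference_surface list describing the carrier surface:
#'   `list(type = "cylinder", radius, length)` (axis +x),
#'   `list(type = "bowl", radius)` (truncated spherical cap, axis +x,
#'   pole at origin), or `list(type = "flat", width, height)` (the x-y
#'   plane patch `[0,width] x [0,height]`).
#' @param tol maximum allowed node distance from the surface (default
#'   covers the dual-layer gap).
#' @param resolution raster cell size, mm (default `strut_radius / 2`).
#' @return porosity as a fraction in [0, 1].
#' @export
computePorosity <- function(frame, reference_surface, tol = 0.2,
                            resolution = frame$strut_radius / 2) {
  stopifnot(inherits(frame, "wireframe"))
  rs <- reference_surface
  w <- 2 * frame$strut_radius
  N <- frame$nodes
  mk <- frame$params$marker_node
  used <- sort(unique(as.vector(frame$struts)))
  if (rs$type == "cylinder") {
    d <- abs(sqrt(N[used, 2]^2 + N[used, 3]^2) - rs$radius)
    if (max(d) > tol)
      stop("frame not on surface: node ", round(max(d), 3),
           " mm off the reference cylinder")
    u <- atan2(N[, 3], N[, 2]) * rs$radius       # unrolled circumference
    v <- N[, 1]
    circ <- 2 * pi * rs$radius
    .rasterPorosity(frame$struts, u, v, w, circ, rs$length, resolution,
                    wrap_u = circ)
  } else if (rs$type == "bowl") {
    rad <- sqrt((N[used, 1] - rs$radius)^2 + N[used, 2]^2 + N[used, 3]^2)
    if (max(abs(rad - rs$radius)) > tol)
      stop("frame not on surface: node ",
           round(max(abs(rad - rs$radius)), 3),
           " mm off the reference bowl")
    ## parameterize by arc from pole (u) and azimuth scaled to arc (v)
    q <- N; q[, 1] <- q[, 1] - rs$radius
    alpha <- acos(pmin(1, pmax(-1, -q[, 1] / rs$radius)))
    u <- rs$radius * alpha
    th <- atan2(q[, 3], q[, 2])
    ## area element: R sin(alpha) dtheta * R dalpha; weight by sin(alpha)
    .rasterPorosityBowl(frame$struts, u, th, alpha, w, rs$radius,
                        resolution)
  } else if (rs$type == "flat") {
    if (max(abs(N[used, 3])) > tol)
      stop("frame not on surface: node off the reference plane")
    .rasterPorosity(frame$struts, N[, 1], N[, 2], w, rs$width, rs$height,
                    resolution, wrap_u = NA)
  } else stop("unknown reference surface type: ", rs$type)
}

## Rasterize strut coverage on a [0,U] x [0,V] parameter patch.
.rasterPorosity <- function(struts, u, v, w, U, V, res, wrap_u = NA) {
  nu <- max(8L, ceiling(U / res)); nv <- max(8L, ceiling(V / res))
  du <- U / nu; dv <- V / nv
  cov <- matrix(FALSE, nu, nv)
  if (!is.na(wrap_u)) u <- u %% wrap_u
  segs <- cbind(u[struts[, 1]], v[struts[, 1]], u[struts[, 2]],
                v[struts[, 2]])
  ## duplicate seam-crossing segments on a wrapped parameterization
  if (!is.na(wrap_u)) {
    cross <- abs(segs[, 1] - segs[, 3]) > wrap_u / 2
    s2 <- segs[cross, , drop = FALSE]
    s2[, 1] <- s2[, 1] + ifelse(s2[, 1] < s2[, 3], wrap_u, -wrap_u)
    s3 <- segs[cross, , drop = FALSE]
    s3[, 3] <- s3[, 3] + ifelse(s3[, 3] < s3[, 1], wrap_u, -wrap_u)
    segs <- rbind(segs[!cross, , drop = FALSE], s2, s3)
  }
  hw <- w / 2
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, ]
    i0 <- max(1L, floor((min(s[1], s[3]) - hw) / du) + 1L)
    i1 <- min(nu, ceiling((max(s[1], s[3]) + hw) / du))
    j0 <- max(1L, floor((min(s[2], s[4]) - hw) / dv) + 1L)
    j1 <- min(nv, ceiling((max(s[2], s[4]) + hw) / dv))
    if (i0 > i1 || j0 > j1) next
    uc <- (seq(i0, i1) - 0.5) * du
    vc <- (seq(j0, j1) - 0.5) * dv
    eu <- s[3] - s[1]; ev <- s[4] - s[2]
    L2 <- eu^2 + ev^2
    pu <- outer(uc - s[1], rep(1, length(vc)))
    pv <- outer(rep(1, length(uc)), vc - s[2])
    t <- pmin(1, pmax(0, (pu * eu + pv * ev) / L2))
    d2 <- (pu - t * eu)^2 + (pv - t * ev)^2
    cov[i0:i1, j0:j1] <- cov[i0:i1, j0:j1] | (d2 <= hw^2)
  }
  1 - sum(cov) / (nu * nv)
}

## Bowl variant: raster in (arc-from-pole, azimuth) with sin(alpha)
## area weights and azimuth wrap.
.rasterPorosityBowl <- function(struts, u, th, alpha, w, R, res) {
  U <- R * pi / 2
  nu <- max(8L, ceiling(U / res))
  nthet <- max(8L, ceiling(2 * pi * R / res))
  du <- U / nu; dth <- 2 * pi / nthet
  cov <- matrix(FALSE, nu, nthet)
  hw <- w / 2
  th <- th %% (2 * pi)
  for (k in seq_len(nrow(struts))) {
    a <- struts[k, 1]; b <- struts[k, 2]
    np <- max(2L, ceiling(sqrt((u[a] - u[b])^2 +
             (R * mean(sin(alpha[c(a, b)])) *
              .angDiff(th[a], th[b]))^2) / (res)))
    tt <- seq(0, 1, length.out = np)
    uu <- u[a] + tt * (u[b] - u[a])
    t2 <- th[a] + tt * .angDiff(th[a], th[b])
    aa <- alpha[a] + tt * (alpha[b] - alpha[a])
    ii <- pmin(nu, pmax(1L, ceiling(uu / du)))
    ru <- ceiling(hw / du)
    rth <- pmin(nthet, ceiling(hw / (pmax(R * sin(aa), 1e-6) * dth)))
    for (q in seq_len(np)) {
      is <- max(1L, ii[q] - ru):min(nu, ii[q] + ru)
      jj <- (ceiling(t2[q] %% (2 * pi) / dth) + (-rth[q]:rth[q]))
      jj <- ((jj - 1L) %% nthet) + 1L
      cov[is, jj] <- TRUE
    }
  }
  wts <- sin(((seq_len(nu) - 0.5) * du) / R)
  1 - sum(cov * wts) / (sum(wts) * nthet)
}

.angDiff <- function(a, b) {
  d <- (b - a) %% (2 * pi)
  if (d > pi) d <- d - 2 * pi
  d
}
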