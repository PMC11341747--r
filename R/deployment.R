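## Fast virtual deployment.
##
## The device is crimped onto a delivery path (braid kinematics: strut
## lengths are preserved, so the braid elongates as the radius shrinks),
## released progressively from the distal to the proximal side with
## respect to the aneurysm sac, and relaxed to equilibrium by damped
## gradient descent on an elastic energy with two terms: linear stretch
## springs along struts (rest lengths from the stress-free reference) and
## a stress-free-shape restoring term that maps the reference shape onto
## the delivery path by parallel transport (the bending/torsion
## surrogate). The vessel wall is rigid and frictionless: penetrating
## nodes are projected back onto the lumen surface each iteration.

#' Construct a delivery path
#'
#' @param points k x 3 matrix of polyline points (mm), proximal first;
#'   the far end is the distal end with respect to the deployment.
#' @param role `"vessel"` (centerline, braided stent) or `"neck"`
#'   (neck-to-dome path, Contour).
#' @return a `deliveryPath` with arc lengths and parallel-transported
#'   cross-section frames.
#' @export
deliveryPath <- function(points, role = c("vessel", "neck")) {
  role <- match.arg(role)
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a delivery path needs at least 2 points")
  seg <- diff(points)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("degenerate delivery path: repeated points")
  tang <- seg / len
  ## parallel transport of an initial normal along the polyline
  t1 <- tang[1, ]
  ## frame convention: a path along +x carries n1 = +y, n2 = +z, so
  ## mapping reference coordinates onto a straight +x path is an
  ## identity placement
  ref <- if (abs(t1[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  n1 <- ref - sum(ref * t1) * t1
  n1 <- n1 / sqrt(sum(n1^2))
  N1 <- matrix(0, nrow(tang), 3)
  N1[1, ] <- n1
  for (i in seq_len(nrow(tang) - 1)) {
    a <- tang[i, ]; b <- tang[i + 1, ]
    v <- .cross3(a, b); s <- sqrt(sum(v^2)); cth <- sum(a * b)
    n <- N1[i, ]
    if (s > 1e-12) {
      k <- v / s
      n <- n * cth + .cross3(k, n) * s + k * sum(k * n) * (1 - cth)
    }
    n <- n - sum(n * b) * b
    N1[i + 1, ] <- n / sqrt(sum(n^2))
  }
  N2 <- t(apply(cbind(tang, N1), 1, function(r) .cross3(r[1:3], r[4:6])))
  structure(list(points = points, role = role, seg_len = len,
                 arc = c(0, cumsum(len)), tang = tang, n1 = N1, n2 = N2),
            class = "deliveryPath")
}

#' Total arc length of a delivery path
#' @param path a `deliveryPath`.
#' @export
pathLength <- function(path) path$arc[length(path$arc)]

#' Delivery path along parent and one daughter centerline
#'
#' Concatenates the parent centerline with the chosen daughter
#' centerline and rounds the bend at the bifurcation with a quadratic
#' fillet, so a stent mapped along the path bends smoothly instead of
#' kinking at the carina.
#'
#' @param geom a `bifurcationGeometry` with daughters.
#' @param daughter index (1 or 2) of the branch the stent lands in.
#' @param fillet fillet half-length at the bend (mm).
#' @param n_fillet sample count along the fillet.
#' @return a `deliveryPath`.
#' @export
stentPath <- function(geom, daughter = 1L, fillet = 2, n_fillet = 9) {
  p0 <- geom$centerlines$parent[1, ]
  apex <- geom$centerlines$parent[nrow(geom$centerlines$parent), ]
  cl <- geom$centerlines[[paste0("daughter", daughter)]]
  dend <- cl[nrow(cl), ]
  t1 <- apex - p0; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- dend - apex; t2 <- t2 / sqrt(sum(t2^2))
  a <- apex - fillet * t1
  b <- apex + fillet * t2
  tt <- seq(0, 1, length.out = n_fillet)[-c(1, n_fillet)]
  bez <- outer((1 - tt)^2, a) + outer(2 * tt * (1 - tt), apex) +
    outer(tt^2, b)
  deliveryPath(rbind(p0, a, bez, b, dend), role = "vessel")
}

## Evaluate position and frame at arc lengths s (vectorized).
.pathEval <- function(path, s) {
  s <- pmin(pmax(s, 0), pathLength(path))
  i <- pmin(findInterval(s, path$arc, rightmost.closed = TRUE),
            nrow(path$tang))
  t <- (s - path$arc[i])
  pos <- path$points[i, , drop = FALSE] + path$tang[i, , drop = FALSE] * t
  list(pos = pos, tang = path$tang[i, , drop = FALSE],
       n1 = path$n1[i, , drop = FALSE], n2 = path$n2[i, , drop = FALSE])
}

## Map reference node coordinates (device axis = +x) onto the path with
## the device's axial origin at arc length s0.
.pathMapReference <- function(ref, path, s0) {
  th <- atan2(ref[, 3], ref[, 2])
  r <- sqrt(ref[, 2]^2 + ref[, 3]^2)
  pe <- .pathEval(path, s0 + ref[, 1])
  pe$pos + pe$n1 * (r * cos(th)) + pe$n2 * (r * sin(th))
}

#' Crimp a wireframe onto a delivery path
#'
#' Compresses the device to the given radius and lays it along the path,
#' preserving strut lengths: the axial advance of each strut becomes
#' `sqrt(L^2 - chord^2)` where `chord` is its circumferential chord at
#' the crimped radius, so the braid elongates axially (crimping to the
#' nominal radius reproduces the reference configuration). The distal
#' end of the crimped device is placed at the distal (far) end of the
#' path.
#'
#' @param frame a `wireframe`. @param radius crimp radius (mm), larger
#'   than the strut radius and at most the nominal radius.
#' @param path a `deliveryPath` at least as long as the crimped device.
#' @return a `deploymentState` with `release_fraction = 0`.
#' @export
crimpWireframe <- function(frame, radius, path) {
  stopifnot(inherits(frame, "wireframe"), inherits(path, "deliveryPath"))
  if (radius <= frame$strut_radius)
    stop("crimp radius must exceed the strut radius")
  if (radius > frame$nominal_diameter / 2 + 1e-9)
    stop("crimp radius exceeds the nominal device radius")
  ref <- frame$reference_nodes
  th <- atan2(ref[, 3], ref[, 2])
  rr <- sqrt(ref[, 2]^2 + ref[, 3]^2)
  Rmax <- max(rr)
  rc <- radius * rr / Rmax                 # preserve relative layer radii
  a_c <- ref[, 1]                          # default (isolated nodes)
  for (w in unique(frame$wire_id)) {
    s <- frame$struts[frame$wire_id == w, , drop = FALSE]
    seqn <- c(s[1, 1], s[, 2])
    L <- frame$rest_lengths[frame$wire_id == w]
    dth <- diff(th[seqn])
    dth <- (dth + pi) %% (2 * pi) - pi
    chord <- 2 * rc[seqn[-1]] * sin(abs(dth) / 2)
    da <- sqrt(pmax(L^2 - chord^2, (0.05 * L)^2))
    a_c[seqn] <- a_c[seqn[1]] + c(0, cumsum(da))
  }
  span <- max(a_c) - min(a_c)
  if (span > pathLength(path))
    stop("path (", round(pathLength(path), 2),
         " mm) shorter than crimped device (", round(span, 2), " mm)")
  s_anchor <- pathLength(path) - max(a_c)
  pe <- .pathEval(path, s_anchor + a_c)
  pos <- pe$pos + pe$n1 * (rc * cos(th)) + pe$n2 * (rc * sin(th))
  structure(list(positions = pos, release_fraction = 0, iteration = 0L,
                 max_step = Inf, contact_set = integer(0),
                 energy_history = numeric(0), converged = FALSE,
                 crimp = list(radius = radius, s_anchor = s_anchor,
                              a_crimped = a_c, path = path),
                 goal = NULL),
            class = "deploymentState")
}

#' Release a crimped device and relax it inside a lumen
#'
#' Unsheathes the device progressively (distal to proximal with respect
#' to the sac, i.e. from the far end of the delivery path backwards) in
#' `schedule` equal increments, relaxing between increments, then
#' iterates to convergence. The wall is rigid: any node outside the
#' lumen is projected back onto the surface each iteration.
#'
#' @param state a `deploymentState` from [crimpWireframe()].
#' @param frame the corresponding `wireframe`.
#' @param lumen a `bifurcationGeometry` (its implicit surface is the
#'   contact wall).
#' @param schedule number of equal release increments (default 48) or a
#'   numeric vector of release fractions increasing to 1.
#' @param relax_params list of optional overrides: `k_goal` (stress-free
#'   shape stiffness relative to unit strut stiffness, default 0.6),
#'   `step` (descent step, default 0.2), `iters_per_increment` (25),
#'   `max_iter` (4000), `tol_step` (mm, default 1e-3), `penetration_tol`
#'   (mm, default 0.01), `deploy_end` (arc length of the deployed distal
#'   end, default `pathLength - 0.5` for stents, path end for bowls).
#' @return converged `deploymentState` (error carrying the last state if
#'   convergence fails).
#' @export
releaseWireframe <- function(state, frame, lumen, schedule = 48,
                             relax_params = list()) {
  stopifnot(inherits(state, "deploymentState"), inherits(frame, "wireframe"),
            inherits(lumen, "bifurcationGeometry"))
  rp <- utils::modifyList(list(
    k_goal = 0.6, step = 0.2, iters_per_increment = 25, max_iter = 4000,
    tol_step = 1e-3, penetration_tol = 0.01, deploy_end = NULL), relax_params)
  sdf <- if (!is.null(lumen$sdf_open)) lumen$sdf_open else lumen$sdf
  if (is.null(sdf)) stop("lumen has no implicit surface for contact")
  path <- state$crimp$path
  if (is.null(rp$deploy_end))
    rp$deploy_end <- if (frame$family == "braided_stent")
      max(frame$nominal_length, pathLength(path) - 0.5)
    else pathLength(path)
  s0 <- rp$deploy_end - max(frame$reference_nodes[, 1])
  goal <- .pathMapReference(frame$reference_nodes, path, s0)

  x <- state$positions
  if (all(sdf(x) > 0))
    stop("device wholly outside lumen: check path and geometry")
  n <- nrow(x)
  ord <- rank(-state$crimp$a_crimped, ties.method = "first")  # 1 = distal
  fr <- if (length(schedule) == 1) seq_len(schedule) / schedule
        else schedule
  if (any(diff(c(0, fr)) <= 0) || abs(fr[length(fr)] - 1) > 1e-12)
    stop("release schedule must increase to 1")
  i1 <- frame$struts[, 1]; i2 <- frame$struts[, 2]
  L0 <- frame$rest_lengths
  energy <- numeric(0)
  it <- 0L
  contact <- integer(0)
  relaxSweep <- function(released, iters, track_step = FALSE) {
    last_step <- Inf
    for (k in seq_len(iters)) {
      d <- x[i2, , drop = FALSE] - x[i1, , drop = FALSE]
      len <- sqrt(rowSums(d * d))
      fs <- d * (1 - L0 / pmax(len, 1e-9))
      acc <- rowsum(rbind(fs, -fs), c(i1, i2))
      Fst <- matrix(0, n, 3)
      Fst[as.integer(rownames(acc)), ] <- acc
      Fg <- rp$k_goal * (goal - x)
      dx <- rp$step * (Fst + Fg)
      dx[!released, ] <- 0
      xn <- x + dx
      ## contact projection (2 Newton steps)
      rel <- which(released)
      for (pr in 1:2) {
        s <- sdf(xn[rel, , drop = FALSE])
        out <- which(s > 0)
        if (length(out) == 0) break
        g <- sdfGradient(sdf, xn[rel[out], , drop = FALSE])
        gn <- rowSums(g * g)
        xn[rel[out], ] <- xn[rel[out], ] -
          g * (s[out] / pmax(gn, 1e-9))
      }
      last_step <- max(abs(xn - x))
      x <<- xn
      it <<- it + 1L
      ## track elastic energy (stretch + shape deviation)
      dd <- x[i2, , drop = FALSE] - x[i1, , drop = FALSE]
      E <- 0.5 * sum((sqrt(rowSums(dd * dd)) - L0)^2) +
        0.5 * rp$k_goal * sum((x[released, , drop = FALSE] -
                               goal[released, , drop = FALSE])^2)
      energy <<- c(energy, E)
      if (track_step && last_step < rp$tol_step) return(last_step)
    }
    last_step
  }
  released <- rep(FALSE, n)
  for (f in fr) {
    released <- ord <= ceiling(f * n)
    relaxSweep(released, rp$iters_per_increment)
  }
  last_step <- relaxSweep(released, rp$max_iter, track_step = TRUE)
  conv <- last_step < rp$tol_step
  contact <- which(released)[abs(sdf(x[released, , drop = FALSE])) < 5e-3]
  newstate <- structure(list(
    positions = x, release_fraction = fr[length(fr)], iteration = it,
    max_step = last_step, contact_set = contact,
    energy_history = energy, converged = conv,
    crimp = state$crimp, goal = goal,
    penetration = max(0, max(sdf(x))),
    relax_params = rp), class = "deploymentState")
  if (!conv) {
    cond <- structure(class = c("aneutreatConvergenceError", "error",
                                "condition"),
                      list(message = paste0(
                        "deployment did not converge within ", rp$max_iter,
                        " iterations (last step ",
                        signif(last_step, 3), " mm); last state attached"),
                        call = sys.call(-1), state = newstate))
    stop(cond)
  }
  newstate
}

#' Extract the deployed wireframe
#'
#' @param state a converged `deploymentState`.
#' @param frame the wireframe that was deployed.
#' @return a `wireframe` with `nodes` replaced by the deployed positions
#'   (reference state and connectivity unchanged).
#' @export
deployedFrame <- function(state, frame) {
  stopifnot(inherits(state, "deploymentState"), inherits(frame, "wireframe"))
  if (!isTRUE(state$converged))
    stop("deployment state is not converged")
  frame$nodes <- state$positions
  frame
}

#' @export
print.deploymentState <- function(x, ...) {
  cat("deploymentState: release fraction ", x$release_fraction,
      ", iteration ", x$iteration, "\n", sep = "")
  cat("  converged:", x$converged, " max step:", signif(x$max_step, 3),
      "mm  contact nodes:", length(x$contact_set), "\n")
  invisible(x)
}

## Elastic energy of a configuration (stretch + shape deviation); used by
## the independent small-frame minimization oracle in the tests.
.deployEnergy <- function(frame, positions, goal, k_goal = 0.6) {
  d <- positions[frame$struts[, 2], , drop = FALSE] -
    positions[frame$struts[, 1], , drop = FALSE]
  0.5 * sum((sqrt(rowSums(d * d)) - frame$rest_lengths)^2) +
    0.5 * k_goal * sum((positions - goal)^2)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
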