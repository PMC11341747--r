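## Parametric idealized bifurcation-aneurysm lumens.
##
## The construction is a desk-scale stand-in for segmented patient
## geometry: a straight parent vessel along +x, two daughter branches in
## the x-y plane at configurable angles, and a spheroidal aneurysm dome
## whose sac opens onto the vascular junction through a planar neck of
## prescribed width. All dimensions are in millimetres.

#' Generate an idealized bifurcation-aneurysm lumen
#'
#' Builds a watertight triangulated lumen of a terminal bifurcation
#' aneurysm: the spheroidal dome sits on the continuation of the parent
#' axis (+x), so the parent jet empties towards the sac, and the two
#' daughter branches leave just proximal of the neck plane at
#' configurable angles, diving slightly out of plane away from the dome.
#' The sac is the part of the spheroid beyond the neck plane, placed so
#' the dome cross-section at the neck plane has exactly the requested
#' neck width `d_n`. The maximum dome width `d_a` equals twice the
#' equatorial semi-axis.
#'
#' @param parent_diameter parent vessel diameter (mm).
#' @param daughter_diameters length-2 vector of daughter diameters (mm).
#' @param branch_angles length-2 vector of angles (degrees) between the
#'   parent axis and each daughter axis; daughters are placed at +/- the
#'   angle in the x-y plane.
#' @param neck_width aneurysm neck width `d_n` (mm).
#' @param dome_semiaxes length-2 vector `c(equatorial, polar)` of dome
#'   semi-axes (mm); maximum aneurysm width `d_a` is `2 * equatorial`.
#' @param parent_length,daughter_length branch lengths (mm).
#' @param dome_offset axial (x) position of the dome centre relative to
#'   the bifurcation origin (mm).
#' @param neck_offset distance (mm) from the bifurcation point to the
#'   neck plane along the parent axis (default 0.8 parent radius).
#' @param daughter_dip out-of-plane angle (degrees) by which the
#'   daughters dive away from the dome after branching (default 10).
#' @param daughter_offsets length-2 vector of branch-point offsets (mm)
#'   along the parent axis; a positive offset moves that daughter's
#'   ostium towards the neck (default `c(0, 0)`).
#' @param edge_length target surface edge length (mm). Default 0.2 mm
#'   resolves the smallest catalogued neck (3.11 mm) with >15 edges.
#' @param perturb optional relative perturbation amplitude applied to the
#'   dome centre and semi-axes (seed-controlled; default 0 = none).
#' @param seed integer seed used only when `perturb > 0`.
#' @return an object of class `bifurcationGeometry`: triangulated surface
#'   (`vertices`, `triangles`), labelled caps, centerlines, stored
#'   diameters/angles, dome description and implicit-surface closures
#'   used by the deployment and flow solvers.
#' @export
generateBifurcationAneurysm <- function(parent_diameter,
                                        daughter_diameters,
                                        branch_angles,
                                        neck_width,
                                        dome_semiaxes,
                                        parent_length = 8,
                                        daughter_length = 8,
                                        neck_offset = 0.4 * parent_diameter,
                                        daughter_dip = 10,
                                        daughter_offsets = c(0, 0),
                                        edge_length = 0.2,
                                        perturb = 0,
                                        seed = NULL) {
  lens <- c(parent_diameter, daughter_diameters, parent_length,
            daughter_length, neck_width, dome_semiaxes, edge_length)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all geometric parameters must be positive and finite ",
         "(violated: positivity of lengths/diameters/semi-axes)")
  if (length(daughter_diameters) != 2 || length(branch_angles) != 2)
    stop("two daughter diameters and two branch angles are required")
  if (any(branch_angles <= 0) || any(branch_angles >= 90))
    stop("branch angles must lie strictly between 0 and 90 degrees")
  if (length(dome_semiaxes) != 2)
    stop("dome_semiaxes must be c(equatorial, polar)")
  ae <- dome_semiaxes[1]; az <- dome_semiaxes[2]
  if (perturb > 0) {
    if (is.null(seed)) stop("perturb > 0 requires a seed")
    rng <- withr_seed_runif(seed, 3)
    ae <- ae * (1 + perturb * (2 * rng[1] - 1))
    az <- az * (1 + perturb * (2 * rng[2] - 1))
    neck_offset <- neck_offset * (1 + perturb * (2 * rng[3] - 1))
  }
  if (neck_width > 2 * ae)
    stop("infeasible parameters: neck width ", neck_width,
         " mm exceeds dome equatorial diameter ", 2 * ae, " mm")
  if (neck_offset <= 0 || neck_offset >= parent_length)
    stop("infeasible parameters: dome does not intersect the vessel ",
         "wall (neck plane offset ", neck_offset,
         " mm must lie between 0 and the parent length)")
  xc <- neck_offset + az * sqrt(max(0, 1 - (neck_width / (2 * ae))^2))
  dome <- list(center = c(xc, 0, 0), semiaxes = c(ae, az),
               axis = c(1, 0, 0), neck_s = neck_offset)
  geom <- .buildVascularTree(parent_diameter, daughter_diameters,
                             branch_angles, parent_length, daughter_length,
                             dome, edge_length, daughter_dip = daughter_dip,
                             daughter_offsets = daughter_offsets)
  ## daughter caps must clear the sac
  for (cp in geom$caps) {
    if (cp$role != "inlet" &&
        any(geom$sdf_sac(matrix(cp$origin, 1, 3)) < cp$radius))
      stop("infeasible parameters: dome engulfs the ", cp$branch,
           " cap; increase daughter_length or shrink the dome")
  }
  geom$params$neck_width <- neck_width
  geom$params$perturb <- perturb
  geom$params$seed <- seed
  geom
}

#' Generate a plain bifurcation lumen (no aneurysm)
#'
#' Same vascular tree as [generateBifurcationAneurysm()] without a dome;
#' used e.g. for symmetric flow-split verification.
#' @inheritParams generateBifurcationAneurysm
#' @return a `bifurcationGeometry` with `dome = NULL`.
#' @export
generateBifurcation <- function(parent_diameter, daughter_diameters,
                                branch_angles, parent_length = 8,
                                daughter_length = 8, edge_length = 0.2) {
  .buildVascularTree(parent_diameter, daughter_diameters, branch_angles,
                     parent_length, daughter_length, dome = NULL,
                     edge_length = edge_length)
}

#' Straight-tube lumen
#'
#' A capped straight tube along +x from `x = 0` to `x = length`; the
#' canonical verification domain (Hagen-Poiseuille flow).
#' @param diameter,length tube dimensions (mm).
#' @param edge_length target surface edge length (mm).
#' @return a `bifurcationGeometry` with a single outlet.
#' @export
tubeGeometry <- function(diameter, length, edge_length = 0.2) {
  stopifnot(diameter > 0, length > 0)
  r <- diameter / 2
  a <- c(0, 0, 0); b <- c(length, 0, 0)
  ext <- 4 * r
  sdf_vessel <- function(p) sdfCapsule(p, a - c(r, 0, 0), b + c(r, 0, 0), r)
  sdf_open <- function(p) sdfCapsule(p, a - c(ext, 0, 0), b + c(ext, 0, 0), r)
  sdf <- function(p) pmax(sdf_vessel(p), -p[, 1], p[, 1] - length)
  caps <- list(
    list(role = "inlet", origin = a, normal = c(-1, 0, 0), radius = r,
         branch = "parent"),
    list(role = "outlet", origin = b, normal = c(1, 0, 0), radius = r,
         branch = "daughter1"))
  geom <- .finishGeometry(sdf, sdf_open, sdf_vessel, NULL, caps,
                          centerlines = list(parent = rbind(a, b)),
                          parent_diameter = diameter,
                          daughter_diameters = numeric(0),
                          bifurcation_angles = numeric(0),
                          dome = NULL, edge_length = edge_length,
                          bbox = rbind(c(-edge_length * 2, -r - 2 * edge_length,
                                         -r - 2 * edge_length),
                                       c(length + 2 * edge_length,
                                         r + 2 * edge_length,
                                         r + 2 * edge_length)),
                          params = list(kind = "tube", diameter = diameter,
                                        length = length, ext = ext))
  geom
}

## Shared builder for parent + daughters (+ optional dome).
.buildVascularTree <- function(parent_diameter, daughter_diameters,
                               branch_angles, parent_length,
                               daughter_length, dome, edge_length,
                               daughter_dip = 0, daughter_offsets = c(0, 0)) {
  Rp <- parent_diameter / 2
  Rd <- daughter_diameters / 2
  if (length(daughter_length) == 1)
    daughter_length <- rep(daughter_length, 2)
  th <- branch_angles * pi / 180
  dd <- daughter_dip * pi / 180
  dirs <- list(c(cos(th[1]) * cos(dd), sin(th[1]) * cos(dd), -sin(dd)),
               c(cos(th[2]) * cos(dd), -sin(th[2]) * cos(dd), -sin(dd)))
  p_in <- c(-parent_length, 0, 0)
  ## parent stub ends just past the neck plane (terminal bifurcation:
  ## the parent jet empties towards the sac orifice)
  p_stub <- c(if (is.null(dome)) 0 else dome$neck_s + 0.1, 0, 0)
  orig <- list(c(daughter_offsets[1], 0, 0), c(daughter_offsets[2], 0, 0))
  ends <- list(orig[[1]] + dirs[[1]] * daughter_length[1],
               orig[[2]] + dirs[[2]] * daughter_length[2])
  ext <- 4 * max(Rp, Rd)

  sdf_vessel <- function(p) {
    f <- sdfCapsule(p, p_in - c(Rp, 0, 0), p_stub, Rp)
    f <- pmin(f, sdfCapsule(p, orig[[1]], ends[[1]] + dirs[[1]] * Rd[1],
                            Rd[1]))
    pmin(f, sdfCapsule(p, orig[[2]], ends[[2]] + dirs[[2]] * Rd[2], Rd[2]))
  }
  sdf_dome <- NULL; sdf_sac <- NULL
  if (!is.null(dome)) {
    adim <- which.max(abs(dome$axis))
    sdf_dome <- function(p) sdfSpheroidAxis(p, dome$center,
                                            dome$semiaxes[1],
                                            dome$semiaxes[2], adim)
    sdf_sac <- function(p)
      pmax(sdf_dome(p), dome$neck_s - as.numeric(p %*% dome$axis))
  }
  core <- function(p) {
    f <- sdf_vessel(p)
    if (!is.null(sdf_sac)) f <- pmin(f, sdf_sac(p))
    f
  }
  sdf <- function(p) {
    f <- core(p)
    f <- pmax(f, -(p[, 1] + parent_length))
    for (i in 1:2)
      f <- pmax(f, sweep(p, 2, ends[[i]]) %*% dirs[[i]])
    f
  }
  sdf_open <- function(p) {
    f <- sdfCapsule(p, p_in - c(ext, 0, 0), p_stub, Rp)
    f <- pmin(f, sdfCapsule(p, orig[[1]], ends[[1]] + dirs[[1]] * ext,
                            Rd[1]))
    f <- pmin(f, sdfCapsule(p, orig[[2]], ends[[2]] + dirs[[2]] * ext,
                            Rd[2]))
    if (!is.null(sdf_sac)) f <- pmin(f, sdf_sac(p))
    f
  }
  caps <- list(
    list(role = "inlet", origin = p_in, normal = c(-1, 0, 0), radius = Rp,
         branch = "parent"),
    list(role = "outlet", origin = ends[[1]], normal = dirs[[1]],
         radius = Rd[1], branch = "daughter1"),
    list(role = "outlet", origin = ends[[2]], normal = dirs[[2]],
         radius = Rd[2], branch = "daughter2"))
  centerlines <- list(parent = rbind(p_in, c(0, 0, 0)),
                      daughter1 = rbind(orig[[1]], ends[[1]]),
                      daughter2 = rbind(orig[[2]], ends[[2]]))
  hx <- max(Rp, Rd)
  bb_lo <- c(-parent_length, min(ends[[1]][2], ends[[2]][2]) - hx,
             min(-hx, ends[[1]][3] - hx, ends[[2]][3] - hx))
  bb_hi <- c(max(p_stub[1], ends[[1]][1], ends[[2]][1]) + hx,
             max(ends[[1]][2], ends[[2]][2]) + hx,
             max(hx, ends[[1]][3] + hx, ends[[2]][3] + hx))
  if (!is.null(dome)) {
    ext_d <- abs(dome$axis) * dome$semiaxes[2] +
      (1 - abs(dome$axis)) * dome$semiaxes[1]
    bb_lo <- pmin(bb_lo, dome$center - ext_d)
    bb_hi <- pmax(bb_hi, dome$center + ext_d)
  }
  m <- 2 * edge_length
  .finishGeometry(sdf, sdf_open, sdf_vessel, sdf_sac, caps, centerlines,
                  parent_diameter, daughter_diameters, branch_angles, dome,
                  edge_length, rbind(bb_lo - m, bb_hi + m),
                  params = list(kind = "bifurcation",
                                parent_length = parent_length,
                                daughter_length = daughter_length,
                                ext = ext),
                  sdf_dome = sdf_dome)
}

## Mesh the implicit lumen and assemble the geometry object.
.finishGeometry <- function(sdf, sdf_open, sdf_vessel, sdf_sac, caps,
                            centerlines, parent_diameter, daughter_diameters,
                            bifurcation_angles, dome, edge_length, bbox,
                            params, sdf_dome = NULL) {
  h <- edge_length
  n <- pmax(4L, as.integer(ceiling((bbox[2, ] - bbox[1, ]) / h)) + 1L)
  origin <- bbox[1, ]
  gx <- origin[1] + (seq_len(n[1]) - 1) * h
  gy <- origin[2] + (seq_len(n[2]) - 1) * h
  gz <- origin[3] + (seq_len(n[3]) - 1) * h
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  f <- array(sdf(pts), dim = n)
  surf <- marchingTetrahedra(f, origin, h)
  if (nrow(surf$triangles) == 0)
    stop("infeasible parameters: empty lumen surface")

  ## label cap triangles: all three vertices on the cap plane
  capTol <- 1e-6
  V <- surf$vertices; Tri <- surf$triangles
  cap_labels <- list(inlet = integer(0), outlets = list())
  for (i in seq_along(caps)) {
    cp <- caps[[i]]
    d <- abs(sweep(V, 2, cp$origin) %*% cp$normal)
    onplane <- d < capTol
    ids <- which(onplane[Tri[, 1]] & onplane[Tri[, 2]] & onplane[Tri[, 3]])
    if (cp$role == "inlet") cap_labels$inlet <- ids
    else cap_labels$outlets[[cp$branch]] <- ids
  }
  structure(list(
    vertices = V, triangles = Tri, cap_labels = cap_labels, caps = caps,
    centerlines = centerlines, parent_diameter = parent_diameter,
    daughter_diameters = daughter_diameters,
    bifurcation_angles = bifurcation_angles, dome = dome,
    sdf = sdf, sdf_open = sdf_open, sdf_vessel = sdf_vessel,
    sdf_dome = sdf_dome, sdf_sac = sdf_sac,
    edge_length = edge_length, params = params),
    class = "bifurcationGeometry")
}

#' @export
print.bifurcationGeometry <- function(x, ...) {
  cat("bifurcationGeometry:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  cat("  parent diameter:", x$parent_diameter, "mm;",
      if (length(x$daughter_diameters))
        paste("daughters:", paste(x$daughter_diameters, collapse = ", "),
              "mm at", paste(x$bifurcation_angles, collapse = ", "), "deg")
      else "no daughters", "\n")
  if (!is.null(x$dome))
    cat("  dome: centre (", paste(round(x$dome$center, 2), collapse = ", "),
        ") mm, semi-axes ", paste(round(x$dome$semiaxes, 2), collapse = " x "),
        " mm\n", sep = "")
  cat("  boundary edges:", meshBoundaryEdgeCount(x$triangles),
      "(0 = watertight)\n")
  invisible(x)
}

## Deterministic uniform deviates from an isolated RNG stream (the global
## RNG state is left untouched).
withr_seed_runif <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}
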