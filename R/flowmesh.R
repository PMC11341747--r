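## Cartesian immersed-boundary flow mesh.
##
## The computational domain is a uniform staggered (MAC) grid covering
## the lumen: cell-centred pressure, face-centred velocity components.
## The lumen wall enters through the signed distance sampled at cell and
## face centres (sub-cell wall positions are used by the solver's
## boundary-corrected diffusion stencils). Branch caps are extended by
## straight buffers: the inlet ends in a Dirichlet-velocity slab, outlet
## buffers are fixed-pressure regions.

#' Build a Cartesian flow mesh for a lumen
#'
#' Cell sizing is `h = density^(-1/3)`, so the fluid element count is
#' approximately `density` times the lumen volume.
#'
#' @param geom a `bifurcationGeometry` with implicit closures (generated
#'   geometries carry them; imported meshes are not supported here).
#' @param frame optional deployed `wireframe`; its struts are recorded as
#'   strut-labelled faces (used by resolved coupling and mesh audits).
#' @param density target mesh density, elements per mm^3.
#' @return a `hemoMesh`.
#' @export
meshDomain <- function(geom, frame = NULL, density) {
  stopifnot(inherits(geom, "bifurcationGeometry"), density > 0)
  if (is.null(geom$sdf_open))
    stop("geometry has no implicit surface; meshDomain needs a generated ",
         "or analytically described lumen")
  h <- density^(-1 / 3)
  ext <- geom$params$ext
  if (is.null(ext)) ext <- 4 * max(geom$parent_diameter / 2, 1)
  if (h > ext / 3)
    stop("density ", density, " elements/mm^3 is infeasible for this ",
         "geometry scale (cell size ", round(h, 2),
         " mm exceeds a third of the cap buffer length)")
  ## bounding box: lumen surface plus cap buffers
  lo <- apply(geom$vertices, 2, min)
  hi <- apply(geom$vertices, 2, max)
  for (cp in geom$caps) {
    tip <- cp$origin + cp$normal * (ext + cp$radius)
    lo <- pmin(lo, tip - cp$radius); hi <- pmax(hi, tip + cp$radius)
  }
  lo <- lo - 2 * h; hi <- hi + 2 * h
  nc <- pmax(4L, as.integer(ceiling((hi - lo) / h)))
  ctr <- (lo + hi) / 2
  origin <- ctr - nc * h / 2         # box corner; cell i centre at
                                     # origin + (i - 0.5) h (symmetric box)
  cellc <- .gridCenters(origin, nc, h, stagger = 0L)
  cs <- geom$sdf_open(cellc)
  fluid <- array(cs < 0, dim = nc)
  ctype <- array(0L, dim = nc)       # 0 solid, 1 interior, 2 outlet, 3 inlet
  ctype[fluid] <- 1L
  outlets <- Filter(function(cp) cp$role == "outlet", geom$caps)
  outlet_id <- array(0L, dim = nc)
  for (k in seq_along(outlets)) {
    cp <- outlets[[k]]
    beyond <- array(sweep(cellc, 2, cp$origin) %*% cp$normal > 0, dim = nc)
    sel <- fluid & beyond & ctype != 2L
    ctype[sel] <- 2L
    outlet_id[sel] <- k
  }
  inlet <- Filter(function(cp) cp$role == "inlet", geom$caps)[[1]]
  beyond_in <- array(sweep(cellc, 2, inlet$origin) %*% inlet$normal >
                     ext - 2.5 * h, dim = nc)
  ctype[fluid & beyond_in] <- 3L
  in_domain <- array(geom$sdf(cellc) < 0, dim = nc)

  ## face-centred signed distances (for wall-corrected stencils)
  fsdf <- lapply(1:3, function(d) {
    fd <- nc; fd[d] <- fd[d] + 1L
    array(geom$sdf_open(.gridCenters(origin, fd, h, stagger = d)), dim = fd)
  })

  mesh <- structure(list(
    geom = geom, h = h, nc = nc, origin = origin,
    ctype = ctype, outlet_id = outlet_id, outlets = outlets,
    inlet = inlet, ext = ext, fsdf = fsdf,
    n_elements = sum(in_domain), in_domain = in_domain,
    density = sum(in_domain) / (sum(in_domain) * h^3),
    strut_faces = NULL, screen = NULL, frame = frame),
    class = "hemoMesh")
  if (!is.null(frame))
    mesh$strut_faces <- .markFacesNearStruts(mesh, frame,
                                             radius = max(frame$strut_radius,
                                                          h / 2))
  mesh
}

#' @export
print.hemoMesh <- function(x, ...) {
  cat("hemoMesh: ", paste(x$nc, collapse = " x "), " cells, h = ",
      signif(x$h, 3), " mm\n", sep = "")
  cat("  fluid elements in domain:", x$n_elements,
      sprintf("(~%.0f per mm^3)", 1 / x$h^3), "\n")
  if (!is.null(x$screen))
    cat("  device screen: porosity", x$screen$porosity, "\n")
  invisible(x)
}

## Centres of cells (stagger = 0) or faces of component d (stagger = d).
.gridCenters <- function(origin, dims, h, stagger = 0L) {
  off <- rep(0.5, 3)
  if (stagger > 0) off[stagger] <- 0
  g <- lapply(1:3, function(d) origin[d] + (seq_len(dims[d]) - 1 + off[d]) * h)
  as.matrix(expand.grid(x = g[[1]], y = g[[2]], z = g[[3]]))
}

## Resample struts into a dense point chain (step h/4). Isolated nodes
## (e.g. the Contour's polar marker hub) are included so the surface
## they occupy is marked too.
.strutChain <- function(frame, h) {
  P1 <- frame$nodes[frame$struts[, 1], , drop = FALSE]
  P2 <- frame$nodes[frame$struts[, 2], , drop = FALSE]
  len <- sqrt(rowSums((P2 - P1)^2))
  nsub <- pmax(1L, ceiling(len / (h / 4)))
  pts <- NULL
  for (k in seq_len(max(nsub))) {
    sel <- nsub >= k
    if (!any(sel)) break
    t <- (k - 0.5) / nsub[sel]
    pts <- rbind(pts, P1[sel, , drop = FALSE] +
                   (P2[sel, , drop = FALSE] - P1[sel, , drop = FALSE]) * t)
  }
  lone <- setdiff(seq_len(nrow(frame$nodes)), unique(as.vector(frame$struts)))
  if (length(lone)) pts <- rbind(pts, frame$nodes[lone, , drop = FALSE])
  pts
}

## Per-point surface normals of the braid surface: smallest principal
## direction of the neighbouring strut-point cloud (neighbours from
## adjacent wires make the local plane well defined).
.chainNormals <- function(pts, radius) {
  key <- paste(floor(pts[, 1] / radius), floor(pts[, 2] / radius),
               floor(pts[, 3] / radius))
  bins <- split(seq_len(nrow(pts)), key)
  keymat <- floor(sweep(pts, 2, rep(radius, 3), "/"))
  nrm <- matrix(0, nrow(pts), 3)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ## subsample query points for speed; marking averages normals anyway
  for (i in seq_len(nrow(pts))) {
    nb <- integer(0)
    for (r in seq_len(27)) {
      k <- paste(keymat[i, 1] + offs[r, 1], keymat[i, 2] + offs[r, 2],
                 keymat[i, 3] + offs[r, 3])
      nb <- c(nb, bins[[k]])
    }
    Q <- pts[nb, , drop = FALSE]
    if (nrow(Q) < 4) { nrm[i, ] <- c(0, 0, 0); next }
    Qc <- sweep(Q, 2, colMeans(Q))
    ev <- eigen(crossprod(Qc), symmetric = TRUE)
    nrm[i, ] <- ev$vectors[, 3]
  }
  nrm
}

## Mark faces of all three component grids lying within `radius` of any
## strut point; optionally accumulate the braid-surface normal tensor
## <n n^T> per face from per-point surface normals (sign-free), from
## which the dominant normal direction is extracted by power iteration.
.markFacesNearStruts <- function(mesh, frame, radius, normals = NULL,
                                 chain = NULL) {
  h <- mesh$h; nc <- mesh$nc; origin <- mesh$origin
  pts <- if (is.null(chain)) .strutChain(frame, h) else chain
  out <- vector("list", 3)
  rg <- ceiling(radius / h)
  offs <- as.matrix(expand.grid(-rg:rg, -rg:rg, -rg:rg))
  tcols <- cbind(c(1, 2, 3, 1, 1, 2), c(1, 2, 3, 2, 3, 3)) # xx yy zz xy xz yz
  for (d in 1:3) {
    fd <- nc; fd[d] <- fd[d] + 1L
    mk <- array(FALSE, dim = fd)
    tsum <- if (!is.null(normals))
      matrix(0, prod(fd), 6) else NULL
    off <- rep(0.5, 3); off[d] <- 0
    idx0 <- sweep(sweep(pts, 2, origin) / h, 2, off - 1, "-")
    for (r in seq_len(nrow(offs))) {
      ii <- round(idx0[, 1]) + offs[r, 1]
      jj <- round(idx0[, 2]) + offs[r, 2]
      kk <- round(idx0[, 3]) + offs[r, 3]
      ok <- ii >= 1 & ii <= fd[1] & jj >= 1 & jj <= fd[2] &
        kk >= 1 & kk <= fd[3]
      if (!any(ok)) next
      fx <- origin[1] + (ii[ok] - 1 + off[1]) * h
      fy <- origin[2] + (jj[ok] - 1 + off[2]) * h
      fz <- origin[3] + (kk[ok] - 1 + off[3]) * h
      near <- (fx - pts[ok, 1])^2 + (fy - pts[ok, 2])^2 +
        (fz - pts[ok, 3])^2 <= radius^2
      if (!any(near)) next
      sel <- cbind(ii[ok][near], jj[ok][near], kk[ok][near])
      mk[sel] <- TRUE
      if (!is.null(normals)) {
        lin <- sel[, 1] + (sel[, 2] - 1) * fd[1] +
          (sel[, 3] - 1) * fd[1] * fd[2]
        nn <- normals[ok, , drop = FALSE][near, , drop = FALSE]
        tens <- cbind(nn[, 1]^2, nn[, 2]^2, nn[, 3]^2,
                      nn[, 1] * nn[, 2], nn[, 1] * nn[, 3],
                      nn[, 2] * nn[, 3])
        agg <- rowsum(tens, lin)
        idxu <- as.numeric(rownames(agg))
        tsum[idxu, ] <- tsum[idxu, ] + agg
      }
    }
    if (is.null(normals)) {
      out[[d]] <- mk
    } else {
      midx <- which(mk)
      Tm <- tsum[midx, , drop = FALSE]
      ## dominant eigenvector of each 3x3 tensor by power iteration
      v <- matrix(1 / sqrt(3), length(midx), 3)
      for (pw in 1:25) {
        v <- cbind(Tm[, 1] * v[, 1] + Tm[, 4] * v[, 2] + Tm[, 5] * v[, 3],
                   Tm[, 4] * v[, 1] + Tm[, 2] * v[, 2] + Tm[, 6] * v[, 3],
                   Tm[, 5] * v[, 1] + Tm[, 6] * v[, 2] + Tm[, 3] * v[, 3])
        v <- v / pmax(sqrt(rowSums(v * v)), 1e-300)
      }
      out[[d]] <- list(mask = mk, idx = midx, normal = v)
    }
  }
  out
}

#' Couple a deployed device as a homogenized porous screen
#'
#' Faces swept by the device surface receive a Brinkman momentum sink
#' whose strength decreases monotonically with porosity: the permeability
#' follows a Kozeny-Carman-type screen law
#' `k = d_w^2 porosity^3 / (180 (1 - porosity)^2)` with `d_w` the wire
#' diameter, and the sink is scaled so the integrated resistance matches
#' a physical screen of thickness `d_w` smeared over one grid layer.
#' Porosity 1 leaves the flow model untouched; porosity 0 seals the
#' screened faces exactly.
#'
#' @param mesh a `hemoMesh`.
#' @param frame the deployed `wireframe` defining the screen surface.
#' @param porosity open-area fraction in `[0, 1]` (e.g. from
#'   [computePorosity()]).
#' @param layer_radius half-thickness (mm) of the face layer marked as
#'   screen; default one grid spacing (covers the surface continuously
#'   for node spacings up to ~2h).
#' @param tangential optional fraction of the normal drag applied to
#'   the tangential velocity inside the screen layer (wire skin
#'   friction). Default 0: the homogenized screen resists through-flow
#'   only, which leaves flow along a wall-apposed braid unimpeded.
#' @details The drag is anisotropic: the velocity component normal to
#'   the braid surface feels the full screen resistance (a thin screen
#'   resists through-flow) while flow along the deployed surface feels
#'   only the weaker wire skin friction. The local surface normal is
#'   estimated per face by principal-component analysis of the
#'   strut-point cloud, and the solver applies the drag as a
#'   Sherman-Morrison filter on the velocity, which is unconditionally
#'   stable for any screen strength.
#' @return the mesh with screen data attached.
#' @export
applyDeviceScreen <- function(mesh, frame, porosity,
                              layer_radius = mesh$h, tangential = 0) {
  stopifnot(inherits(mesh, "hemoMesh"), inherits(frame, "wireframe"))
  if (!is.finite(porosity) || porosity < 0 || porosity > 1)
    stop("porosity must lie in [0, 1] (0 = sealed, 1 = fully open)")
  chain <- .strutChain(frame, mesh$h)
  nrm <- .chainNormals(chain, radius = max(2.5 * layer_radius, 0.8))
  marked <- .markFacesNearStruts(mesh, frame, radius = layer_radius,
                                 normals = nrm, chain = chain)
  dw <- 2 * frame$strut_radius
  if (porosity >= 1) {
    coef <- 0
  } else if (porosity <= 0) {
    coef <- Inf
  } else {
    k_perm <- dw^2 * porosity^3 / (180 * (1 - porosity)^2)  # mm^2
    t_num <- 2 * layer_radius
    coef <- (dw / t_num) / k_perm                           # 1 / mm^2
  }
  mesh$screen <- list(faces = lapply(marked, `[[`, "mask"),
                      idx = lapply(marked, `[[`, "idx"),
                      normal = lapply(marked, `[[`, "normal"),
                      porosity = porosity, coef = coef,
                      tangential = tangential, wire_diameter = dw)
  mesh
}
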