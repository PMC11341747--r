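## Morphometric measurement of an aneurysm sac on a lumen surface.
##
## The neck contour is taken as the intersection curve between the dome
## surface and the vessel/neck envelope: operationally, the boundary of
## the set of surface triangles lying on the dome, refined by Newton
## projection onto {dome = 0, envelope = 0} when implicit closures are
## available. d_n is the maximum chord of that contour; d_a the maximum
## chord of the dome parallel to the fitted neck plane. Both clinical
## sizing measurements (neck width, maximum width) are 3D max-chord
## readings here.

#' Measure an aneurysm sac
#'
#' @param geom a `bifurcationGeometry` with a dome.
#' @param stented_daughter index (1 or 2) of the daughter designated for
#'   stent placement; the size-degree ratio `sdr` is the *other*
#'   (non-stented) daughter diameter over the parent diameter.
#' @return object of class `aneurysmMeasures` with fields `d_n`, `d_a`
#'   (mm), `sdr`, and `neck_plane` (origin + unit normal oriented into
#'   the sac).
#' @export
measureAneurysm <- function(geom, stented_daughter = 1L) {
  stopifnot(inherits(geom, "bifurcationGeometry"))
  if (is.null(geom$dome) || is.null(geom$sdf_dome))
    stop("no identifiable neck contour: geometry has no aneurysm dome")
  e <- geom$edge_length
  C <- meshCentroids(geom$vertices, geom$triangles)
  fd <- geom$sdf_dome(C)
  ax <- geom$dome$axis
  sac <- abs(fd) < 0.35 * e &
    as.numeric(C %*% ax) > geom$dome$neck_s + 0.35 * e
  ## branch tubes grazing the dome surface are vessel wall, not sac
  if (!is.null(geom$sdf_vessel))
    sac <- sac & geom$sdf_vessel(C) > 0.3 * e
  if (!any(sac)) stop("no identifiable neck contour: no sac surface found")
  sacTri <- geom$triangles[sac, , drop = FALSE]
  loops <- meshBoundaryLoops(sacTri)
  if (length(loops) == 0)
    stop("no identifiable neck contour: sac surface has no boundary")
  ## the neck is the largest-circumference boundary loop (branch exit
  ## holes through the dome are smaller than the neck by construction)
  circ <- vapply(loops, function(l) {
    P <- geom$vertices[l, , drop = FALSE]
    sum(sqrt(rowSums((P - P[c(2:nrow(P), 1), , drop = FALSE])^2)))
  }, numeric(1))
  loop <- loops[[which.max(circ)]]
  P <- geom$vertices[loop, , drop = FALSE]

  ## refine contour points onto {dome = 0, envelope = 0}
  neck_s <- geom$dome$neck_s
  env <- function(p) as.numeric(p %*% ax) - neck_s
  for (it in 1:3) {
    F1 <- geom$sdf_dome(P); F2 <- env(P)
    g1 <- sdfGradient(geom$sdf_dome, P)
    g2 <- sdfGradient(env, P)
    a <- rowSums(g1 * g1); b <- rowSums(g1 * g2); cc <- rowSums(g2 * g2)
    det <- a * cc - b * b
    ok <- det > 1e-12
    l1 <- ifelse(ok, (cc * F1 - b * F2) / det, 0)
    l2 <- ifelse(ok, (-b * F1 + a * F2) / det, 0)
    P <- P - (g1 * l1 + g2 * l2)
  }

  d_n <- .maxChord(P)
  ## least-squares neck plane
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  normal <- sv$v[, 3]
  if (sum(normal * (geom$dome$center - ctr)) < 0) normal <- -normal

  ## d_a: max chord parallel to the neck plane, from sac vertices binned
  ## by height above the plane
  vs <- sort(unique(as.vector(sacTri)))
  Vs <- geom$vertices[vs, , drop = FALSE]
  ## keep only vertices genuinely on the dome surface (triangles at the
  ## branch exit holes own vertices on the tube walls)
  keepv <- abs(geom$sdf_dome(Vs)) < 0.2 * e
  if (!is.null(geom$sdf_vessel))
    keepv <- keepv & geom$sdf_vessel(Vs) > 0.2 * e
  Vs <- rbind(Vs[keepv, , drop = FALSE], P)
  s <- as.numeric(sweep(Vs, 2, ctr) %*% normal)
  bins <- floor(s / e)
  d_a <- 0
  for (bv in unique(bins)) {
    Q <- Vs[bins == bv, , drop = FALSE]
    if (nrow(Q) < 2) next
    if (nrow(Q) > 800) Q <- Q[seq(1, nrow(Q), length.out = 800), ]
    d_a <- max(d_a, .maxChord(Q))
  }
  structure(list(
    d_n = d_n, d_a = d_a,
    sdr = if (length(geom$daughter_diameters) == 2)
      geom$daughter_diameters[c(2, 1)[stented_daughter]] /
        geom$parent_diameter else NA_real_,
    neck_plane = list(origin = ctr, normal = normal),
    contour = P), class = "aneurysmMeasures")
}

#' @export
print.aneurysmMeasures <- function(x, ...) {
  cat(sprintf("aneurysmMeasures: d_n = %.3f mm, d_a = %.3f mm, sdr = %.3f\n",
              x$d_n, x$d_a, x$sdr))
  cat("  neck plane origin (", paste(round(x$neck_plane$origin, 2),
      collapse = ", "), "), normal (",
      paste(round(x$neck_plane$normal, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

## Maximum pairwise distance between rows of P (exact; P is modest here).
.maxChord <- function(P) {
  n <- nrow(P)
  if (n < 2) return(0)
  g <- rowSums(P^2)
  d2max <- 0
  step <- max(1L, floor(2e6 / n))
  for (i0 in seq(1L, n, by = step)) {
    ii <- i0:min(n, i0 + step - 1L)
    d2 <- outer(g[ii], g, "+") - 2 * P[ii, , drop = FALSE] %*% t(P)
    d2max <- max(d2max, d2)
  }
  sqrt(max(0, d2max))
}
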