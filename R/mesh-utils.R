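## Small triangle-mesh utilities shared by the geometry and I/O code.

#' Count boundary edges of a triangle mesh
#'
#' A watertight (closed, manifold) mesh has zero boundary edges: every
#' edge is shared by exactly two triangles.
#'
#' @param triangles m x 3 integer matrix of vertex indices.
#' @return number of edges not shared by exactly two triangles.
#' @export
meshBoundaryEdgeCount <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  sum(tab != 2L)
}

#' Signed volume enclosed by a triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedra against the origin;
#' positive for consistently outward-oriented closed surfaces.
#'
#' @param vertices n x 3 matrix (mm); @param triangles m x 3 indices.
#' @return volume in mm^3.
#' @export
meshVolume <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  sum(rowSums(p1 * .rowCross(p2, p3))) / 6
}

#' Total surface area of a triangle mesh
#' @inheritParams meshVolume
#' @return area in mm^2.
#' @export
meshArea <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  sum(sqrt(rowSums(.rowCross(p2 - p1, p3 - p1)^2))) / 2
}

## Triangle centroids.
meshCentroids <- function(vertices, triangles) {
  (vertices[triangles[, 1], , drop = FALSE] +
   vertices[triangles[, 2], , drop = FALSE] +
   vertices[triangles[, 3], , drop = FALSE]) / 3
}

## Boundary loops of a triangle subset: returns list of integer vectors of
## vertex ids, each an ordered closed loop. Non-manifold junctions are not
## expected on the meshes produced here.
meshBoundaryLoops <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  if (length(bkey) == 0) return(list())
  be <- e[match(bkey, key), , drop = FALSE]
  ## walk loops
  nxt <- split(seq_len(nrow(be)), be[, 1])
  nxt2 <- split(seq_len(nrow(be)), be[, 2])
  used <- logical(nrow(be))
  loops <- list()
  for (start in seq_len(nrow(be))) {
    if (used[start]) next
    loop <- c(be[start, 1], be[start, 2])
    used[start] <- TRUE
    repeat {
      tail <- loop[length(loop)]
      cand <- c(nxt[[as.character(tail)]], nxt2[[as.character(tail)]])
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      k <- cand[1]
      used[k] <- TRUE
      nb <- if (be[k, 1] == tail) be[k, 2] else be[k, 1]
      if (nb == loop[1]) break
      loop <- c(loop, nb)
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

## Build an icosphere (subdivided icosahedron); used in tests and examples.
#' Unit icosphere triangle mesh
#' @param subdiv number of 4-to-1 subdivisions.
#' @param radius sphere radius (mm).
#' @return list with `vertices`, `triangles`.
#' @export
icosphere <- function(subdiv = 2, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  Tri <- matrix(c(1,12,6, 1,6,2, 1,2,8, 1,8,11, 1,11,12, 2,6,10, 6,12,5,
                  12,11,3, 11,8,7, 8,2,9, 4,10,5, 4,5,3, 4,3,7, 4,7,9,
                  4,9,10, 5,10,6, 3,5,12, 7,3,11, 9,7,8, 10,9,2),
                ncol = 3, byrow = TRUE)
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (is.null(id)) {
        p <- (V[a, ] + V[b, ]) / 2
        p <- p / sqrt(sum(p^2))
        V <<- rbind(V, p)
        id <- nrow(V)
        assign(key, id, envir = mid)
      }
      id
    }
    newT <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(Tri))) {
      a <- Tri[t, 1]; b <- Tri[t, 2]; cc <- Tri[t, 3]
      ab <- getMid(a, b); bc <- getMid(b, cc); ca <- getMid(cc, a)
      newT <- rbind(newT, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    Tri <- newT
  }
  list(vertices = V * radius, triangles = Tri)
}
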