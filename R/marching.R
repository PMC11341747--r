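## Marching-tetrahedra isosurface extraction on a uniform grid.
##
## Each grid cube is split into the six Kuhn tetrahedra sharing the main
## diagonal; the same split in every cube makes the induced triangulation
## consistent across cube faces, so a closed zero level set that stays
## inside the grid yields a watertight triangle mesh. Surface vertices are
## keyed by the grid edge they lie on, which welds shared vertices exactly
## and deterministically.

## Kuhn split: cube corners numbered v = bx + 2*by + 4*bz.
.tetDef <- matrix(c(
  0L, 1L, 3L, 7L,
  0L, 1L, 5L, 7L,
  0L, 2L, 3L, 7L,
  0L, 2L, 6L, 7L,
  0L, 4L, 5L, 7L,
  0L, 4L, 6L, 7L), ncol = 4, byrow = TRUE)

## Per-sign-pattern triangle tables. Pattern code: sum over inside corners
## of 2^(local index - 1). Each entry: list of triangles; a triangle is a
## 3 x 2 matrix of local corner indices (edge endpoints); `ref` gives the
## local corners spanning the inside region (orientation reference).
.buildTetCases <- function() {
  cases <- vector("list", 16)
  for (code in 1:14) {
    ins <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0L)
    outs <- setdiff(1:4, ins)
    if (length(ins) == 1 || length(ins) == 3) {
      a <- if (length(ins) == 1) ins else outs
      others <- setdiff(1:4, a)
      tri <- matrix(c(a, others[1], a, others[2], a, others[3]),
                    ncol = 2, byrow = TRUE)
      cases[[code + 1]] <- list(tris = list(tri), ref = ins)
    } else if (length(ins) == 2) {
      a <- ins[1]; b <- ins[2]; cc <- outs[1]; d <- outs[2]
      e1 <- c(a, cc); e2 <- c(a, d); e3 <- c(b, d); e4 <- c(b, cc)
      t1 <- rbind(e1, e2, e3)
      t2 <- rbind(e1, e3, e4)
      cases[[code + 1]] <- list(tris = list(t1, t2), ref = ins)
    }
  }
  cases
}
.tetCases <- .buildTetCases()

#' Extract the zero isosurface of a scalar field on a uniform grid
#'
#' @param f 3-d array of field values (negative inside).
#' @param origin coordinates of grid point `[1,1,1]` (mm).
#' @param h grid spacing (mm).
#' @return list with `vertices` (n x 3) and `triangles` (m x 3, 1-based,
#'   consistently outward-oriented).
#' @keywords internal
marchingTetrahedra <- function(f, origin, h) {
  dims <- dim(f)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  fv <- as.numeric(f)
  fv[fv == 0] <- 1e-12          # break exact-zero ties deterministically
  inside <- fv < 0

  ## cubes with a sign change
  idx3 <- function(i, j, k) {
    outer3 <- outer(i, (j - 1L) * nx, "+")
    sweep3 <- outer(as.vector(outer3), (k - 1L) * nx * ny, "+")
    as.vector(sweep3)
  }
  ci <- seq_len(nx - 1L); cj <- seq_len(ny - 1L); ck <- seq_len(nz - 1L)
  base <- idx3(ci, cj, ck)
  off <- c(0L, 1L, nx, nx + 1L, nx * ny, nx * ny + 1L, nx * ny + nx,
           nx * ny + nx + 1L)   # corners v0..v7 (bit order x, y, z)
  cnt <- integer(length(base))
  for (o in off) cnt <- cnt + inside[base + o]
  mixed <- base[cnt > 0L & cnt < 8L]
  if (length(mixed) == 0)
    return(list(vertices = matrix(0, 0, 3), triangles = matrix(0L, 0, 3)))

  ## corner grid ids of all tets from mixed cubes
  corn <- outer(mixed, off, "+")          # ncube x 8
  tg <- matrix(0, nrow = length(mixed) * 6L, ncol = 4L)
  for (t in 1:6)
    tg[seq_along(mixed) + (t - 1L) * length(mixed), ] <-
      corn[, .tetDef[t, ] + 1L]
  ftet <- matrix(fv[tg], ncol = 4L)
  stet <- ftet < 0
  code <- stet[, 1] + 2L * stet[, 2] + 4L * stet[, 3] + 8L * stet[, 4]
  keep <- code > 0L & code < 15L
  tg <- tg[keep, , drop = FALSE]
  ftet <- ftet[keep, , drop = FALSE]
  code <- code[keep]

  ptOf <- function(id) {
    id0 <- id - 1
    k <- id0 %/% (nx * ny)
    r <- id0 %% (nx * ny)
    j <- r %/% nx
    i <- r %% nx
    cbind(origin[1] + i * h, origin[2] + j * h, origin[3] + k * h)
  }

  e1 <- e2 <- e3 <- NULL        # triangle corner edges (grid-id pairs)
  refp <- NULL                  # per-triangle inside reference point
  for (cd in sort(unique(code))) {
    cs <- .tetCases[[cd + 1]]
    rows <- which(code == cd)
    tgc <- tg[rows, , drop = FALSE]
    rp <- ptOf(tgc[, cs$ref[1]])
    if (length(cs$ref) > 1)
      rp <- (rp + ptOf(tgc[, cs$ref[2]])) / 2
    for (tr in cs$tris) {
      e1 <- rbind(e1, cbind(tgc[, tr[1, 1]], tgc[, tr[1, 2]]))
      e2 <- rbind(e2, cbind(tgc[, tr[2, 1]], tgc[, tr[2, 2]]))
      e3 <- rbind(e3, cbind(tgc[, tr[3, 1]], tgc[, tr[3, 2]]))
      refp <- rbind(refp, rp)
    }
  }

  ## weld vertices by grid edge
  allE <- rbind(e1, e2, e3)
  lo <- pmin(allE[, 1], allE[, 2]); hi <- pmax(allE[, 1], allE[, 2])
  key <- lo * (nx * ny * nz + 1) + hi
  uk <- sort(unique(key))
  vid <- match(key, uk)
  m <- nrow(e1)
  tri <- cbind(vid[1:m], vid[m + 1:m], vid[2 * m + 1:m])

  ## vertex positions by interpolation along each unique edge
  pos <- match(uk, key)
  ulo <- lo[pos]; uhi <- hi[pos]
  fl <- fv[ulo]; fh <- fv[uhi]
  tt <- fl / (fl - fh)
  V <- ptOf(ulo) * (1 - tt) + ptOf(uhi) * tt

  ## orient outward: normal should point away from the inside reference
  p1 <- V[tri[, 1], , drop = FALSE]
  p2 <- V[tri[, 2], , drop = FALSE]
  p3 <- V[tri[, 3], , drop = FALSE]
  n <- .rowCross(p2 - p1, p3 - p1)
  ctr <- (p1 + p2 + p3) / 3
  flip <- rowSums(n * (ctr - refp)) < 0
  tmp <- tri[flip, 2]
  tri[flip, 2] <- tri[flip, 3]
  tri[flip, 3] <- tmp

  ## drop degenerate (zero-area) slivers from vertices hitting grid nodes
  keepT <- tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3]
  list(vertices = V, triangles = tri[keepT, , drop = FALSE])
}

.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
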