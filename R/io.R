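## Surface-mesh I/O: STL (binary and ASCII) and legacy VTK PolyData,
## with a JSON sidecar carrying cap labels, centerlines and measured
## metadata that the mesh formats cannot hold.

#' Write a lumen surface to disk
#'
#' @param geom a `bifurcationGeometry`.
#' @param path output file path; extension is advisory, `format` decides.
#' @param format one of `"stl"` (binary), `"stl-ascii"`, `"vtk"` (legacy
#'   ASCII PolyData). Default guessed from the extension (binary STL for
#'   `.stl`).
#' @param sidecar write `<path>.json` with caps, centerlines, diameters
#'   and dome metadata (default TRUE).
#' @return `path`, invisibly.
#' @export
writeGeometry <- function(geom, path, format = NULL, sidecar = TRUE) {
  stopifnot(inherits(geom, "bifurcationGeometry"))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl", vtk = "vtk", vtp = "vtk",
                     stop("cannot guess format from extension of ", path))
  }
  V <- geom$vertices; Tri <- geom$triangles
  switch(format,
    "stl" = .writeStlBinary(V, Tri, path),
    "stl-ascii" = .writeStlAscii(V, Tri, path),
    "vtk" = .writeVtkPolyData(V, Tri, path),
    stop("unsupported format: ", format))
  if (sidecar) {
    meta <- list(
      caps = lapply(geom$caps, function(cp)
        list(role = cp$role, branch = cp$branch, origin = cp$origin,
             normal = cp$normal, radius = cp$radius)),
      centerlines = geom$centerlines,
      parent_diameter = geom$parent_diameter,
      daughter_diameters = geom$daughter_diameters,
      bifurcation_angles = geom$bifurcation_angles,
      dome = geom$dome, edge_length = geom$edge_length)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a lumen surface from disk
#'
#' Reads STL (binary or ASCII, auto-detected) or legacy VTK PolyData.
#' Duplicated vertices are welded (exact coordinate match after reading),
#' and a `<path>.json` sidecar written by [writeGeometry()] is restored
#' when present. Non-watertight input is reported with its boundary-edge
#' count but still returned; repair beyond vertex welding is out of scope.
#'
#' @param path input file.
#' @return a `bifurcationGeometry` (without implicit-surface closures for
#'   meshes of unknown provenance).
#' @export
readGeometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("format error: ", path, " is empty")
  ext <- tolower(tools::file_ext(path))
  mesh <- if (ext %in% c("vtk", "vtp")) .readVtkPolyData(path)
          else .readStl(path)
  if (nrow(mesh$triangles) == 0)
    stop("format error: no triangles found in ", path)
  nb <- meshBoundaryEdgeCount(mesh$triangles)
  if (nb > 0)
    warning("non-manifold/open surface in ", path, ": ", nb,
            " boundary edges after welding")
  geom <- structure(list(
    vertices = mesh$vertices, triangles = mesh$triangles,
    cap_labels = list(inlet = integer(0), outlets = list()),
    caps = list(), centerlines = list(),
    parent_diameter = NA_real_, daughter_diameters = numeric(0),
    bifurcation_angles = numeric(0), dome = NULL,
    sdf = NULL, sdf_open = NULL, sdf_vessel = NULL, sdf_dome = NULL,
    sdf_sac = NULL, edge_length = NA_real_, params = list(kind = "imported")),
    class = "bifurcationGeometry")
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = FALSE)
    geom$caps <- lapply(meta$caps, function(cp)
      list(role = cp$role, branch = cp$branch,
           origin = as.numeric(unlist(cp$origin)),
           normal = as.numeric(unlist(cp$normal)),
           radius = as.numeric(cp$radius)))
    geom$centerlines <- lapply(meta$centerlines, function(cl)
      matrix(as.numeric(unlist(cl)), ncol = 3, byrow = TRUE))
    geom$parent_diameter <- as.numeric(meta$parent_diameter)
    geom$daughter_diameters <- as.numeric(unlist(meta$daughter_diameters))
    geom$bifurcation_angles <- as.numeric(unlist(meta$bifurcation_angles))
    geom$edge_length <- as.numeric(meta$edge_length)
    if (!is.null(meta$dome)) {
      geom$dome <- list(center = as.numeric(unlist(meta$dome$center)),
                        semiaxes = as.numeric(unlist(meta$dome$semiaxes)),
                        axis = as.numeric(unlist(meta$dome$axis)),
                        neck_s = as.numeric(meta$dome$neck_s))
      geom$sdf_dome <- local({
        d <- geom$dome
        adim <- which.max(abs(d$axis))
        function(p) sdfSpheroidAxis(p, d$center, d$semiaxes[1],
                                    d$semiaxes[2], adim)
      })
    }
  }
  geom
}

.writeStlBinary <- function(V, Tri, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(Tri)), con, size = 4, endian = "little")
  p1 <- V[Tri[, 1], , drop = FALSE]
  p2 <- V[Tri[, 2], , drop = FALSE]
  p3 <- V[Tri[, 3], , drop = FALSE]
  n <- .rowCross(p2 - p1, p3 - p1)
  n <- n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
  block <- t(cbind(n, p1, p2, p3))           # 12 floats per facet
  for (i in seq_len(ncol(block))) {
    writeBin(block[, i], con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

.writeStlAscii <- function(V, Tri, path) {
  p1 <- V[Tri[, 1], , drop = FALSE]
  p2 <- V[Tri[, 2], , drop = FALSE]
  p3 <- V[Tri[, 3], , drop = FALSE]
  n <- .rowCross(p2 - p1, p3 - p1)
  n <- n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
  fmt <- function(m) sprintf("%.9e %.9e %.9e", m[, 1], m[, 2], m[, 3])
  txt <- c("solid aneutreat",
           as.vector(rbind(
             paste0("facet normal ", fmt(n)),
             "  outer loop",
             paste0("    vertex ", fmt(p1)),
             paste0("    vertex ", fmt(p2)),
             paste0("    vertex ", fmt(p3)),
             "  endloop",
             "endfacet")),
           "endsolid aneutreat")
  writeLines(txt, path)
  invisible(path)
}

.readStl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  isAscii <- identical(rawToChar(head), "solid") && {
    ## binary STL may also start with "solid": check facet count plausibility
    sz <- file.size(path)
    txt <- readLines(path, n = 2, warn = FALSE)
    length(txt) >= 2 && grepl("facet|endsolid", txt[2])
  }
  tri9 <- if (isAscii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("format error: malformed ASCII STL ", path,
           " (vertex line count ", length(vl), ")")
    num <- matrix(as.numeric(unlist(strsplit(trimws(sub("\\s*vertex\\s+", "",
           vl)), "\\s+"))), ncol = 3, byrow = TRUE)
    num
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.finite(nf) || nf <= 0 || 84 + nf * 50 > file.size(path) + 2)
      stop("format error: corrupt binary STL ", path)
    vals <- matrix(0, nf, 12)
    for (i in seq_len(nf)) {
      vals[i, ] <- readBin(con, "numeric", n = 12, size = 4,
                           endian = "little")
      readBin(con, "raw", n = 2)
    }
    matrix(t(vals[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
  }
  ## weld exactly equal vertices in first-occurrence order; welding can
  ## collapse sliver facets whose corners coincide -- drop those
  key <- paste(tri9[, 1], tri9[, 2], tri9[, 3])
  uk <- unique(key)
  vid <- match(key, uk)
  V <- tri9[match(uk, key), , drop = FALSE]
  Tri <- matrix(vid, ncol = 3, byrow = TRUE)
  ok <- Tri[, 1] != Tri[, 2] & Tri[, 2] != Tri[, 3] & Tri[, 1] != Tri[, 3]
  list(vertices = V, triangles = Tri[ok, , drop = FALSE])
}

.writeVtkPolyData <- function(V, Tri, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aneutreat surface", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(V), "double")), con)
  writeLines(sprintf("%.12g %.12g %.12g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(paste("POLYGONS", nrow(Tri), nrow(Tri) * 4), con)
  writeLines(sprintf("3 %d %d %d", Tri[, 1] - 1L, Tri[, 2] - 1L,
                     Tri[, 3] - 1L), con)
  invisible(path)
}

.readVtkPolyData <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)
  if (length(ip) != 1) stop("format error: no POINTS section in ", path)
  np <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  ig <- grep("^POLYGONS", txt)
  if (length(ig) != 1) stop("format error: no POLYGONS section in ", path)
  nums <- as.numeric(unlist(strsplit(trimws(txt[(ip + 1):(ig - 1)]), "\\s+")))
  if (length(nums) < np * 3) stop("format error: short POINTS block in ", path)
  V <- matrix(nums[seq_len(np * 3)], ncol = 3, byrow = TRUE)
  nt <- as.integer(strsplit(txt[ig], "\\s+")[[1]][2])
  tn <- as.integer(unlist(strsplit(trimws(txt[(ig + 1):(ig + nt)]), "\\s+")))
  m <- matrix(tn, ncol = 4, byrow = TRUE)
  if (any(m[, 1] != 3L)) stop("format error: non-triangle polygons in ", path)
  list(vertices = V, triangles = m[, 2:4, drop = FALSE] + 1L)
}

#' Write a wireframe as a legacy VTK PolyData line set
#'
#' @param frame a `wireframe`.
#' @param path output `.vtk` path.
#' @export
writeWireframeVtk <- function(frame, path) {
  stopifnot(inherits(frame, "wireframe"))
  V <- frame$nodes; S <- frame$struts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aneutreat wireframe", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(V), "double")), con)
  writeLines(sprintf("%.12g %.12g %.12g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(paste("LINES", nrow(S), nrow(S) * 3), con)
  writeLines(sprintf("2 %d %d", S[, 1] - 1L, S[, 2] - 1L), con)
  writeLines(c(paste("CELL_DATA", nrow(S)), "SCALARS wire_id int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", frame$wire_id), con)
  invisible(path)
}
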