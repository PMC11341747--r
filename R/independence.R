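## Mesh-independence machinery: solve the same case on a ladder of mesh
## densities and report successive changes of the monitored quantities
## (aneurysm inflow Q and maximum wall shear stress).

#' Mesh-independence study
#'
#' Solves steady flow on the same geometry at increasing mesh densities
#' and reports the successive relative changes of the aneurysm inflow
#' (neck-plane influx; for dome-less geometries the total outflow) and
#' the maximum wall shear stress. The first density at which both
#' changes drop below `threshold` (default 1%) is flagged.
#'
#' @param geom a generated `bifurcationGeometry`.
#' @param frame optional deployed `wireframe` coupled as a porous screen.
#' @param densities increasing vector of at least three mesh densities
#'   (elements/mm^3).
#' @param fluid a [fluidModel()]. @param config a [solverConfig()].
#' @param porosity screen porosity used when `frame` is given.
#' @param threshold relative-change criterion (default 0.01).
#' @return data frame with one row per density (`density`, `h`, `Q_in`,
#'   `WSS_max`, `dQ_rel`, `dWSS_rel`); attribute `first_independent`
#'   holds the first density meeting the criterion (NA if none).
#' @export
meshIndependenceStudy <- function(geom, frame = NULL, densities,
                                  fluid = fluidModel(),
                                  config = solverConfig(),
                                  porosity = NULL, threshold = 0.01) {
  if (length(densities) < 3)
    stop("a mesh-independence study needs at least 3 densities")
  if (any(diff(densities) <= 0))
    stop("densities must be strictly increasing")
  hasDome <- !is.null(geom$dome)
  if (hasDome) {
    meas <- measureAneurysm(geom)
    np <- meas$neck_plane
    plane <- samplingPlane(np$origin + 0.15 * np$normal, np$normal,
                           meas$d_n / 2 + 0.5, role = "neck")
  }
  out <- data.frame(density = densities, h = densities^(-1 / 3),
                    Q_in = NA_real_, WSS_max = NA_real_,
                    dQ_rel = NA_real_, dWSS_rel = NA_real_)
  for (i in seq_along(densities)) {
    mesh <- meshDomain(geom, frame = frame, density = densities[i])
    if (!is.null(frame) && !is.null(porosity))
      mesh <- applyDeviceScreen(mesh, frame, porosity)
    fl <- solveSteady(mesh, fluid, config)
    out$Q_in[i] <- if (hasDome) integrateInflux(fl, plane)
                   else sum(fl$Q_out)
    out$WSS_max[i] <- wallShearStress(
      fl, if (hasDome) "sac" else "wall")$wss_max
    if (i > 1) {
      out$dQ_rel[i] <- abs(out$Q_in[i] - out$Q_in[i - 1]) /
        max(abs(out$Q_in[i - 1]), 1e-12)
      out$dWSS_rel[i] <- abs(out$WSS_max[i] - out$WSS_max[i - 1]) /
        max(abs(out$WSS_max[i - 1]), 1e-12)
    }
  }
  ok <- which(out$dQ_rel < threshold & out$dWSS_rel < threshold)
  attr(out, "first_independent") <-
    if (length(ok)) out$density[ok[1]] else NA_real_
  attr(out, "threshold") <- threshold
  out
}
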