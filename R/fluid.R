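## Fluid and solver configuration containers.

#' Newtonian fluid model
#'
#' Blood is modelled as an incompressible Newtonian fluid; the defaults
#' are the standard cerebrovascular values (density 1000 kg/m^3, dynamic
#' viscosity 0.004 Pa s).
#'
#' @param density kg/m^3. @param dynamic_viscosity Pa s.
#' @return a `fluidModel`.
#' @export
fluidModel <- function(density = 1000, dynamic_viscosity = 0.004) {
  stopifnot(density > 0, dynamic_viscosity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluidModel")
}

#' Steady-solver configuration
#'
#' @param inlet_flow inlet volumetric flow, ml/min. The reference mean
#'   internal-carotid-artery flow is 230 ml/min; for synthetic
#'   MCA-only domains the value is set directly per case.
#' @param outlet_gauge_pressure fixed gauge pressure (Pa) applied at all
#'   outlets (equal at both outlets by default).
#' @param rel_residual_tol,abs_residual_tol convergence thresholds: the
#'   iteration is converged when the normalized momentum residual drops
#'   below `rel_residual_tol` times its scale, or below
#'   `abs_residual_tol` absolutely (defaults 1e-5 / 1e-8).
#' @param max_iterations pseudo-time iteration cap.
#' @param mesh_density_target elements per mm^3 (reference value 4000;
#'   desk-scale runs use far coarser grids).
#' @param device_coupling `"screen"` (homogenized porous screen, the
#'   default) or `"resolved"` (no-slip strut faces; requires grids fine
#'   enough to resolve strut diameters).
#' @param cfl advective Courant number for the pseudo-time step.
#' @return a `solverConfig`.
#' @export
solverConfig <- function(inlet_flow = 230, outlet_gauge_pressure = 0,
                         rel_residual_tol = 1e-5, abs_residual_tol = 1e-8,
                         max_iterations = 6000,
                         mesh_density_target = 4000,
                         device_coupling = c("screen", "resolved"),
                         cfl = 0.35) {
  stopifnot(inlet_flow > 0,
            rel_residual_tol > 0, rel_residual_tol < 1,
            abs_residual_tol > 0, abs_residual_tol < 1,
            max_iterations >= 1, cfl > 0)
  structure(list(inlet_flow = inlet_flow,
                 outlet_gauge_pressure = outlet_gauge_pressure,
                 rel_residual_tol = rel_residual_tol,
                 abs_residual_tol = abs_residual_tol,
                 max_iterations = max_iterations,
                 mesh_density_target = mesh_density_target,
                 device_coupling = match.arg(device_coupling),
                 cfl = cfl),
            class = "solverConfig")
}

## ml/min -> mm^3/s
mlMinToMm3s <- function(q) q * 1000 / 60
## mm^3/s -> ml/min
mm3sToMlMin <- function(q) q * 60 / 1000
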