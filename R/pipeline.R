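## End-to-end case orchestration: generate -> size -> deploy -> solve ->
## report, for the three arms (no device, braided stent, Contour) of a
## synthetic bifurcation-aneurysm case.

#' Case configuration
#'
#' Assembles the full configuration of a treatment-comparison case. Two
#' presets reproduce the package's reference synthetic cases: a large
#' wide-neck aneurysm (`"caseI"`, d_n 8.58 / d_a 9.37 mm) and a small
#' narrow-neck one (`"caseII"`, d_n 3.11 / d_a 5.56 mm), with untreated
#' parent inflows of 126.4 and 74.4 ml/min respectively.
#'
#' @param preset `"caseI"`, `"caseII"` or `"custom"`.
#' @param ... overrides of any configuration field (see Details).
#' @details Fields: `geometry` (argument list for
#'   [generateBifurcationAneurysm()]), `inlet_flow` (ml/min),
#'   `stented_daughter` (1 or 2; the braided stent lands in this
#'   daughter, the other one is monitored), `density` (elements/mm^3),
#'   `devices` (`"auto"` or `list(contour=, braided=)` product codes),
#'   `crimp_radius` (mm), `schedule` (release increments),
#'   `rel_residual_tol`, `max_iterations`, `seed`.
#' @return a `caseConfig`.
#' @export
caseConfig <- function(preset = c("caseI", "caseII", "custom"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    caseI = list(
      geometry = list(parent_diameter = 2.4,
                      daughter_diameters = c(2.1, 2.2),
                      branch_angles = c(70, 80), neck_width = 8.58,
                      dome_semiaxes = c(9.37 / 2, 4.2),
                      parent_length = 12, daughter_length = 12,
                      daughter_offsets = c(0, -1.5),
                      edge_length = 0.25),
      inlet_flow = 126.4),
    caseII = list(
      geometry = list(parent_diameter = 2.8,
                      daughter_diameters = c(2.8, 1.9),
                      branch_angles = c(55, 65), neck_width = 3.11,
                      dome_semiaxes = c(5.56 / 2, 2.5),
                      parent_length = 12, daughter_length = 12,
                      edge_length = 0.2),
      inlet_flow = 74.4),
    custom = list(geometry = NULL, inlet_flow = 100))
  cfg <- utils::modifyList(c(base, list(
    stented_daughter = 1L, density = 8, devices = "auto",
    crimp_radius = 0.35, schedule = 48, rel_residual_tol = 1e-4,
    max_iterations = 8000, seed = 1L, preset = preset)), list(...))
  if (is.null(cfg$geometry))
    stop("a custom caseConfig needs an explicit `geometry` argument list")
  structure(cfg, class = "caseConfig")
}

#' Run a full treatment-comparison case
#'
#' Generates the lumen, measures the aneurysm, sizes both devices,
#' virtually deploys them, solves steady flow for the three arms (no
#' device / braided stent / Contour) on the same mesh and inlet flow,
#' and assembles the comparison report. All arms share one geometry and
#' mesh so treated/untreated differences are attributable to the device
#' coupling alone.
#'
#' @param config a [caseConfig()].
#' @param outdir optional output directory; when given, surfaces,
#'   deployed wireframes and the report (CSV + JSON) are written there.
#' @param arms subset of `c("nd", "stent", "contour")` to run.
#' @return a `caseResult`: per-arm fluxes and WSS, device selections,
#'   comparison report, and provenance (config hash, package version).
#' @export
runCase <- function(config, outdir = NULL,
                    arms = c("nd", "stent", "contour")) {
  stopifnot(inherits(config, "caseConfig"))
  t0 <- Sys.time()
  geom <- do.call(generateBifurcationAneurysm, config$geometry)
  meas <- measureAneurysm(geom, stented_daughter = config$stented_daughter)
  cat_log("measured d_n = %.2f mm, d_a = %.2f mm, sdr = %.2f",
          meas$d_n, meas$d_a, meas$sdr)
  catg <- deviceCatalogue()
  if (identical(config$devices, "auto")) {
    spec_c <- selectContour(meas$d_n, meas$d_a, catg)
    spec_b <- selectBraided(
      config$geometry$daughter_diameters[config$stented_daughter], catg)
  } else {
    spec_c <- .catalogueByCode(catg$contour, config$devices$contour)
    spec_b <- .catalogueByCode(catg$braided, config$devices$braided)
  }
  cat_log("selected %s (%g mm) and %s (%g x %g mm)",
          spec_c$product_code, spec_c$nominal_diameter_mm,
          spec_b$product_code, spec_b$nominal_diameter_mm, spec_b$length_mm)

  mesh <- meshDomain(geom, density = config$density)
  scfg <- solverConfig(inlet_flow = config$inlet_flow,
                       rel_residual_tol = config$rel_residual_tol,
                       max_iterations = config$max_iterations)
  fluid <- fluidModel()
  np <- meas$neck_plane
  mon <- c(2L, 1L)[config$stented_daughter]     # non-stented daughter
  mon_name <- paste0("daughter", mon)
  cl_mon <- geom$centerlines[[mon_name]]
  ddir <- {
    v <- cl_mon[nrow(cl_mon), ] - cl_mon[1, ]
    v / sqrt(sum(v^2))
  }
  ddiam <- geom$daughter_diameters[mon]
  pl_dv <- samplingPlane(cl_mon[1, ] + ddir * 3 * ddiam, ddir,
                         ddiam / 2 + 0.3, role = "daughter")

  ## ---- deploy both devices first (the neck measurement plane sits
  ## just sac-side of the deployed device crowns: the device surface is
  ## the treated sac boundary, and all arms share one plane) ----
  frames <- list(); states <- list(); porosities <- list()
  if ("stent" %in% arms) {
    frame <- buildBraidedStent(spec_b$nominal_diameter_mm,
                               spec_b$length_mm)
    porosities$stent <- computePorosity(frame, list(
      type = "cylinder", radius = spec_b$nominal_diameter_mm / 2,
      length = spec_b$length_mm))
    path <- stentPath(geom, config$stented_daughter)
    st <- crimpWireframe(frame, config$crimp_radius, path)
    states$stent <- releaseWireframe(st, frame, geom,
                                     schedule = config$schedule)
    frames$stent <- deployedFrame(states$stent, frame)
  }
  if ("contour" %in% arms) {
    frame <- buildContour(spec_c$nominal_diameter_mm)
    porosities$contour <- computePorosity(frame, list(
      type = "bowl", radius = spec_c$nominal_diameter_mm / 2))
    Rb <- spec_c$nominal_diameter_mm / 2
    prox <- max(12, 2.2 * Rb)
    path <- deliveryPath(rbind(np$origin - prox * np$normal,
                               np$origin + (Rb + 1) * np$normal),
                         role = "neck")
    st <- crimpWireframe(frame, config$crimp_radius, path)
    states$contour <- releaseWireframe(
      st, frame, geom, schedule = config$schedule,
      relax_params = list(deploy_end = prox + Rb))
    frames$contour <- deployedFrame(states$contour, frame)
  }
  crown <- 0
  for (fr in frames) {
    lat <- sweep(fr$nodes, 2, np$origin)
    s <- as.numeric(lat %*% np$normal)
    rad2 <- rowSums(lat^2) - s^2
    nearaxis <- rad2 < (0.5 * meas$d_n + 0.3)^2
    if (any(nearaxis)) crown <- max(crown, s[nearaxis])
  }
  pl_neck <- samplingPlane(np$origin + (crown + 0.2) * np$normal,
                           np$normal, meas$d_n / 2 + 0.5, role = "neck")

  fields <- list(); metrics <- list()
  for (arm in arms) {
    armmesh <- if (arm %in% names(frames))
      applyDeviceScreen(mesh, frames[[arm]], porosities[[arm]])
    else mesh
    fl <- solveSteady(armmesh, fluid, scfg)
    if (!fl$converged)
      stop("stage solve (arm ", arm, "): solver did not converge in ",
           scfg$max_iterations, " iterations")
    wss <- wallShearStress(fl, "sac")
    metrics[[arm]] <- list(
      Q_in = integrateInflux(fl, pl_neck),
      Q_in_DV = integrateInflux(fl, pl_dv),
      WSS_max_sac = wss$wss_max, WSS_p99_sac = wss$wss_p99,
      Q_outlets = fl$Q_out, mass_imbalance = fl$mass_imbalance,
      iterations = length(fl$residual_history))
    fields[[arm]] <- fl
    cat_log("arm %-7s Q_in %6.2f  Q_in_DV %6.2f  WSS_max(sac) %5.2f Pa",
            arm, metrics[[arm]]$Q_in, metrics[[arm]]$Q_in_DV,
            metrics[[arm]]$WSS_max_sac)
  }

  qin <- vapply(metrics, `[[`, numeric(1), "Q_in")
  qdv <- vapply(metrics, `[[`, numeric(1), "Q_in_DV")
  names(qin)[names(qin) == "nd"] <- "nd"
  report <- if ("nd" %in% names(metrics))
    comparisonReport(list(list(id = config$preset, Q_in = as.list(qin),
                               Q_in_DV = as.list(qdv))))
  else NULL

  prov <- list(config_hash = .hashConfig(config),
               package_version = as.character(
                 utils::packageVersion("aneutreat")),
               timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  res <- structure(list(
    config = config, measures = meas, devices = list(contour = spec_c,
                                                     braided = spec_b),
    porosities = porosities, metrics = metrics, report = report,
    provenance = prov, fields = fields, deployments = states,
    frames = frames,
    planes = list(neck = pl_neck, daughter = pl_dv), geometry = geom),
    class = "caseResult")
  if (!is.null(outdir)) .writeCaseResult(res, outdir)
  res
}

#' @export
print.caseResult <- function(x, ...) {
  cat("caseResult (", x$config$preset, "): d_n ", round(x$measures$d_n, 2),
      " mm, devices ", x$devices$contour$product_code, " / ",
      x$devices$braided$product_code, "\n", sep = "")
  for (arm in names(x$metrics))
    cat(sprintf("  %-8s Q_in %7.2f  Q_in_DV %7.2f  WSS_max(sac) %6.2f Pa\n",
                arm, x$metrics[[arm]]$Q_in, x$metrics[[arm]]$Q_in_DV,
                x$metrics[[arm]]$WSS_max_sac))
  if (!is.null(x$report)) {
    cat("  inflow reductions:\n")
    print(x$report$inflow, row.names = FALSE)
  }
  invisible(x)
}

.catalogueByCode <- function(tab, code) {
  hit <- which(tab$product_code == code)
  if (length(hit) != 1) stop("unknown product code: ", code)
  structure(lapply(tab, `[`, hit), class = "deviceSpec")
}

.hashConfig <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

.writeCaseResult <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeGeometry(res$geometry, file.path(outdir, "lumen.vtk"),
                format = "vtk")
  for (arm in names(res$frames))
    writeWireframeVtk(res$frames[[arm]],
                      file.path(outdir, paste0(arm, "_deployed.vtk")))
  if (!is.null(res$report)) {
    utils::write.csv(res$report$inflow,
                     file.path(outdir, "report_inflow.csv"),
                     row.names = FALSE)
    if (!is.null(res$report$daughter))
      utils::write.csv(res$report$daughter,
                       file.path(outdir, "report_daughter.csv"),
                       row.names = FALSE)
  }
  out <- list(measures = res$measures[c("d_n", "d_a", "sdr")],
              devices = list(contour = res$devices$contour$product_code,
                             braided = res$devices$braided$product_code),
              porosities = res$porosities,
              metrics = res$metrics, report = res$report,
              provenance = res$provenance)
  jsonlite::write_json(out, file.path(outdir, "case_result.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

cat_log <- function(fmt, ...) {
  message(sprintf(paste0("[aneutreat] ", fmt), ...))
}

#' Build the small in-memory fixture bundle used by the test-suite
#'
#' Deterministic for a fixed seed: a short verification tube with an
#' analytic (Hagen-Poiseuille) flow field, a coarse aneurysm geometry
#' and low-wire-count device frames.
#'
#' @param seed integer seed (the bundle is deterministic; the seed is
#'   recorded and applied for any future stochastic options).
#' @return named list of fixtures.
#' @export
makeFixtures <- function(seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  tube <- tubeGeometry(3, 10, edge_length = 0.3)
  mesh <- meshDomain(tube, density = 200)
  field <- analyticTubeField(tube, mesh, inlet_flow = 60)
  aneu <- generateBifurcationAneurysm(
    2.8, c(2.8, 1.9), c(45, 45), neck_width = 3.11,
    dome_semiaxes = c(5.56 / 2, 2.5), parent_length = 8,
    daughter_length = 8, edge_length = 0.35)
  list(seed = seed,
       tube_geom = tube, tube_mesh = mesh, tube_field = field,
       aneurysm_geom = aneu,
       svb_small = buildBraidedStent(2.25, 10, wires = 8),
       contour_small = buildContour(5, wires_per_layer = 12,
                                    nodes_per_wire = 10))
}

#' Analytic Hagen-Poiseuille flow field on a tube mesh
#'
#' Fills a `flowField` with the closed-form parabolic profile and linear
#' pressure, bypassing the solver; the canonical oracle for the
#' flux/WSS integration machinery.
#'
#' @param geom a [tubeGeometry()] (axis +x).
#' @param mesh a `hemoMesh` built on it.
#' @param inlet_flow flow in ml/min.
#' @return a `flowField` (flagged converged; residual history empty).
#' @export
analyticTubeField <- function(geom, mesh, inlet_flow) {
  stopifnot(identical(geom$params$kind, "tube"))
  Q <- mlMinToMm3s(inlet_flow)
  R <- geom$parent_diameter / 2
  L <- geom$params$length
  mu <- 0.004
  umax <- 2 * Q / (pi * R^2)
  UU <- vector("list", 3)
  for (d in 1:3) {
    fd <- mesh$nc; fd[d] <- fd[d] + 1L
    arr <- array(0, dim = fd)
    if (d == 1) {
      pts <- .gridCenters(mesh$origin, fd, mesh$h, stagger = d)
      r2 <- pts[, 2]^2 + pts[, 3]^2
      arr[] <- umax * pmax(0, 1 - r2 / R^2)
    }
    UU[[d]] <- arr
  }
  pts <- .gridCenters(mesh$origin, mesh$nc, mesh$h, stagger = 0L)
  G <- 8 * mu * Q / (pi * R^4)           # pressure gradient, Pa/mm
  P <- array(G * (L - pts[, 1]), dim = mesh$nc)
  structure(list(U = UU[[1]], V = UU[[2]], W = UU[[3]], P = P,
                 mesh = mesh, fluid = fluidModel(),
                 config = solverConfig(inlet_flow = inlet_flow),
                 dt = NA_real_, residual_history = numeric(0),
                 converged = TRUE, Q_in = inlet_flow,
                 Q_out = inlet_flow, mass_imbalance = 0),
            class = "flowField")
}
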