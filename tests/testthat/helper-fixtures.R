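## Shared fixtures, built lazily and cached for the whole test session
## (several files reuse the same solved flow fields).

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

## Verification tube: 3 mm diameter, 10 mm long, 60 ml/min, solved at
## the reference test density (300 elements/mm^3).
tubeCase <- function() fixture("tubeCase", function() {
  geom <- tubeGeometry(3, 10, edge_length = 0.3)
  mesh <- meshDomain(geom, density = 300)
  field <- solveSteady(mesh, fluidModel(),
                       solverConfig(inlet_flow = 60,
                                    max_iterations = 4000))
  list(geom = geom, mesh = mesh, field = field,
       Q = 60, R = 1.5, L = 10, mu = 0.004)
})

## Symmetric Y bifurcation, equal daughters and outlet pressures.
symmetricYCase <- function() fixture("symmetricYCase", function() {
  geom <- generateBifurcation(3, c(2.2, 2.2), c(40, 40),
                              parent_length = 6, daughter_length = 6,
                              edge_length = 0.3)
  field <- solveSteady(meshDomain(geom, density = 150), fluidModel(),
                       solverConfig(inlet_flow = 120,
                                    max_iterations = 8000))
  list(geom = geom, field = field)
})

## Small narrow-neck aneurysm used for the refinement study.
toyAneurysm <- function() fixture("toyAneurysm", function() {
  do.call(generateBifurcationAneurysm,
          utils::modifyList(caseConfig("caseII")$geometry,
                            list(parent_length = 7, daughter_length = 7,
                                 edge_length = 0.3)))
})

## Screen-limit toy: a plain symmetric bifurcation with a braided bowl
## deployed inside one daughter, where the screen spans the whole
## cross-section (no geometric bypass, so the sealed limit is exact).
toyScreenGeom <- function() fixture("toyScreenGeom", function() {
  generateBifurcation(3, c(2.2, 2.2), c(45, 45), parent_length = 7,
                      daughter_length = 9, edge_length = 0.3)
})

toyScreenFrame <- function() fixture("toyScreenFrame", function() {
  geom <- toyScreenGeom()
  frame <- buildContour(5, wires_per_layer = 36, nodes_per_wire = 14)
  cl <- geom$centerlines$daughter1
  dir <- (cl[2, ] - cl[1, ]) / sqrt(sum((cl[2, ] - cl[1, ])^2))
  path <- deliveryPath(rbind(cl[1, ] - 8 * dir, cl[1, ] + 7 * dir))
  st <- crimpWireframe(frame, 0.35, path)
  dep <- releaseWireframe(st, frame, geom, schedule = 24,
                          relax_params = list(deploy_end = 8 + 5))
  deployedFrame(dep, frame)
})

## Solve the screen toy with an optional screen porosity; memoised.
toySolve <- function(porosity = NULL) {
  key <- paste0("toySolve_", if (is.null(porosity)) "nd" else porosity)
  fixture(key, function() {
    geom <- toyScreenGeom()
    mesh <- meshDomain(geom, density = 40)
    if (!is.null(porosity))
      mesh <- applyDeviceScreen(mesh, toyScreenFrame(), porosity)
    solveSteady(mesh, fluidModel(),
                solverConfig(inlet_flow = 120, rel_residual_tol = 1e-4,
                             max_iterations = 10000))
  })
}

## Sampling plane across the screened daughter, downstream of the bowl.
toyScreenPlane <- function() fixture("toyScreenPlane", function() {
  geom <- toyScreenGeom()
  cl <- geom$centerlines$daughter1
  dir <- (cl[2, ] - cl[1, ]) / sqrt(sum((cl[2, ] - cl[1, ])^2))
  samplingPlane(cl[1, ] + 7 * dir, dir, 1.4, role = "daughter")
})

## Full three-arm treatment comparison on the large synthetic case at
## coarse density (shared between the directional acceptance check and
## any inspection).
caseIResult <- function() fixture("caseIResult", function() {
  suppressWarnings(suppressMessages(
    runCase(caseConfig("caseI", density = 27))))
})

## Refinement ladder on the toy aneurysm.
toyIndependence <- function() fixture("toyIndependence", function() {
  meshIndependenceStudy(
    toyAneurysm(), densities = c(8, 27, 64),
    config = solverConfig(inlet_flow = 74.4, rel_residual_tol = 1e-4,
                          max_iterations = 10000))
})

## Analytic Poiseuille field fixtures (no solver involved).
analyticTube <- function(flow = 60) {
  key <- paste0("analyticTube_", flow)
  fixture(key, function() {
    fx <- makeFixtures(1)
    if (flow == 60) return(fx)
    field <- analyticTubeField(fx$tube_geom, fx$tube_mesh, flow)
    fx$tube_field <- field
    fx
  })
}

## Construct a minimal geometry whose sac is a sphere of radius r cut by
## the plane {x = x_cut}: the analytic oracle for measureAneurysm.
sphereCapGeometry <- function(r = 5, x_cut = 0, edge = 0.15) {
  center <- c(x_cut + 0, 0, 0)
  sdf_dome <- function(p) sqrt(rowSums(sweep(p, 2, center)^2)) - r
  sdf <- function(p) pmax(sdf_dome(p), x_cut - p[, 1])
  h <- edge
  lo <- center - r - 3 * h; hi <- center + r + 3 * h
  lo[1] <- x_cut - 3 * h
  n <- as.integer(ceiling((hi - lo) / h)) + 1L
  gx <- lapply(1:3, function(d) lo[d] + (seq_len(n[d]) - 1) * h)
  pts <- as.matrix(expand.grid(x = gx[[1]], y = gx[[2]], z = gx[[3]]))
  f <- array(sdf(pts), dim = n)
  surf <- aneutreat:::marchingTetrahedra(f, lo, h)
  structure(list(
    vertices = surf$vertices, triangles = surf$triangles,
    cap_labels = list(inlet = integer(0), outlets = list()),
    caps = list(), centerlines = list(),
    parent_diameter = 1, daughter_diameters = numeric(0),
    bifurcation_angles = numeric(0),
    dome = list(center = center, semiaxes = c(r, r), axis = c(1, 0, 0),
                neck_s = x_cut),
    sdf = sdf, sdf_open = sdf, sdf_vessel = NULL,
    sdf_dome = sdf_dome, sdf_sac = sdf,
    edge_length = edge, params = list(kind = "synthetic-sac")),
    class = "bifurcationGeometry")
}
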