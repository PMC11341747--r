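test_that("the steady solve reproduces Hagen-Poiseuille flow", {
  tc <- tubeCase()
  fl <- tc$field
  expect_true(fl$converged)
  Q <- tc$Q * 1000 / 60                       # mm^3/s
  R <- tc$R
  u_cl_th <- 2 * Q / (pi * R^2)
  u_cl <- interpolateVelocity(fl, matrix(c(5, 0, 0), 1, 3))[1]
  expect_lt(abs(u_cl - u_cl_th) / u_cl_th, 0.03)
  dp <- interpolatePressure(fl, matrix(c(2, 0, 0), 1, 3)) -
    interpolatePressure(fl, matrix(c(8, 0, 0), 1, 3))
  dp_th <- 8 * tc$mu * 6 * Q / (pi * R^4)
  expect_lt(abs(dp - dp_th) / dp_th, 0.05)
  ## discrete mass balance is exact to projection accuracy
  expect_lt(fl$mass_imbalance, 1e-3)
  expect_equal(fl$Q_in, tc$Q, tolerance = 0.01)
})

test_that("wall shear stress on the tube is uniform at 4 mu Q / (pi R^3)", {
  tc <- tubeCase()
  w <- wallShearStress(tc$field, "parent")
  s <- w$samples
  mid <- s$x > 2 & s$x < 8
  wss_th <- 4 * tc$mu * (tc$Q * 1000 / 60) / (pi * tc$R^3)
  expect_lt(max(abs(s$wss[mid] - wss_th)) / wss_th, 0.05)
})

test_that("plane flux integration agrees with the solved tube flow", {
  tc <- tubeCase()
  for (x0 in c(3, 7)) {
    q <- integrateInflux(tc$field,
                         samplingPlane(c(x0, 0, 0), c(1, 0, 0), 1.6,
                                       role = "daughter"))
    expect_lt(abs(q - tc$Q) / tc$Q, 0.01)
  }
})

test_that("a symmetric bifurcation splits the flow 50/50", {
  sy <- symmetricYCase()
  fl <- sy$field
  expect_true(fl$converged)
  split <- fl$Q_out[1] / sum(fl$Q_out)
  expect_lt(abs(split - 0.5), 0.01)
  expect_lt(fl$mass_imbalance, 1e-3)
})

test_that("residuals decay and divergence is reported with history", {
  tc <- tubeCase()
  rh <- tc$field$residual_history
  expect_gt(length(rh), 10)
  expect_lt(rh[length(rh)] / max(rh), 1e-4)
  ## a hopeless time step must abort with the residual trail
  g <- tubeGeometry(3, 6, edge_length = 0.4)
  mesh <- meshDomain(g, density = 60)
  expect_error(
    solveSteady(mesh, fluidModel(),
                solverConfig(inlet_flow = 60, cfl = 80,
                             max_iterations = 200)),
    "diverged")
})

test_that("a porosity-1 screen reproduces the untreated field exactly", {
  nd <- toySolve()
  open <- toySolve(porosity = 1)
  expect_identical(open$U, nd$U)
  expect_identical(open$V, nd$V)
  expect_identical(open$P, nd$P)
})

test_that("a sealed screen passes below 1e-6 of the inlet flow", {
  sealed <- toySolve(porosity = 0)
  q <- integrateInflux(sealed, toyScreenPlane(), mode = "net")
  expect_lt(abs(q) / sealed$config$inlet_flow, 1e-6)
  ## mass still balances through the open daughter
  expect_lt(sealed$mass_imbalance, 1e-3)
})

test_that("trans-screen flux decreases strictly with decreasing porosity", {
  plane <- toyScreenPlane()
  q <- vapply(c(0.9, 0.6, 0.3), function(eps)
    integrateInflux(toySolve(porosity = eps), plane), numeric(1))
  q_nd <- integrateInflux(toySolve(), plane)
  expect_true(all(diff(q) < 0))
  expect_lt(q[1], q_nd)
})

test_that("mesh refinement shrinks the flux change on the toy aneurysm", {
  study <- toyIndependence()
  expect_identical(nrow(study), 3L)
  expect_true(all(is.na(study$dQ_rel[1])))
  expect_true(all(study$dQ_rel[-1] > 0))
  expect_lt(study$dQ_rel[3], study$dQ_rel[2])
  expect_error(meshIndependenceStudy(toyAneurysm(), densities = c(8, 27)),
               "at least 3")
  expect_error(meshIndependenceStudy(toyAneurysm(),
                                     densities = c(27, 8, 64)),
               "increasing")
})
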