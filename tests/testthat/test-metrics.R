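test_that("plane flux integration matches the closed-form tube flow", {
  fx <- analyticTube()
  fl <- fx$tube_field
  pl <- samplingPlane(c(5, 0, 0), c(1, 0, 0), 1.6, role = "daughter")
  q <- integrateInflux(fl, pl)
  expect_lt(abs(q - 60) / 60, 0.005)            # quadrature within 0.5%
  ## net flux equals influx in unidirectional flow
  expect_equal(integrateInflux(fl, pl, mode = "net"), q, tolerance = 1e-9)
  ## plane invariance along the tube (mass conservation restated)
  q2 <- integrateInflux(fl, samplingPlane(c(8, 0, 0), c(1, 0, 0), 1.6,
                                          role = "daughter"))
  expect_lt(abs(q2 - q) / q, 0.005)
  ## reversed normal sees zero influx but the negated net flux
  plr <- samplingPlane(c(5, 0, 0), c(-1, 0, 0), 1.6, role = "daughter")
  expect_equal(integrateInflux(fl, plr), 0)
  expect_equal(integrateInflux(fl, plr, mode = "net"), -q,
               tolerance = 1e-9)
  ## zero field integrates to zero
  fl0 <- fl
  fl0$U[] <- 0; fl0$V[] <- 0; fl0$W[] <- 0
  expect_equal(integrateInflux(fl0, pl), 0)
  expect_error(integrateInflux(fl, samplingPlane(c(5, 0, 10), c(1, 0, 0),
                                                 1, role = "neck")),
               "outside")
})

test_that("wall shear stress matches 4 mu Q / (pi R^3) and scales linearly", {
  fx <- analyticTube()
  w <- wallShearStress(fx$tube_field, "parent")
  s <- w$samples
  mid <- s$x > 2 & s$x < 8
  wss_th <- 4 * 0.004 * 1000 / (pi * 1.5^3)
  expect_lt(abs(median(s$wss[mid]) - wss_th) / wss_th, 0.05)
  expect_gte(w$wss_max, w$wss_p99)
  ## doubling Q doubles WSS (Stokes-dominated tube flow)
  fx2 <- analyticTube(flow = 120)
  w2 <- wallShearStress(fx2$tube_field, "parent")
  expect_equal(median(w2$samples$wss[mid]) /
                 median(s$wss[mid]), 2, tolerance = 0.01)
  ## multiplying viscosity by k multiplies WSS by k
  fl_mu <- fx$tube_field
  fl_mu$fluid <- fluidModel(dynamic_viscosity = 0.008)
  w3 <- wallShearStress(fl_mu, "parent")
  expect_equal(median(w3$samples$wss[mid]) /
                 median(s$wss[mid]), 2, tolerance = 1e-9)
  ## zero flow gives identically zero WSS
  fl0 <- fx$tube_field
  fl0$U[] <- 0
  expect_equal(wallShearStress(fl0, "parent")$wss_max, 0)
})

test_that("percentage reduction reproduces the printed worked examples", {
  expect_equal(percentReduction(126.4, 16.5), 86.9)
  expect_equal(percentReduction(126.4, 11.2), 91.1)
  expect_equal(percentReduction(51.8, 5.7), 89.0)
  ## printed inputs for the last cell give 91.3 (the table's 91.4 is a
  ## rounding inconsistency upstream of the printed flows)
  expect_equal(percentReduction(51.8, 4.5), 91.3)
  expect_equal(percentReduction(100, 100), 0)
  expect_error(percentReduction(-1, 5), "positive")
  expect_error(percentReduction(100, -5), "non-negative")
})

test_that("relative change reproduces the printed worked examples", {
  expect_equal(relativeChange(23.01, 27.75), 20.60)
  expect_equal(relativeChange(23.01, 19.47), -15.38)
  expect_equal(relativeChange(36.45, 37.68), 3.37)
  expect_equal(relativeChange(36.45, 35.79), -1.81)
  expect_equal(relativeChange(10, 10), 0)
  expect_error(relativeChange(0, 5), "positive")
})

test_that("rounding is half away from zero at the stated precision", {
  expect_equal(roundHalfAway(87.95, 1), 88.0)   # base round() gives 87.9
  expect_equal(roundHalfAway(-8.595, 2), -8.60)
  expect_equal(roundHalfAway(11.985, 2), 11.99)
  expect_equal(roundHalfAway(2.5), 3)
  expect_equal(roundHalfAway(-2.5), -3)
})

test_that("the comparison report aggregates per-case rounded values", {
  cases <- list(
    list(id = "I", Q_in = list(nd = 126.4, stent = 16.5, contour = 11.2),
         Q_in_DV = list(nd = 23.01, stent = 19.47, contour = 27.75)),
    list(id = "II", Q_in = list(nd = 51.8, stent = 5.7, contour = 4.5),
         Q_in_DV = list(nd = 36.45, stent = 35.79, contour = 37.68)))
  rep <- comparisonReport(cases)
  expect_equal(rep$inflow$reduction, c(86.9, 91.1, 89.0, 91.3))
  expect_equal(rep$daughter$relative_change,
               c(-15.38, 20.60, -1.81, 3.37))
  expect_equal(rep$averages$reduction_stent, 87.95)
  expect_equal(rep$averages$dv_change_contour, 11.99)
  expect_equal(rep$averages$dv_change_stent, -8.60)
  ## a single case averages to its own values
  rep1 <- comparisonReport(cases[1])
  expect_equal(rep1$averages$reduction_contour, 91.1)
  expect_error(comparisonReport(list(list(id = "x", Q_in = list(a = 1)))),
               "pairing")
  expect_error(comparisonReport(list()), "at least one")
})
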