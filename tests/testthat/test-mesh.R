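test_that("element count tracks density times lumen volume", {
  g <- tubeGeometry(3, 10, edge_length = 0.3)
  V <- pi * 1.5^2 * 10
  for (dens in c(100, 300)) {
    mesh <- meshDomain(g, density = dens)
    expect_lt(abs(mesh$n_elements - dens * V) / (dens * V), 0.2)
  }
  ## refining density 4x reduces the cell size by ~4^(1/3)
  m1 <- meshDomain(g, density = 100)
  m4 <- meshDomain(g, density = 400)
  expect_equal(m1$h / m4$h, 4^(1 / 3), tolerance = 1e-9)
  expect_error(meshDomain(g, density = 0.01), "infeasible")
})

test_that("strut-labelled faces lie near every strut", {
  g <- tubeGeometry(3, 10, edge_length = 0.3)
  fr <- buildBraidedStent(2.25, 8, wires = 8)
  fr$nodes[, 1] <- fr$nodes[, 1] + 1      # place inside the tube
  fr$reference_nodes <- fr$nodes
  mesh <- meshDomain(g, frame = fr, density = 100)
  expect_false(is.null(mesh$strut_faces))
  h <- mesh$h
  ## every strut midpoint has a labelled face within the marking radius
  mid <- (fr$nodes[fr$struts[, 1], ] + fr$nodes[fr$struts[, 2], ]) / 2
  for (d in 1:3) {
    fd <- mesh$nc; fd[d] <- fd[d] + 1L
    off <- rep(0.5, 3); off[d] <- 0
    idx <- which(mesh$strut_faces[[d]], arr.ind = TRUE)
    fc <- cbind(mesh$origin[1] + (idx[, 1] - 1 + off[1]) * h,
                mesh$origin[2] + (idx[, 2] - 1 + off[2]) * h,
                mesh$origin[3] + (idx[, 3] - 1 + off[3]) * h)
    for (k in seq(1, nrow(mid), by = 7)) {
      dmin <- min(sqrt(rowSums(sweep(fc, 2, mid[k, ])^2)))
      expect_lt(dmin, max(fr$strut_radius, h / 2) + h)
    }
  }
})

test_that("screen application validates porosity and has exact limits", {
  g <- tubeGeometry(3, 10, edge_length = 0.3)
  fr <- buildBraidedStent(2.25, 8, wires = 8)
  fr$nodes[, 1] <- fr$nodes[, 1] + 1
  mesh <- meshDomain(g, density = 100)
  expect_error(applyDeviceScreen(mesh, fr, -0.1), "porosity")
  expect_error(applyDeviceScreen(mesh, fr, 1.5), "porosity")
  expect_equal(applyDeviceScreen(mesh, fr, 1)$screen$coef, 0)
  expect_identical(applyDeviceScreen(mesh, fr, 0)$screen$coef, Inf)
  s1 <- applyDeviceScreen(mesh, fr, 0.9)$screen$coef
  s2 <- applyDeviceScreen(mesh, fr, 0.6)$screen$coef
  s3 <- applyDeviceScreen(mesh, fr, 0.3)$screen$coef
  expect_true(s1 < s2 && s2 < s3)   # drag decreases with porosity
  ## estimated screen normals are unit vectors
  scr <- applyDeviceScreen(mesh, fr, 0.6)$screen
  for (d in 1:3)
    if (length(scr$idx[[d]]))
      expect_equal(rowSums(scr$normal[[d]]^2),
                   rep(1, length(scr$idx[[d]])), tolerance = 1e-6)
})
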