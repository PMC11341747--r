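test_that("generated lumens are watertight, deterministic and labelled", {
  g <- generateBifurcationAneurysm(2.8, c(2.8, 1.9), c(65, 55),
                                   neck_width = 3.11,
                                   dome_semiaxes = c(2.78, 2.5),
                                   parent_length = 7, daughter_length = 7,
                                   edge_length = 0.3)
  expect_identical(meshBoundaryEdgeCount(g$triangles), 0L)
  g2 <- generateBifurcationAneurysm(2.8, c(2.8, 1.9), c(65, 55),
                                    neck_width = 3.11,
                                    dome_semiaxes = c(2.78, 2.5),
                                    parent_length = 7, daughter_length = 7,
                                    edge_length = 0.3)
  expect_identical(g$vertices, g2$vertices)
  expect_identical(g$triangles, g2$triangles)

  ## cap triangles are planar to 1e-6 mm and every cap is labelled
  expect_gt(length(g$cap_labels$inlet), 0)
  expect_length(g$cap_labels$outlets, 2)
  for (cp in g$caps) {
    ids <- if (cp$role == "inlet") g$cap_labels$inlet
           else g$cap_labels$outlets[[cp$branch]]
    vids <- unique(as.vector(g$triangles[ids, ]))
    d <- abs(sweep(g$vertices[vids, , drop = FALSE], 2, cp$origin) %*%
               cp$normal)
    expect_lt(max(d), 1e-6)
  }
  ## centerlines start on the parent axis and end at cap centres
  expect_equal(unname(g$centerlines$parent[1, ]), c(-7, 0, 0))
  for (b in c("daughter1", "daughter2")) {
    cl <- g$centerlines[[b]]
    expect_equal(cl[1, 2:3], c(0, 0))  # branch point on the parent axis
    cap <- Filter(function(cp) identical(cp$branch, b), g$caps)[[1]]
    expect_equal(unname(cl[nrow(cl), ]), unname(cap$origin),
                 tolerance = 1e-8)
  }
})

test_that("measured neck and dome widths recover construction values", {
  cases <- list(
    list(d_n = 8.58, d_a = 9.37, par = 2.4, dau = c(2.1, 2.2),
         ang = c(80, 70), az = 4.2),
    list(d_n = 3.11, d_a = 5.56, par = 2.8, dau = c(2.8, 1.9),
         ang = c(65, 55), az = 2.5))
  for (cs in cases) {
    g <- generateBifurcationAneurysm(cs$par, cs$dau, cs$ang,
                                     neck_width = cs$d_n,
                                     dome_semiaxes = c(cs$d_a / 2, cs$az),
                                     parent_length = 8,
                                     daughter_length = 8,
                                     edge_length = 0.25)
    m <- measureAneurysm(g)
    expect_lt(abs(m$d_n - cs$d_n) / cs$d_n, 0.02)
    expect_lt(abs(m$d_a - cs$d_a) / cs$d_a, 0.02)
    expect_gte(m$d_a, m$d_n)
    expect_equal(sum(m$neck_plane$normal^2), 1, tolerance = 1e-9)
    expect_equal(m$sdr, cs$dau[2] / cs$par, tolerance = 1e-12)
  }
})

test_that("sphere and hemisphere sacs give the closed-form measures", {
  ## sphere of diameter 10 intersected at its equator: d_n = d_a = 10
  g <- sphereCapGeometry(r = 5, x_cut = 0)
  m <- measureAneurysm(g)
  expect_equal(m$d_n, 10, tolerance = 0.02)
  expect_equal(m$d_a, 10, tolerance = 0.02)
  ## hemispherical dome of radius r on the neck plane: d_n = d_a = 2r
  g2 <- sphereCapGeometry(r = 3, x_cut = 0, edge = 0.12)
  m2 <- measureAneurysm(g2)
  expect_equal(m2$d_n, 6, tolerance = 0.02)
  expect_equal(m2$d_a, 6, tolerance = 0.02)
  ## the fitted neck plane is the cutting plane
  expect_equal(abs(m2$neck_plane$normal[1]), 1, tolerance = 1e-3)
})

test_that("infeasible generator parameters raise informative errors", {
  expect_error(
    generateBifurcationAneurysm(3, c(2, 2), c(45, 45), neck_width = 5,
                                dome_semiaxes = c(0, 0)),
    "positive")
  expect_error(
    generateBifurcationAneurysm(3, c(2, 2), c(45, 45), neck_width = 12,
                                dome_semiaxes = c(4, 3)),
    "neck width")
  expect_error(
    generateBifurcationAneurysm(3, c(2, 2), c(45, 45), neck_width = 5,
                                dome_semiaxes = c(4, 3),
                                neck_offset = -1),
    "does not intersect")
  expect_error(measureAneurysm(tubeGeometry(3, 10)), "neck contour")
})

test_that("seeded dome perturbation is reproducible and optional", {
  base <- list(2.8, c(2.8, 1.9), c(65, 55))
  g1 <- generateBifurcationAneurysm(2.8, c(2.8, 1.9), c(65, 55),
                                    neck_width = 3.11,
                                    dome_semiaxes = c(2.78, 2.5),
                                    parent_length = 6, daughter_length = 6,
                                    edge_length = 0.4,
                                    perturb = 0.05, seed = 7)
  g2 <- generateBifurcationAneurysm(2.8, c(2.8, 1.9), c(65, 55),
                                    neck_width = 3.11,
                                    dome_semiaxes = c(2.78, 2.5),
                                    parent_length = 6, daughter_length = 6,
                                    edge_length = 0.4,
                                    perturb = 0.05, seed = 7)
  expect_identical(g1$vertices, g2$vertices)
  expect_error(
    generateBifurcationAneurysm(2.8, c(2.8, 1.9), c(65, 55),
                                neck_width = 3.11,
                                dome_semiaxes = c(2.78, 2.5),
                                perturb = 0.05),
    "seed")
})
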