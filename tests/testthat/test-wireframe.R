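test_that("braided stent geometry matches its construction contract", {
  for (d in c(2.25, 3)) {
    s <- buildBraidedStent(d, 15)
    r <- sqrt(s$nodes[, 2]^2 + s$nodes[, 3]^2)
    expect_equal(range(r), rep(d / 2, 2), tolerance = 1e-12)
    expect_equal(range(s$nodes[, 1]), c(0, 15), tolerance = 1e-12)
    expect_identical(s$reference_nodes, s$nodes)
    expect_true(all(s$rest_lengths > 0))
  }
  s2 <- buildBraidedStent(2.25, 15)
  expect_identical(buildBraidedStent(2.25, 15), s2)   # deterministic
  expect_error(buildBraidedStent(3, 15, wires = 5), "even")
  expect_error(buildBraidedStent(3, 2, braid_angle = 20), "pitch")
  ## each wire's strut graph is a simple path
  for (w in unique(s2$wire_id)) {
    sub <- s2$struts[s2$wire_id == w, , drop = FALSE]
    deg <- table(as.vector(sub))
    expect_lte(max(deg), 2)
    expect_identical(sum(deg == 1), 2L)
  }
})

test_that("counter-rotating helix crossings match the closed form", {
  ## 2 wires per family over one pitch: each of the 4 opposite-family
  ## pairs crosses twice, so 2 * (w/2)^2 = 8 crossings
  R <- 1.5; beta <- 45
  pitch <- 2 * pi * R / tan(beta * pi / 180)
  s <- buildBraidedStent(3, pitch, wires = 4, braid_angle = beta,
                         node_spacing = 0.2)
  A <- s$struts[s$wire_id %in% 1:2, , drop = FALSE]
  B <- s$struts[s$wire_id %in% 3:4, , drop = FALSE]
  N <- s$nodes
  segdist <- function(p1, p2, q1, q2) {
    t <- seq(0, 1, length.out = 12)
    P <- sweep(outer(t, p2 - p1), 2, p1, "+")
    Q <- sweep(outer(t, q2 - q1), 2, q1, "+")
    min(sqrt(pmax(0, outer(rowSums(P^2), rowSums(Q^2), "+") -
                    2 * P %*% t(Q))))
  }
  hits <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- segdist(N[A[i, 1], ], N[A[i, 2], ], N[B[j, 1], ], N[B[j, 2], ])
    if (d < 0.04)
      hits <- rbind(hits, (N[A[i, 1], ] + N[A[i, 2], ] +
                           N[B[j, 1], ] + N[B[j, 2], ]) / 4)
  }
  cl <- rep(0L, nrow(hits)); k <- 0L
  for (i in seq_len(nrow(hits))) {
    if (cl[i] == 0L) { k <- k + 1L; cl[i] <- k }
    for (j in seq_len(nrow(hits)))
      if (cl[j] == 0 &&
          sqrt(sum((hits[i, ] - hits[j, ])^2)) < 0.5) cl[j] <- cl[i]
  }
  expect_identical(k, 8L)
})

test_that("the Contour bowl has the nominal rim and wire count", {
  c14 <- buildContour(14)
  expect_identical(length(unique(c14$wire_id)), 144L)  # 2 x 72 wires
  r <- sqrt(c14$nodes[, 2]^2 + c14$nodes[, 3]^2)
  expect_equal(max(r), 7, tolerance = 1e-9)            # rim = equator
  ## rim nodes sit at the equator plane x = R
  expect_equal(max(c14$nodes[, 1]), 7, tolerance = 1e-9)
  c7 <- buildContour(7)
  expect_equal(max(sqrt(c7$nodes[, 2]^2 + c7$nodes[, 3]^2)), 3.5,
               tolerance = 1e-9)
  expect_error(buildContour(8), "unsupported")
  expect_silent(buildContour(8, allow_any = TRUE))
  ## marker node is inert: no strut references it
  expect_false(c14$params$marker_node %in% as.vector(c14$struts))
})

test_that("porosity follows the definition on a flat patch", {
  ## single straight strut of length L and width w on an A = W x H patch
  L <- 8; rs <- 0.1; W <- 10; H <- 5
  nodes <- rbind(c(1, 2.5, 0), c(1 + L, 2.5, 0))
  frame <- aneutreat:::.newWireframe(nodes, rbind(c(1L, 2L)), 1L, rs,
                                     "braided_stent", 1, L, list())
  p <- computePorosity(frame, list(type = "flat", width = W, height = H),
                       resolution = 0.01)
  expect_equal(p, 1 - L * 2 * rs / (W * H), tolerance = 0.01)
})

test_that("deployed-cylinder braid porosity is near the nominal 60%", {
  s <- buildBraidedStent(2.25, 15)
  p <- computePorosity(s, list(type = "cylinder", radius = 1.125,
                               length = 15))
  expect_lt(abs(p - 0.60), 0.05)
  ## doubling the strut radius strictly decreases porosity
  s2 <- buildBraidedStent(2.25, 15, strut_radius = 2 * s$strut_radius)
  p2 <- computePorosity(s2, list(type = "cylinder", radius = 1.125,
                                 length = 15))
  expect_lt(p2, p)
  ## porosity is scale invariant
  s3 <- buildBraidedStent(4.5, 30, strut_radius = 2 * s$strut_radius)
  p3 <- computePorosity(s3, list(type = "cylinder", radius = 2.25,
                                 length = 30))
  expect_equal(p3, p, tolerance = 0.02)
  expect_error(computePorosity(s, list(type = "cylinder", radius = 2,
                                       length = 15)),
               "not on surface")
})

test_that("bowl porosity is computable and strut-radius monotone", {
  c14 <- buildContour(14)
  p <- computePorosity(c14, list(type = "bowl", radius = 7))
  expect_gt(p, 0.3); expect_lt(p, 0.95)
  c14b <- buildContour(14, strut_radius = 0.03)
  p2 <- computePorosity(c14b, list(type = "bowl", radius = 7))
  expect_lt(p2, p)
})
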