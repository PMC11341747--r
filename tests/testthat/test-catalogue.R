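## The five-row Contour product-selection table, frozen field-for-field.
.contourRows <- data.frame(
  product_code = c("CNS21005-15", "CNS21007-15", "CNS21009-15",
                   "CNS011-15", "CNS014-15"),
  microcatheter_id_in = c(0.021, 0.021, 0.021, 0.027, 0.027),
  nominal_diameter_mm = c(5, 7, 9, 11, 14),
  dn_min = c(2, 3, 4, 5, 7), dn_max = c(3, 5, 6, 8, 10),
  da_min = c(2, 3, 5, 7, 8), da_max = c(3.5, 5.5, 7.5, 8.5, 10.5),
  stringsAsFactors = FALSE)

test_that("the catalogue reproduces the selection table field-for-field", {
  ct <- deviceCatalogue()$contour
  for (col in names(.contourRows))
    expect_equal(ct[[col]], .contourRows[[col]], ignore_attr = TRUE,
                 label = col)
  expect_true(all(ct$dn_min <= ct$dn_max))
  expect_true(all(ct$da_min <= ct$da_max))
  expect_true(all(ct$wires_per_layer == 72))
  expect_true(all(ct$layers == 2))
  br <- deviceCatalogue()$braided
  expect_equal(br$nominal_porosity, rep(0.6, nrow(br)))
  expect_equal(br$nominal_pore_density_per_mm, rep(45, nrow(br)))
  expect_true(all(br$length_mm == 15))
})

test_that("device selection reproduces the worked sizing examples", {
  s1 <- selectContour(8.58, 9.37)
  expect_identical(s1$product_code, "CNS014-15")
  expect_identical(s1$nominal_diameter_mm, 14)
  expect_warning(s2 <- selectContour(3.11, 5.56), "advisory")
  expect_identical(s2$product_code, "CNS21007-15")
  expect_identical(s2$nominal_diameter_mm, 7)
  expect_error(selectContour(12, 12), "sizing error")
  ## braided: smallest nominal diameter covering the landing vessel
  expect_identical(selectBraided(2.1)$product_code, "SVB-2.25x15")
  expect_identical(selectBraided(2.8)$product_code, "SVB-3x15")
  expect_error(selectBraided(4.0), "sizing error")
})

test_that("selection is total on the union of neck ranges and rejects outside", {
  grid <- seq(1, 11, by = 0.05)
  inside <- vapply(grid, function(dn)
    any(.contourRows$dn_min <= dn & dn <= .contourRows$dn_max),
    logical(1))
  for (i in seq_along(grid)) {
    res <- tryCatch(
      suppressWarnings(selectContour(grid[i], d_a = grid[i] + 0.5)),
      error = function(e) NULL)
    expect_identical(!is.null(res), inside[i],
                     label = paste("d_n =", grid[i]))
    if (!is.null(res))
      expect_true(res$dn_min <= grid[i] && grid[i] <= res$dn_max)
  }
})

test_that("overlapping neck ranges prefer d_a containment, then size", {
  ## d_n = 5 is covered by the 7, 9 and 11 mm rows: d_a containment
  ## picks among them ...
  expect_identical(selectContour(5, 8.0)$product_code, "CNS011-15")
  expect_identical(selectContour(5, 6.2)$product_code, "CNS21009-15")
  ## ... and ties (several rows contain d_a) go to the smallest device
  expect_identical(selectContour(5, 5.0)$product_code, "CNS21007-15")
  ## no row contains d_a = 9.5 at d_n = 5: smallest diameter wins, with
  ## a warning that d_a is outside the advisory range
  expect_warning(s <- selectContour(5, 9.5), "advisory")
  expect_identical(s$product_code, "CNS21007-15")
})
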