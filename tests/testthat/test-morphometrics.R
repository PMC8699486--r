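test_that("segmentation finds the right number of cells", {
  sc <- generate_sperm_phantom(small_spec())
  cells <- segment_cells(sc$opd)
  expect_length(cells, 1)
  expect_lt(sqrt(sum((cells[[1]]$centroid_um -
                        sc$truth$cell_centers[1, ])^2)), 0.5)

  blank <- opd_map(matrix(0, 128, 128), 0.16)
  expect_length(segment_cells(blank), 0)
  expect_equal(nrow(measure_cells(blank)), 0)

  # two cells sharing one droplet field of view
  two <- generate_sperm_phantom(small_spec(),
    centers_um = rbind(c(13, 13), c(28, 28)),
    orientations_deg = c(0, 120))
  expect_length(segment_cells(two$opd), 2)
})

test_that("head masks are disjoint from appendage masks and non-empty", {
  sc <- generate_sperm_phantom(small_spec(residual_cytoplasm_fraction = 0.4))
  cell <- segment_cells(sc$opd)[[1]]
  expect_gt(sum(cell$head_mask), 0)
  expect_false(any(cell$head_mask & cell$midpiece_mask))
  expect_false(any(cell$head_mask & cell$cytoplasm_mask))
  acr <- partition_acrosome(cell, sc$opd)
  expect_true(all(cell$head_mask[acr$acrosome_mask]))
})

test_that("moment ellipse recovers rasterized axis ratios", {
  # rasterized 5 x 3 um ellipse -> ratio 0.6; circle -> 1.0
  sc <- generate_sperm_phantom(small_spec(head_major = 5, head_minor = 3))
  ell <- fit_head_ellipse(segment_cells(sc$opd)[[1]])
  expect_equal(ell$radii_ratio, 0.6, tolerance = 0.05)
  expect_equal(ell$major_um, 5, tolerance = 0.1)

  near_circle <- generate_sperm_phantom(
    small_spec(head_major = 4.01, head_minor = 4,
               midpiece_length_um = 0, tail_length_um = 0))
  ellc <- fit_head_ellipse(segment_cells(near_circle$opd)[[1]])
  expect_equal(ellc$radii_ratio, 1.0, tolerance = 0.02)
})

test_that("radii-ratio recovery is monotone over a generative sweep", {
  ratios <- c(0.4, 0.5, 0.6, 0.7, 0.8)
  est <- vapply(ratios, function(r) {
    sc <- generate_sperm_phantom(small_spec(head_major = 5,
                                            head_minor = 5 * r))
    fit_head_ellipse(segment_cells(sc$opd)[[1]])$radii_ratio
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(max(abs(est - ratios)), 0.05)
})

test_that("acrosome partition recovers generative fractions", {
  sc <- generate_sperm_phantom(small_spec(acrosome_fraction = 0.5,
                                          acrosome_opd_scale = 0.6))
  acr <- partition_acrosome(segment_cells(sc$opd)[[1]], sc$opd)
  expect_false(acr$indeterminate)
  expect_equal(acr$acrosome_head_ratio, 50, tolerance = 3 / 50)

  sc65 <- generate_sperm_phantom(small_spec(acrosome_fraction = 0.65))
  a65 <- partition_acrosome(segment_cells(sc65$opd)[[1]], sc65$opd)
  expect_true(a65$acrosome_head_ratio >= 40 &&
                a65$acrosome_head_ratio <= 70)

  # uniform-OPD head has no class contrast
  scu <- generate_sperm_phantom(small_spec(acrosome_opd_scale = 1))
  au <- partition_acrosome(segment_cells(scu$opd)[[1]], scu$opd)
  expect_true(au$indeterminate)
  expect_true(is.na(au$acrosome_head_ratio))
})

test_that("midpiece length, ratio and axis offset are recovered", {
  sc <- generate_sperm_phantom(small_spec(midpiece_length_um = 5))
  cell <- segment_cells(sc$opd)[[1]]
  mid <- measure_midpiece(cell, sc$opd)
  expect_equal(mid$midpiece_head_ratio, 1.0, tolerance = 0.15)
  expect_lt(mid$axis_offset_deg, 5)

  none <- generate_sperm_phantom(small_spec(midpiece_length_um = 0,
                                            tail_length_um = 0))
  m0 <- measure_midpiece(segment_cells(none$opd)[[1]], none$opd)
  expect_equal(m0$midpiece_head_ratio, 0)
  expect_equal(m0$flag, "no_midpiece")
})

test_that("vacuole detection counts, sizes and flags large vacuoles", {
  a <- 2.5; b <- 1.5
  r5 <- sqrt(0.05 * a * b)
  two <- generate_sperm_phantom(small_spec(vacuoles = data.frame(
    du_um = c(-1.4, 1.3), dv_um = c(0.35, -0.35),
    radius_um = r5, depth_nm = 80)))
  v2 <- detect_vacuoles(segment_cells(two$opd)[[1]], two$opd)
  expect_equal(v2$vacuole_count, 2)
  expect_equal(v2$vacuole_area_fraction, 0.10, tolerance = 0.02 / 0.10)
  expect_false(v2$any_large)

  clean <- generate_sperm_phantom(small_spec())
  v0 <- detect_vacuoles(segment_cells(clean$opd)[[1]], clean$opd)
  expect_equal(v0$vacuole_count, 0)
  expect_equal(v0$vacuole_area_fraction, 0)
  expect_false(v0$any_large)

  # a large vacuole (25% of the head) on a uniform-OPD head, so the
  # depression cannot straddle the acrosome boundary exclusion band
  r25 <- sqrt(0.25 * a * b)
  big <- generate_sperm_phantom(small_spec(acrosome_opd_scale = 1,
    vacuoles = data.frame(
      du_um = -0.5, dv_um = 0, radius_um = r25, depth_nm = 80)))
  vb <- detect_vacuoles(segment_cells(big$opd)[[1]], big$opd)
  expect_true(vb$any_large)
})

test_that("residual cytoplasm fraction is recovered and zero when absent", {
  sc <- generate_sperm_phantom(small_spec(residual_cytoplasm_fraction = 0.5))
  f <- detect_residual_cytoplasm(segment_cells(sc$opd)[[1]], sc$opd)
  expect_equal(f, 0.5, tolerance = 0.1 / 0.5)

  clean <- generate_sperm_phantom(small_spec())
  expect_equal(detect_residual_cytoplasm(segment_cells(clean$opd)[[1]],
                                         clean$opd), 0)
})

test_that("measure_cell composes all parameters with clean flags", {
  sc <- generate_sperm_phantom(small_spec(acrosome_fraction = 0.5964))
  m <- measure_cells(sc$opd)
  expect_equal(nrow(m), 1)
  expect_equal(m$acrosome_head_ratio_pct, 59.64, tolerance = 3 / 59.64)
  expect_equal(m$flags, "")
  # reported fractions are consistent with the masks exactly
  cell <- segment_cells(sc$opd)[[1]]
  acr <- partition_acrosome(cell, sc$opd)
  expect_equal(acr$acrosome_head_ratio,
               100 * sum(acr$acrosome_mask) / sum(cell$head_mask))
})

test_that("morphometrics are robust to cell rotation", {
  ref <- measure_cells(generate_sperm_phantom(small_spec())$opd)
  for (ang in c(30, 60, 90)) {
    m <- measure_cells(generate_sperm_phantom(
      small_spec(orientation_deg = ang))$opd)
    expect_equal(m$acrosome_head_ratio_pct, 55, tolerance = 3 / 55)
    expect_equal(m$radii_ratio, 0.6, tolerance = 0.05 / 0.6)
    expect_equal(m$midpiece_head_ratio, 1, tolerance = 0.15)
  }
})

test_that("dimensionless ratios are stable under pixel-size rescaling", {
  fine <- generate_sperm_phantom(phantom_spec(image_shape = c(360, 360),
                                              pixel_size = 0.12))
  coarse <- generate_sperm_phantom(phantom_spec(image_shape = c(216, 216),
                                                pixel_size = 0.2))
  mf <- measure_cells(fine$opd)
  mc <- measure_cells(coarse$opd)
  expect_equal(mf$radii_ratio, mc$radii_ratio, tolerance = 0.05)
  expect_equal(mf$acrosome_head_ratio_pct, mc$acrosome_head_ratio_pct,
               tolerance = 4 / 55)
  expect_equal(mf$midpiece_head_ratio, mc$midpiece_head_ratio,
               tolerance = 0.15)
})
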