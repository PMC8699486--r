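test_that("ground-truth morphometrics are the analytic generative values", {
  sp <- small_spec(acrosome_fraction = 0.5)
  tr <- generate_sperm_phantom(sp)$truth$morphometrics
  expect_equal(tr$acrosome_head_ratio_pct, 50)
  expect_equal(tr$vacuole_count, 0)
  expect_equal(tr$vacuole_area_fraction, 0)

  tr2 <- generate_sperm_phantom(small_spec(head_major = 5, head_minor = 3))
  expect_equal(tr2$truth$morphometrics$radii_ratio, 0.6)
})

test_that("vacuole ground truth matches a brute-force rasterization", {
  # two vacuoles, each with area 5% of the head
  a <- 2.5; b <- 1.5
  r5 <- sqrt(0.05 * a * b)
  sp <- small_spec(vacuoles = data.frame(
    du_um = c(-1.3, 1.2), dv_um = c(0.4, -0.3),
    radius_um = r5, depth_nm = 80))
  out <- generate_sperm_phantom(sp)
  expect_equal(out$truth$morphometrics$vacuole_count, 2)
  expect_equal(out$truth$morphometrics$vacuole_area_fraction, 0.10,
               tolerance = 1e-9)
  # rasterized pixel-count oracle agrees with the analytic fraction
  # pixel counting at ~2.7 px vacuole radius carries a few percent of
  # discretization
  orc <- raster_oracle(sp)
  expect_equal(sum(orc$vacuole) / sum(orc$head), 0.10, tolerance = 0.08)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(head_major = 3, head_minor = 5), "head_major")
  expect_error(phantom_spec(acrosome_fraction = 1.2), "acrosome_fraction")
  expect_error(phantom_spec(vacuoles = data.frame(
    du_um = 3, dv_um = 0, radius_um = 0.4, depth_nm = 50)), "outside head")
  expect_error(phantom_spec(pixel_size = 0), "pixel_size")
})

test_that("no-contrast acrosome is allowed but flagged in the truth", {
  tr <- generate_sperm_phantom(small_spec(acrosome_opd_scale = 1))$truth
  expect_false(tr$morphometrics$acrosome_contrast)
})

test_that("droplet rug amplitude and lattice count follow the spec", {
  sp0 <- small_spec(droplet_residual_opd = 0)
  expect_true(all(unclass(generate_droplet_rug(sp0)) == 0))

  sp <- phantom_spec(image_shape = c(1251, 1251), pixel_size = 0.16,
                     droplet_pitch = 40, droplet_residual_opd = 10)
  rug <- generate_droplet_rug(sp)
  expect_equal(max(rug) - min(rug), 10, tolerance = 1e-6)

  # bump centers equal a brute-force hexagonal lattice enumeration
  W <- (1251 - 1) * 0.16
  centers <- hex_lattice(40, W, W)
  bf <- 0
  dy <- 40 * sqrt(3) / 2
  r <- 0
  repeat {
    y <- r * dy
    if (y > W) break
    off <- if (r %% 2 == 1) 20 else 0
    bf <- bf + sum(seq(off, W + 40, by = 40) <= W)
    r <- r + 1
  }
  expect_equal(nrow(centers), bf)
  expect_error(generate_droplet_rug(small_spec(droplet_pitch = 0.2)),
               "pitch")
})

test_that("rendered fringes carry the carrier and contrast", {
  blank <- opd_map(matrix(0, 128, 128), 0.16)
  ig <- render_interferogram(blank, carrier_spec(fx = 0.25, fy = 0.25,
                                                 fringe_contrast = 1))
  # Fourier peak (excluding DC) sits at the carrier
  F <- Mod(stats::fft(unclass(ig)))
  F[1, 1] <- 0
  pk <- which(F == max(F), arr.ind = TRUE)[1, ]
  expect_equal(unname((pk - 1) / 128), c(0.25, 0.25))

  flat <- render_interferogram(blank, carrier_spec(fringe_contrast = 0,
                                                   mean_intensity = 2))
  expect_true(all(unclass(flat) == 2))
})

test_that("a half-wave OPD bump shifts the fringe phase by pi", {
  # Gaussian bump peaking at lambda/2 = 316.5 nm; demodulation round trip
  n <- 256
  x <- matrix(0:(n - 1), n, n, byrow = TRUE) - (n - 1) / 2
  y <- t(x)
  bump <- 316.5 * exp(-(x^2 + y^2) / (2 * 20^2))
  opd <- opd_map(bump, 0.16, wavelength = 633)
  ig <- render_interferogram(opd, carrier_spec())
  fld <- demodulate_sideband(ig, c(0.25, 0.25))
  ph <- Arg(fld)
  ctr <- ph[n / 2, n / 2] - median(ph[1:16, 1:16])
  expect_equal(abs(wrap_to_pi_test(ctr)), pi, tolerance = 0.02)
})

test_that("rendering is reproducible under a fixed seed and clips negatives", {
  blank <- opd_map(matrix(0, 64, 64), 0.16)
  cs <- carrier_spec(detector_noise_sigma = 0.5)
  i1 <- render_interferogram(blank, cs, seed = 7)
  i2 <- render_interferogram(blank, cs, seed = 7)
  expect_identical(unclass(i1), unclass(i2))
  expect_gt(attr(i1, "n_clipped"), 0)
  expect_true(all(unclass(i1) >= 0))
})

test_that("same seed gives bit-identical phantom scenes", {
  s1 <- generate_sperm_phantom(small_spec(seed = 3))
  s2 <- generate_sperm_phantom(small_spec(seed = 3))
  expect_identical(unclass(s1$opd), unclass(s2$opd))
})

test_that("free progressive motion follows the stated kinematics", {
  sp <- small_spec()
  mot <- simulate_motion(sp, n_frames = 10, dt = 0.05,
                         mode = "free_progressive", speeds_um_s = 0.2,
                         headings_deg = 0, jitter_sd_deg = 0)
  tr <- mot$truth$tracks
  expect_equal(max(tr$x_um) - min(tr$x_um), 0.09, tolerance = 1e-12)
  expect_equal(max(tr$y_um) - min(tr$y_um), 0)

  still <- simulate_motion(sp, n_frames = 5, dt = 0.05,
                           mode = "free_progressive", speeds_um_s = 0)
  expect_equal(length(unique(still$truth$tracks$x_um)), 1)
})

test_that("droplet-confined motion stays within the droplet radius", {
  sp <- small_spec(droplet_pitch = 40)
  mot <- simulate_motion(sp, n_frames = 8, dt = 0.05,
                         mode = "droplet_confined", speeds_um_s = 0.1,
                         centers_um = matrix(c(20, 20), 1),
                         droplet_radius_um = 20)
  tr <- mot$truth$tracks
  d <- sqrt((tr$x_um - 20)^2 + (tr$y_um - 20)^2)
  expect_true(all(d <= 20 + 1e-9))
})

test_that("motion rejects impossible speeds and short sequences", {
  sp <- small_spec()
  expect_error(simulate_motion(sp, n_frames = 1, dt = 0.05), "n_frames")
  expect_error(simulate_motion(sp, n_frames = 5, dt = 1e4,
                               speeds_um_s = 10), "exceeds image width")
})
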