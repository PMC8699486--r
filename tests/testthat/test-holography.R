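test_that("carrier estimation recovers synthetic fringes", {
  n <- 256
  blank <- opd_map(matrix(0, n, n), 0.16)
  ig <- render_interferogram(blank, carrier_spec(fx = 0.25, fy = 0.25))
  est <- estimate_carrier(ig)
  expect_equal(unname(est), c(0.25, 0.25), tolerance = 1 / (2 * n))

  expect_error(estimate_carrier(interferogram(matrix(1, 64, 64), 0.16)),
               "no carrier detected")

  # with a cell in the scene and an off-grid carrier
  sc <- generate_sperm_phantom(small_spec())
  ig2 <- render_interferogram(sc$opd, carrier_spec(fx = 0.2, fy = 0.3))
  est2 <- estimate_carrier(ig2)
  expect_lt(max(abs(est2 - c(0.2, 0.3))), 0.005)
})

test_that("sideband demodulation returns the wrapped forward phase", {
  n <- 256
  blank <- opd_map(matrix(0, n, n), 0.16)
  ig <- render_interferogram(blank, carrier_spec())
  ph <- Arg(demodulate_sideband(ig, c(0.25, 0.25)))
  inner <- ph[17:(n - 16), 17:(n - 16)]
  expect_lt(sd(inner), 1e-3)

  # Gaussian phase bump, noiseless: wrapped phase matches the forward model
  x <- matrix(0:(n - 1), n, n, byrow = TRUE) - (n - 1) / 2
  bump <- 150 * exp(-(x^2 + t(x)^2) / (2 * 15^2))
  opd <- opd_map(bump, 0.16)
  ig2 <- render_interferogram(opd, carrier_spec())
  ph2 <- Arg(demodulate_sideband(ig2, c(0.25, 0.25)))
  truth <- 2 * pi * bump / 633
  truth <- truth - (median(ph2[1:16, 1:16]) - 0)  # common offset is free
  d <- (ph2 - truth)[17:(n - 16), 17:(n - 16)]
  expect_lt(sqrt(mean((d - mean(d))^2)), 1e-2)

  expect_error(demodulate_sideband(ig, c(0.05, 0), crop_radius = 0.1),
               "orders overlap")
})

test_that("phase unwrapping restores smooth fields modulo 2*pi", {
  # linear ramp 0 -> 4*pi
  n <- 128
  ramp <- matrix(seq(0, 4 * pi, length.out = n), n, n, byrow = TRUE)
  w <- wrap_to_pi_test(ramp)
  for (m in c("reliability", "itoh")) {
    u <- unwrap_phase(w, method = m)
    off <- (u - ramp)[1, 1]
    expect_equal(off / (2 * pi), round(off / (2 * pi)), tolerance = 1e-9)
    expect_lt(max(abs(u - ramp - off)), 1e-9)
  }
  # constant field is a fixed point
  const <- matrix(1.2, 32, 32)
  expect_equal(unwrap_phase(const), const, ignore_attr = TRUE)
})

test_that("a 3*pi phantom phase unwraps to the pre-wrap oracle", {
  n <- 192
  x <- matrix(0:(n - 1), n, n, byrow = TRUE) - (n - 1) / 2
  ph <- 3 * pi * exp(-(x^2 + t(x)^2) / (2 * 18^2))
  u <- unwrap_phase(wrap_to_pi_test(ph))
  off <- 2 * pi * round((u - ph)[1, 1] / (2 * pi))
  expect_lt(sqrt(mean((u - ph - off)^2)), 1e-3)
})

test_that("unwrap(wrap(phi)) - phi is one global 2*pi multiple on smooth fields", {
  set.seed(42)
  n <- 64
  fx <- matrix(0:(n - 1), n, n, byrow = TRUE) / n
  fy <- t(fx)
  for (i in 1:100) {
    # random smooth field: a few low-frequency cosines, peak ~ +-2.5 cycles
    ph <- matrix(0, n, n)
    for (k in 1:4) {
      ph <- ph + runif(1, -4, 4) *
        cos(2 * pi * (runif(1, 0, 2.5) * fx + runif(1, 0, 2.5) * fy) +
              runif(1, 0, 2 * pi))
    }
    u <- unwrap_phase(wrap_to_pi_test(ph))
    resid <- (u - ph) / (2 * pi)
    expect_lt(max(abs(resid - round(resid[1]))), 1e-6)
  }
})

test_that("phase-to-OPD conversion is the linear wavelength scaling", {
  expect_equal(phase_to_opd(2 * pi, 633), 633)
  expect_equal(phase_to_opd(0, 633), 0)
  expect_equal(phase_to_opd(pi, 633), 316.5)
  ph <- matrix(runif(16), 4, 4)
  expect_equal(phase_to_opd(3 * ph, 633), 3 * phase_to_opd(ph, 633))
})

test_that("background flattening removes fitted polynomials", {
  n <- 128
  U <- matrix(seq(-1, 1, length.out = n), n, n, byrow = TRUE)
  tilt <- opd_map(5 + 10 * U + 3 * t(U), 0.16)
  out <- flatten_background(tilt, order = 1)
  expect_lt(sd(out), 1e-6 * 10)

  offs <- opd_map(matrix(7, n, n), 0.16)
  out0 <- flatten_background(offs, order = 0)
  expect_equal(median(out0), 0)
  expect_error(flatten_background(offs, order = -1), "order")
})

test_that("noiseless reconstruction round trip is sub-nanometer", {
  sc <- generate_sperm_phantom(small_spec(seed = 11))
  ig <- render_interferogram(sc$opd, carrier_spec())
  rec <- reconstruct(ig)
  expect_lt(rmse(rec, sc$opd, margin = 16), 1)
})

test_that("reconstruction of a blank noisy scene has near-zero mean", {
  blank <- opd_map(matrix(0, 256, 256), 0.16)
  ig <- render_interferogram(blank,
                             carrier_spec(detector_noise_sigma = 0.02),
                             seed = 5)
  rec <- reconstruct(ig, carrier = c(0.25, 0.25))
  inner <- unclass(rec)[17:240, 17:240]
  expect_lt(abs(mean(inner)), sd(inner))
})

test_that("reconstruction is equivariant to whole-pixel translations", {
  sp <- small_spec(tail_length_um = 5)
  base <- c(18, 18)
  shift_px <- 8
  sc1 <- generate_sperm_phantom(sp, centers_um = matrix(base, 1))
  sc2 <- generate_sperm_phantom(sp,
    centers_um = matrix(base + shift_px * sp$pixel_size, 1))
  r1 <- reconstruct(render_interferogram(sc1$opd, carrier_spec()))
  r2 <- reconstruct(render_interferogram(sc2$opd, carrier_spec()))
  a <- unclass(r1)[33:200, 33:200]
  b <- unclass(r2)[33:200 + shift_px, 33:200 + shift_px]
  expect_lt(sqrt(mean((a - b)^2)), 0.1)
})

test_that("temporal std of reconstructions scales with detector noise", {
  sigmas <- c(0.01, 0.02)
  blank <- opd_map(matrix(0, 128, 128), 0.16)
  tstd <- vapply(sigmas, function(s) {
    frames <- lapply(1:6, function(k) {
      ig <- render_interferogram(blank, carrier_spec(detector_noise_sigma = s),
                                 seed = 100 + k)
      as_plain <- unclass(reconstruct(ig, carrier = c(0.25, 0.25)))
      as_plain[33:96, 33:96]
    })
    stk <- opd_stack(frames, 0.16, 0.04)
    temporal_noise(stk, 1)$temporal_std_avg
  }, numeric(1))
  expect_equal(tstd[2] / tstd[1], 2, tolerance = 0.2)
})
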