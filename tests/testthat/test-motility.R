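test_that("centroid detection finds cells to sub-pixel accuracy", {
  sc <- generate_sperm_phantom(small_spec())
  cen <- detect_centroids(sc$opd)
  expect_equal(nrow(cen), 1)
  expect_lt(sqrt(sum((cen[1, ] - sc$truth$cell_centers[1, ])^2)), 0.5)

  expect_equal(nrow(detect_centroids(opd_map(matrix(0, 64, 64), 0.16))), 0)

  # five cells matched to the truth by nearest neighbor
  centers <- rbind(c(10, 10), c(30, 10), c(10, 30), c(30, 30), c(20, 20))
  sc5 <- generate_sperm_phantom(small_spec(tail_length_um = 4),
    centers_um = centers, orientations_deg = c(0, 45, 90, 200, 300))
  cen5 <- detect_centroids(sc5$opd)
  expect_equal(nrow(cen5), 5)
  d <- apply(centers, 1, function(p)
    min(sqrt(rowSums(sweep(cen5, 2, p)^2))))
  expect_lt(max(d), 0.5)
})

test_that("linking matches brute-force optimal assignment for separated cells", {
  set.seed(3)
  n <- 5
  p0 <- cbind(runif(n, 5, 55), runif(n, 5, 55))
  # keep cells well separated relative to their per-frame displacement
  frames <- list(p0)
  for (f in 2:10)
    frames[[f]] <- frames[[f - 1]] + matrix(rnorm(2 * n, 0, 0.05), n, 2)
  tracks <- link_tracks(frames, dt = 0.05)
  expect_equal(length(unique(tracks$cell_id)), n)
  # frame-to-frame assignments equal the brute-force optimum
  for (f in 2:10) {
    bf <- brute_force_assignment(frames[[f - 1]], frames[[f]])
    expect_equal(bf, seq_len(n))  # identity is optimal by construction
  }
  # every track is a coherent cell: its positions match one true cell
  for (id in unique(tracks$cell_id)) {
    tr <- tracks[tracks$cell_id == id, ]
    k <- which.min(rowSums(sweep(p0, 2, as.numeric(tr[1, c("x_um", "y_um")]))^2))
    true_pos <- t(vapply(seq_len(10), function(f) frames[[f]][k, ], numeric(2)))
    expect_lt(max(abs(cbind(tr$x_um, tr$y_um) - true_pos)), 1e-9)
  }
})

test_that("links longer than max_disp start new tracks", {
  fr <- list(matrix(c(0, 0), 1, 2), matrix(c(10, 0), 1, 2))
  tracks <- link_tracks(fr, dt = 1, max_disp = 5)
  expect_equal(length(unique(tracks$cell_id)), 2)
})

test_that("track velocity is the mean per-step speed", {
  # 0.01 um steps every 50 ms -> 0.2 um/s
  tr <- tibble::tibble(t_s = (0:9) * 0.05, x_um = (0:9) * 0.01, y_um = 0)
  expect_equal(track_velocity(tr), 0.2)
  expect_equal(track_velocity(tr, method = "net"), 0.2)

  still <- tibble::tibble(t_s = (0:4) * 0.05, x_um = 1, y_um = 2)
  expect_equal(track_velocity(still), 0)
  expect_error(track_velocity(still[1, ]), "at least 2")

  # random walk: equals direct recomputation
  set.seed(9)
  rw <- tibble::tibble(t_s = cumsum(runif(20, 0.01, 0.1)),
                       x_um = cumsum(rnorm(20)), y_um = cumsum(rnorm(20)))
  oracle <- mean(sqrt(diff(rw$x_um)^2 + diff(rw$y_um)^2) / diff(rw$t_s))
  expect_equal(track_velocity(rw), oracle)
})

test_that("velocity is invariant to scene translation and rotation", {
  set.seed(13)
  tr <- tibble::tibble(t_s = (0:9) * 0.05,
                       x_um = cumsum(rnorm(10, 0.01, 0.002)),
                       y_um = cumsum(rnorm(10, 0, 0.002)))
  v0 <- track_velocity(tr)
  shifted <- tr; shifted$x_um <- tr$x_um + 100; shifted$y_um <- tr$y_um - 50
  expect_equal(track_velocity(shifted), v0)
  a <- 0.7
  rot <- tr
  rot$x_um <- cos(a) * tr$x_um - sin(a) * tr$y_um
  rot$y_um <- sin(a) * tr$x_um + cos(a) * tr$y_um
  expect_equal(track_velocity(rot), v0)
})

test_that("motile fraction counts strictly-above-threshold cells", {
  expect_equal(motile_fraction(c(0.1, 0.1, 0, 0, 0), 0.05), 0.4)
  expect_equal(motile_fraction(c(0.01, 0.015), 0.02), 0)
  expect_error(motile_fraction(numeric(0)), "empty")
  # monotone non-increasing in the threshold
  set.seed(5)
  v <- runif(200, 0, 0.3)
  fr <- vapply(seq(0, 0.3, by = 0.02), motile_fraction,
               velocities = v, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("population simulation recovers a known motile proportion", {
  pop <- simulate_track_population(1000, p_motile = 0.2, seed = 42)
  vel <- vapply(split(pop$tracks, pop$tracks$cell_id), track_velocity,
                numeric(1))
  est <- motile_fraction(vel, 0.02)
  expect_equal(est, mean(pop$motile))   # threshold separates the two groups
  ci <- stats::binom.test(sum(pop$motile), 1000, 0.2)$conf.int
  expect_true(est >= ci[1] && est <= ci[2])
})

test_that("pipeline velocity recovery on rendered free-progressive frames", {
  spec <- small_spec()
  mot <- simulate_motion(spec, n_frames = 10, dt = 0.05,
                         mode = "free_progressive", speeds_um_s = 0.15,
                         headings_deg = 70)
  vel <- track_velocities(link_tracks(lapply(mot$frames, detect_centroids),
                                      dt = 0.05))
  expect_equal(nrow(vel), 1)
  expect_equal(vel$velocity_um_s, 0.15, tolerance = 0.1)
})
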