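test_that("wall trajectory: timing, zeros, and cardiac peak count", {
  tr <- make_wall_trajectory(200, 3.2, 4)
  expect_equal(nrow(tr), 200)
  expect_equal(tr$time_s[2] - tr$time_s[1], 3.2 / 200)
  expect_equal(max(tr$time_s) + 3.2 / 200, 3.2)
  expect_equal(c(tr$d_long_mm[1], tr$d_rad_mm[1]), c(0, 0))
  expect_equal(count_peaks(tr$d_rad_mm), 4)
  z <- make_wall_trajectory(50, 3.2, 4, amp_rad_mm = 0, amp_long_mm = 0)
  expect_true(all(z$d_rad_mm == 0) && all(z$d_long_mm == 0))
  expect_error(make_wall_trajectory(50, -1), "duration")
  expect_error(make_wall_trajectory(50, 3.2, 4, amp_rad_mm = -1),
               "amplitudes")
})

test_that("disturbance generator: determinism, zeros, glitch statistics", {
  d1 <- make_disturbance(64, 3.2, c(0.4, 0.25, 0.5), 2.5, c(0.25, 0.15, 0.4),
                         seed = 7)
  d2 <- make_disturbance(64, 3.2, c(0.4, 0.25, 0.5), 2.5, c(0.25, 0.15, 0.4),
                         seed = 7)
  expect_identical(d1, d2)
  expect_equal(unlist(d1[1, c("d_long_mm", "d_rad_mm", "theta_deg")],
                      use.names = FALSE), c(0, 0, 0))
  z <- make_disturbance(64, 3.2, drift_amp = 0, glitch_rate = 0,
                        glitch_amp = 0, seed = 7)
  expect_true(all(z$d_long_mm == 0) && all(z$theta_deg == 0))
  # Monte-Carlo glitch count over 50 seeds: mean approx rate x duration
  counts <- vapply(1:50, function(s) {
    length(attr(make_disturbance(16, 3.2, 0, 2.5, 0.2, seed = 1000 + s),
                "glitch_times"))
  }, numeric(1))
  lambda <- 2.5 * 3.2
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 50))
  expect_error(make_disturbance(10, 3.2, 0.1, 1, 0.1), "seed")
})

test_that("phantom amplitudes follow the template and the vessel layers", {
  ph <- make_phantom(0.8, NULL, 500, seed = 71, dim = c(40, 40))
  expect_true(all(abs(ph$amplitude - 0.8) < 1e-12))
  expect_true(all(ph$amplitude >= 0))
  tmpl <- cbind(matrix(0.2, 40, 20), matrix(0.9, 40, 20))
  ph2 <- make_phantom(tmpl, NULL, 4000, seed = 72)
  bright <- ph2$col_mm > 1.1
  dark <- ph2$col_mm < 0.9
  expect_gt(mean(ph2$amplitude[bright]), mean(ph2$amplitude[dark]))
  wm <- wall_model(1.0, 0.4)
  ph3 <- make_phantom(matrix(1, 40, 40), wm, 4000, seed = 73)
  lum <- abs(ph3$row_mm - 1.0) < 0.35
  expect_true(all(ph3$amplitude[lum] <= wm$multipliers[1] * 1 + 1e-12))
  expect_error(make_phantom(matrix(numeric(0), 0, 0), NULL, 10, seed = 1),
               "empty")
})

test_that("rendering: Rayleigh speckle statistics and log-compression", {
  rc <- render_config(160, 192)
  ph <- make_phantom(0.8, NULL, 28000, seed = 74, dim = c(160, 192))
  fr <- render_bmode(ph, rc)
  env <- attr(fr, "envelope")
  sub <- env[20:140, 20:170]
  expect_lt(abs(mean(sub) / stats::sd(sub) - 1.913), 0.15)
  expect_true(all(fr >= 0 & fr <= 255))
  # zero amplitudes give a uniform minimum frame
  ph0 <- ph
  ph0$amplitude <- ph0$amplitude * 0
  expect_true(all(render_bmode(ph0, rc) == 0))
  # doubling amplitudes shifts unclipped log-compressed values by a constant
  ph2 <- ph
  ph2$amplitude <- 2 * ph$amplitude
  f1 <- render_bmode(ph, rc, ref_level = 1, quantize = FALSE)
  f2 <- render_bmode(ph2, rc, ref_level = 1, quantize = FALSE)
  sel <- f1 > 0 & f1 < 255 & f2 > 0 & f2 < 255
  d <- (f2 - f1)[sel]
  expect_lt(diff(range(d)), 1e-9)
  expect_equal(d[1], 255 * 20 * log10(2) / rc$dynamic_range_db,
               tolerance = 1e-9)
})

test_that("simulate_sequence: pass-through truth, timing, determinism", {
  n <- 6L
  rc <- render_config(96, 96)
  wm <- wall_model(2.4, 0.5)
  tmpl <- make_tissue_template(96, 96, 75)
  ph <- make_phantom(tmpl, wm, 6000, seed = 76)
  traj <- make_wall_trajectory(n, 3.2, 2, 0.2, 0.2)
  dist <- make_disturbance(n, 3.2, 0.2, 1, 0.1, seed = 77)
  sim <- simulate_sequence(traj, dist, ph, wm, rc, seed = 78)
  expect_identical(sim$motion, traj)
  expect_identical(sim$disturbance, dist)
  expect_equal(sim$sequence$frame_interval_s, 3.2 / n)
  sim2 <- simulate_sequence(traj, dist, ph, wm, rc, seed = 78)
  expect_identical(sim$sequence$frames, sim2$sequence$frames)
  expect_error(simulate_sequence(traj[1:4, ], dist, ph, wm, rc, seed = 1),
               "equal frame counts")
  # 200 frames over 3.2 s gives the familiar 0.016 s frame interval
  expect_equal(make_wall_trajectory(200, 3.2)$time_s[2], 0.016)
})

test_that("static scene stays statistically stationary across frames", {
  n <- 4L
  rc <- render_config(96, 96)
  tmpl <- make_tissue_template(96, 96, 79)
  ph <- make_phantom(tmpl, NULL, 14000, seed = 80)
  wm <- wall_model(2.4, 0.5)
  traj <- make_wall_trajectory(n, 1.0, 1, 0, 0)
  sim <- simulate_sequence(traj, zero_disturbance(n, 1.0), ph, wm, rc,
                           seed = 81, elev_jitter_sd_mm = 0.15)
  f1 <- sim$sequence$frames[[1]]
  f4 <- sim$sequence$frames[[4]]
  # speckle jitter decorrelates texture but the scene must not move or
  # change in distribution
  expect_lt(mean(abs(f4 - f1)), 20)
  ks <- suppressWarnings(stats::ks.test(as.vector(f1[10:86, 10:86]),
                                        as.vector(f4[10:86, 10:86])))
  expect_gt(ks$p.value, 0.01)
  m <- ncc_shift_map(f1, f4, 6, 6)
  pk <- ncc_argmax(m)
  expect_equal(c(pk$d_row, pk$d_col), c(0, 0))
})

test_that("a pure disturbance shift shows up at the preset lag", {
  n <- 2L
  rc <- render_config(96, 96)
  tmpl <- make_tissue_template(96, 96, 82)
  ph <- make_phantom(tmpl, NULL, 14000, seed = 83)
  wm <- wall_model(2.4, 0.5)
  traj <- make_wall_trajectory(n, 1.0, 1, 0, 0)
  dist <- zero_disturbance(n, 1.0)
  dist$d_long_mm[2] <- 0.5  # 10 px at 0.05 mm/px
  sim <- simulate_sequence(traj, dist, ph, wm, rc, seed = 84,
                           elev_jitter_sd_mm = 0)
  m <- ncc_shift_map(sim$sequence$frames[[1]], sim$sequence$frames[[2]],
                     14, 14)
  pk <- ncc_argmax(m)
  expect_equal(c(pk$d_row, pk$d_col), c(0, 10))
})
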