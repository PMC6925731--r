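test_that("rigid transform algebra: inverse and composition", {
  a <- rigid_transform(3.2, -1.5, 2)
  b <- rigid_transform(-0.7, 2.1, -1)
  ia <- invert_rigid(a)
  ab <- compose_rigid(a, ia)
  expect_equal(c(ab$d_col, ab$d_row, ab$theta_deg), c(0, 0, 0),
               tolerance = 1e-12)
  # composition applied to an image equals sequential warps
  img <- speckle_fixture(64, 96, seed = 61)
  w2 <- warp_rigid(warp_rigid(img, a, fill = NA), b, fill = NA)
  w1 <- warp_rigid(img, compose_rigid(a, b), fill = NA)
  ok <- is.finite(w1) & is.finite(w2)
  ok[c(1:6, 59:64), ] <- FALSE
  ok[, c(1:6, 91:96)] <- FALSE
  # two bilinear passes smooth fine speckle more than one composed pass,
  # so agreement is statistical, not pointwise
  expect_lt(mean(abs(w1[ok] - w2[ok])), 6)
  expect_gt(stats::cor(w1[ok], w2[ok]), 0.99)
})

test_that("warp_rigid round-trips integer translations losslessly", {
  img <- speckle_fixture(48, 64, seed = 62)
  tf <- rigid_transform(7, -4, 0)
  back <- warp_rigid(warp_rigid(img, tf, fill = NA), invert_rigid(tf),
                     fill = NA)
  ok <- is.finite(back)
  expect_equal(back[ok], img[ok], tolerance = 1e-12)
})

test_that("extract_subimages slices the expected bands", {
  fr <- matrix(seq_len(100 * 10), 100, 10)
  sub <- extract_subimages(fr, subimage_spec(0.30, 0.30))
  expect_identical(sub$upper, fr[1:30, ])
  expect_identical(sub$lower, fr[71:100, ])
  expect_error(extract_subimages(fr, subimage_spec(0.30, 0.30,
                                                   wall_rows = c(25, 75))),
               "overlap")
  again <- extract_subimages(rbind(sub$upper, sub$lower),
                             subimage_spec(0.5, 0.5))
  expect_identical(again$upper, sub$upper)
  expect_identical(again$lower, sub$lower)
})

test_that("register_rigid: identity, exact integer shifts, small rotations", {
  band <- speckle_fixture(48, 160, seed = 63)
  bounds <- register_bounds(12L, 2, 0.5)
  idem <- register_rigid(band, band, bounds)
  expect_equal(c(idem$transform$d_col, idem$transform$d_row,
                 idem$transform$theta_deg), c(0, 0, 0))
  expect_equal(idem$score, 1)
  flt <- warp_rigid(band, rigid_transform(-4, 7, 0), fill = NA)
  r1 <- register_rigid(band, flt, bounds)
  expect_identical(c(r1$transform$d_col, r1$transform$d_row,
                     r1$transform$theta_deg), c(-4, 7, 0))
  flt2 <- warp_rigid(band, rigid_transform(0, 0, 1.5), fill = NA)
  r2 <- register_rigid(band, flt2, bounds)
  expect_lt(abs(r2$transform$theta_deg - 1.5), 0.25)
  expect_lt(abs(r2$transform$d_col), 0.5)
  expect_lt(abs(r2$transform$d_row), 0.5)
  expect_error(register_rigid(matrix(1, 48, 160), band, bounds),
               "degenerate")
})

test_that("registration is equivariant under composed transforms", {
  band <- speckle_fixture(48, 160, seed = 64)
  bounds <- register_bounds(10L, 2, 0.5)
  t0 <- rigid_transform(2.5, -1.2, 0.8)
  t1 <- rigid_transform(-1.4, 0.9, -0.6)
  f0 <- warp_rigid(band, t0, fill = NA)
  f1 <- warp_rigid(band, t1, fill = NA)
  r0 <- register_rigid(band, f0, bounds)$transform
  expect_lt(abs(r0$d_col - t0$d_col), 0.2)
  expect_lt(abs(r0$d_row - t0$d_row), 0.2)
  expect_lt(abs(r0$theta_deg - t0$theta_deg), 0.1)
  # registering warp(T0) onto warp(T1) recovers T0 o T1^-1
  r01 <- register_rigid(f1, f0, bounds)$transform
  expected <- compose_rigid(t0, invert_rigid(t1))
  expect_lt(abs(r01$d_col - expected$d_col), 0.35)
  expect_lt(abs(r01$d_row - expected$d_row), 0.35)
  expect_lt(abs(r01$theta_deg - expected$theta_deg), 0.15)
})

test_that("estimate_disturbance averages the upper and lower transforms", {
  # frame 2 carries a different known shift in each band; the average of
  # the two is the reported common-mode estimate
  fr <- speckle_fixture(120, 160, seed = 65)
  spec <- subimage_spec(0.25, 0.25)
  f2 <- fr
  f2[1:30, ] <- warp_rigid(fr[1:30, ], rigid_transform(2, 0, 0), fill = 0)
  f2[91:120, ] <- warp_rigid(fr[91:120, ], rigid_transform(4, 0, 0), fill = 0)
  seq <- image_sequence(list(fr, f2), 0.05, 0.1)
  est <- estimate_disturbance(seq, "BM", spec, register_bounds(8L, 1, 0.5))
  expect_equal(est$d_long_px_up[2], 2)
  expect_equal(est$d_long_px_lo[2], 4)
  expect_equal(est$d_long_px[2], 3)
  expect_equal(est$theta_deg[2], 0)
  expect_equal(est$d_long_px[1], 0)  # frame 1 is the identity reference
})

test_that("align_sequence inverts the estimated transforms", {
  fr <- speckle_fixture(96, 128, seed = 66)
  tf <- rigid_transform(3.3, -2.1, 0.7)
  moved <- warp_rigid(fr, tf, fill = 0)
  seq <- image_sequence(list(fr, moved), 0.05, 0.1)
  dist <- data.frame(frame = 1:2, d_long_px = c(0, tf$d_col),
                     d_rad_px = c(0, tf$d_row),
                     theta_deg = c(0, tf$theta_deg))
  aligned <- align_sequence(seq, dist)
  expect_identical(aligned$frames[[1]], fr)
  err <- abs(aligned$frames[[2]][20:76, 30:106] - fr[20:76, 30:106])
  expect_lt(mean(err), 6)  # double bilinear resampling of fine speckle
  expect_gt(stats::cor(as.vector(aligned$frames[[2]][20:76, 30:106]),
                       as.vector(fr[20:76, 30:106])), 0.97)
  # integer translation round-trip is exact in the interior
  tfi <- rigid_transform(5, -3, 0)
  seqi <- image_sequence(list(fr, warp_rigid(fr, tfi, fill = 0)), 0.05, 0.1)
  disti <- data.frame(frame = 1:2, d_long_px = c(0, 5), d_rad_px = c(0, -3),
                      theta_deg = c(0, 0))
  ai <- align_sequence(seqi, disti)
  expect_equal(ai$frames[[2]][10:80, 10:120], fr[10:80, 10:120],
               tolerance = 1e-12)
})

test_that("disturbance_to_mm converts pixel estimates to physical units", {
  est <- data.frame(frame = 1:2, d_long_px = c(0, 4), d_rad_px = c(0, -2),
                    theta_deg = c(0, 0.5))
  mm <- disturbance_to_mm(est, 0.05, times = c(0, 0.1))
  expect_equal(mm$d_long_mm, c(0, 0.2))
  expect_equal(mm$d_rad_mm, c(0, -0.1))
  expect_equal(mm$theta_deg, c(0, 0.5))
})
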