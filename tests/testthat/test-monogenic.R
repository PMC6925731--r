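test_that("DoG bandpass has zero DC gain and the predicted passband peak", {
  cfg <- monogenic_config(sigma1 = 10)
  C <- matrix(5, 96, 96)
  expect_lt(max(abs(dog_bandpass(C, cfg))), 1e-10)
  # grating response peaks where the analytic transfer function peaks
  n <- 192
  cfg2 <- monogenic_config(sigma1 = 10)
  ks <- 1:12
  resp <- vapply(ks, function(k) {
    g <- outer(rep(1, 96), cos(2 * pi * k * (1:n) / n))
    max(abs(dog_bandpass(g, cfg2)))
  }, numeric(1))
  transfer <- function(f) {
    exp(-2 * pi^2 * cfg2$sigma1^2 * f^2) - exp(-2 * pi^2 * cfg2$sigma2^2 * f^2)
  }
  f_star <- stats::optimize(transfer, c(1e-4, 0.2), maximum = TRUE)$maximum
  expect_equal(ks[which.max(resp)], ks[which.min(abs(ks / n - f_star))])
  expect_error(dog_bandpass(C, monogenic_config(sigma1 = 30)), "too small")
  expect_error(monogenic_config(sigma1 = 5, sigma2 = 4), "sigma")
})

test_that("Riesz multipliers have unit magnitude off DC and zero at DC", {
  n <- 33  # odd: every nonzero frequency has a conjugate partner
  imp <- matrix(0, n, n)
  imp[1, 1] <- 1
  r <- riesz(imp)
  Hu <- fft(r$rx)
  Hv <- fft(r$ry)
  mag <- sqrt(Mod(Hu)^2 + Mod(Hv)^2)
  expect_lt(abs(mag[1, 1]), 1e-12)
  expect_lt(max(abs(mag[-1] - 1)), 1e-10)
  # even sizes: the partnerless Nyquist bins are zeroed, all else unit
  m <- 32
  imp2 <- matrix(0, m, m)
  imp2[1, 1] <- 1
  r2 <- riesz(imp2)
  mag2 <- sqrt(Mod(fft(r2$rx))^2 + Mod(fft(r2$ry))^2)
  keep <- setdiff(seq_len(m), m / 2 + 1)
  sub <- mag2[keep, keep]
  expect_lt(max(abs(sub[-1] - 1)), 1e-10)  # all except DC
  expect_lt(max(mag2[m / 2 + 1, ]), 1e-12)
})

test_that("Riesz of plane gratings matches the closed form exactly", {
  n <- 64
  xs <- outer(rep(1, n), 0:(n - 1))
  ys <- outer(0:(n - 1), rep(1, n))
  for (kk in list(c(3, 0), c(0, 5), c(4, 7), c(-5, 2))) {
    u <- kk[1] / n
    v <- kk[2] / n
    f <- cos(2 * pi * (u * xs + v * ys))
    r <- riesz(f)
    s <- sin(2 * pi * (u * xs + v * ys))
    nrm <- sqrt(u^2 + v^2)
    expect_equal(r$rx, (u / nrm) * s, tolerance = 1e-10)
    expect_equal(r$ry, (v / nrm) * s, tolerance = 1e-10)
  }
  # horizontal cosine: no row-axis component at all
  g <- outer(rep(1, n), cos(2 * pi * 4 * (0:(n - 1)) / n))
  expect_lt(max(abs(riesz(g)$ry)), 1e-10)
})

test_that("Riesz agrees with spatial convolution by the x/2pi r^3 kernels", {
  # the sampled continuous kernel is only a moderate-accuracy discretization
  # of the exact frequency-domain operator (the 1/r^2 singularity aliases),
  # so agreement is asserted at that honest level on a bandlimited blob
  n <- 64
  xg <- outer(rep(1, n), (1:n) - 33)
  yg <- outer((1:n) - 33, rep(1, n))
  blob <- exp(-(xg^2 + yg^2) / (2 * 4^2))
  r <- riesz(blob)
  P <- 256
  xo <- outer(rep(1, P), c(0:(P / 2 - 1), -(P / 2):-1))
  yo <- outer(c(0:(P / 2 - 1), -(P / 2):-1), rep(1, P))
  rad2 <- xo^2 + yo^2
  kx <- ifelse(rad2 == 0, 0, xo / (2 * pi * rad2^1.5))
  ky <- ifelse(rad2 == 0, 0, yo / (2 * pi * rad2^1.5))
  bp <- matrix(0, P, P)
  bp[1:n, 1:n] <- blob
  sx <- Re(fft(fft(bp) * fft(kx), inverse = TRUE) / P^2)[1:n, 1:n]
  sy <- Re(fft(fft(bp) * fft(ky), inverse = TRUE) / P^2)[1:n, 1:n]
  int <- 9:56
  expect_lt(max(abs(r$rx - sx)[int, int]), 0.05)
  expect_lt(max(abs(r$ry - sy)[int, int]), 0.05)
  expect_gt(stats::cor(as.vector(r$rx[int, int]), as.vector(sx[int, int])),
            0.995)
})

test_that("local phase/orientation follow the two-argument arctangent", {
  f <- matrix(2, 3, 3)
  z <- matrix(0, 3, 3)
  lv <- local_features(f, z, z)
  expect_equal(lv$phi, matrix(0, 3, 3))
  lv2 <- local_features(z, matrix(1, 3, 3), z)
  expect_equal(lv2$phi, matrix(pi / 2, 3, 3))
  set.seed(41)
  f <- matrix(rnorm(36), 6, 6)
  rx <- matrix(rnorm(36), 6, 6)
  ry <- matrix(rnorm(36), 6, 6)
  a <- local_features(f, rx, ry)
  b <- local_features(2 * f, 2 * rx, 2 * ry)
  expect_equal(a$phi, b$phi, tolerance = 1e-12)
  expect_equal(a$theta, b$theta, tolerance = 1e-12)
  # energy split and range invariants
  expect_equal(a$A^2, f^2 + rx^2 + ry^2, tolerance = 1e-12)
  expect_true(all(a$phi >= 0 & a$phi <= pi))
  expect_true(all(a$theta >= 0 & a$theta <= pi))
  expect_equal(a$confidence, sin(a$phi)^2, tolerance = 1e-12)
})

test_that("degenerate near-zero-amplitude pixels get zero confidence", {
  f <- matrix(1, 4, 4)
  rx <- matrix(0, 4, 4)
  f[2, 2] <- 1e-15
  lv <- local_features(f, rx, rx)
  expect_equal(lv$confidence[2, 2], 0)
  expect_equal(lv$phi[2, 2], pi / 2)
  expect_equal(lv$theta[2, 2], 0)
})

test_that("confidence combination is sin^2(phi) * theta", {
  mk <- function(phi, theta) {
    structure(list(phi = matrix(phi, 2, 2), theta = matrix(theta, 2, 2),
                   confidence = matrix(sin(phi)^2, 2, 2)),
              class = "local_vector_image")
  }
  expect_equal(combine_features(mk(pi / 2, 0.7)), matrix(0.7, 2, 2))
  expect_equal(combine_features(mk(0, 0.7)), matrix(0, 2, 2),
               tolerance = 1e-12)
  expect_equal(combine_features(mk(pi / 4, pi / 3)), matrix(pi / 6, 2, 2),
               tolerance = 1e-12)
  emb <- combine_features(mk(pi / 2, pi / 6), mode = "embedding")
  expect_equal(emb$c1, matrix(cos(pi / 3), 2, 2), tolerance = 1e-12)
  expect_equal(emb$c2, matrix(sin(pi / 3), 2, 2), tolerance = 1e-12)
})

test_that("feature images are invariant to affine intensity changes", {
  I <- speckle_fixture(96, 96, seed = 43)
  cfg <- monogenic_config(sigma1 = 4)
  expect_identical(make_feature_image(I, cfg, "intensity"), I)
  for (mode in c("phase", "orientation", "combined")) {
    a <- make_feature_image(I, cfg, mode)
    b <- make_feature_image(0.7 * I + 20, cfg, mode)
    expect_lt(max(abs(a - b)), 1e-9)
  }
  expect_error(make_feature_image(I, cfg, "nonsense"))
})

test_that("orientation histogram mode recovers the grating angle", {
  n <- 96
  cfg <- monogenic_config(sigma1 = 4)
  xs <- outer(rep(1, n), 1:n)
  ys <- outer(1:n, rep(1, n))
  breaks <- seq(0, 180, by = 6)
  for (alpha in c(0, 30, 60, 90, 120)) {
    a <- alpha * pi / 180
    g <- 128 + 100 * cos(2 * pi * (cos(a) * xs + sin(a) * ys) / 18)
    th <- make_feature_image(g, cfg, "orientation")
    ph <- make_feature_image(g, cfg, "phase")
    conf <- sin(ph)^2
    sel <- conf > 0.5
    h <- hist(th[sel] * 180 / pi, breaks = breaks, plot = FALSE)
    mode_angle <- h$mids[which.max(h$counts)]
    dist <- min(abs(mode_angle - alpha), 180 - abs(mode_angle - alpha))
    expect_lte(dist, 6)
  }
})
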