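# Independent naive implementations of the printed formulas (per-pixel
# double loops, closed forms), used as oracles against the vectorized /
# FFT-based implementations, plus small fixture builders.

naive_icov <- function(I, h = 1, w = 1) {
  eps <- 1e-6 * max(I)
  I[I <= 0] <- eps
  m <- nrow(I); n <- ncol(I)
  q <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    dN <- (I[max(i - 1, 1), j] - I[i, j]) / h
    dS <- (I[min(i + 1, m), j] - I[i, j]) / h
    dW <- (I[i, max(j - 1, 1)] - I[i, j]) / h
    dE <- (I[i, min(j + 1, n)] - I[i, j]) / h
    if (w == 1) {
      G2 <- (dN^2 + dS^2 + dW^2 + dE^2) / I[i, j]^2
      L <- (dN + dS + dW + dE) / I[i, j]
    } else {
      G2 <- (dN^2 + dS^2 + 4 * dW^2 + 4 * dE^2) / I[i, j]^2
      L <- (dN + dS + 2 * dW + 2 * dE) / I[i, j]
    }
    q2 <- (0.5 * G2 - (1 / 16) * L^2) / (1 + 0.25 * L)^2
    q[i, j] <- sqrt(max(q2, 0))
  }
  q
}

naive_diffusion_coeff <- function(q, q0) {
  cc <- 1 / (1 + (q^2 - q0^2) / (q0^2 * (1 + q0^2)))
  pmin(pmax(cc, 0), 1)
}

naive_srad_step <- function(I, q0, dt, h = 1, w = 1) {
  eps <- 1e-6 * max(I)
  I[I <= 0] <- eps
  m <- nrow(I); n <- ncol(I)
  cc <- naive_diffusion_coeff(naive_icov(I, h, w), q0)
  out <- I
  for (i in 1:m) for (j in 1:n) {
    dN <- (I[max(i - 1, 1), j] - I[i, j]) / h
    dS <- (I[min(i + 1, m), j] - I[i, j]) / h
    dW <- (I[i, max(j - 1, 1)] - I[i, j]) / h
    dE <- (I[i, min(j + 1, n)] - I[i, j]) / h
    div <- (cc[min(i + 1, m), j] * dS + cc[i, j] * dN +
              cc[i, min(j + 1, n)] * dE + cc[i, j] * dW) / h
    out[i, j] <- I[i, j] + (dt / 4) * div
  }
  out
}

naive_ncc <- function(R, F) {
  M <- nrow(R); N <- ncol(R)
  rb <- mean(R); fb <- mean(F)
  num <- 0; dr <- 0; df <- 0
  for (m in 1:M) for (n in 1:N) {
    num <- num + (R[m, n] - rb) * (F[m, n] - fb)
    dr <- dr + (R[m, n] - rb)^2
    df <- df + (F[m, n] - fb)^2
  }
  num / sqrt(dr * df)
}

# overlap-only NCC at a single integer shift, by explicit submatrix slicing
naive_shift_ncc <- function(ref, flt, dr, dc) {
  m <- nrow(ref); n <- ncol(ref)
  r1 <- max(1, 1 + dr); r2 <- min(m, m + dr)
  c1 <- max(1, 1 + dc); c2 <- min(n, n + dc)
  if (r1 > r2 || c1 > c2) return(NA_real_)
  a <- ref[(r1:r2) - dr, (c1:c2) - dc, drop = FALSE]
  b <- flt[r1:r2, c1:c2, drop = FALSE]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 16) return(NA_real_)
  av <- a[ok] - mean(a[ok]); bv <- b[ok] - mean(b[ok])
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(NA_real_)
  sum(av * bv) / den
}

naive_regression <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  list(slope = slope, intercept = intercept, r = r)
}

naive_nrmse <- function(est, ref) {
  sqrt(sum((est - ref)^2) / length(ref)) / (max(ref) - min(ref))
}

naive_bland_altman <- function(a, b) {
  d <- a - b
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  list(mean_diff = m, sd_diff = s, lower = m - 1.96 * s, upper = m + 1.96 * s)
}

# small rendered speckle image with tissue-like texture (no vessel)
speckle_fixture <- function(nr = 96, nc = 128, seed = 42) {
  rc <- render_config(nr, nc)
  tmpl <- make_tissue_template(nr, nc, seed)
  ph <- make_phantom(tmpl, NULL, round(nr * nc * 1.5), seed + 1)
  fr <- render_bmode(ph, rc)
  attr(fr, "envelope") <- NULL
  fr
}

# count strict local maxima above a fraction of the series peak
count_peaks <- function(x, min_frac = 0.5) {
  n <- length(x)
  thr <- min_frac * max(x)
  sum(vapply(2:(n - 1), function(i) {
    x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] > thr
  }, logical(1)))
}
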