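# Small spectral and interpolation helpers shared by the simulator, the
# monogenic features and the registration/matching code. Images are plain
# numeric matrices; rows index depth (radial axis), columns index the vessel
# (longitudinal) axis.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @noRd
next_fast_size <- function(n) stats::nextn(n, factors = c(2L, 3L, 5L))

#' Circular 2D convolution with a centred kernel
#'
#' The kernel (odd sizes recommended) is wrapped so that its centre element
#' multiplies the pixel itself; boundaries are periodic. Used for the
#' point-spread-function rendering and the DoG bandpass, where the kernel is
#' much smaller than the image.
#' @noRd
conv2_circular <- function(img, kernel) {
  d <- dim(img)
  kd <- dim(kernel)
  if (any(kd > d)) {
    stop("kernel does not fit inside the image (", kd[1], "x", kd[2],
         " vs ", d[1], "x", d[2], ")")
  }
  kp <- matrix(0, d[1], d[2])
  kp[seq_len(kd[1]), seq_len(kd[2])] <- kernel
  cr <- (kd[1] + 1L) %/% 2L
  cc <- (kd[2] + 1L) %/% 2L
  # circularly shift so the kernel centre sits at index (1, 1)
  ridx <- c(cr:d[1], seq_len(cr - 1L))
  cidx <- c(cc:d[2], seq_len(cc - 1L))
  out <- ifft2(fft2(img) * fft2(kp[ridx, cidx, drop = FALSE]))
  if (is.complex(img) || is.complex(kernel)) out else Re(out)
}

#' Bilinear sampling of a matrix at continuous (row, col) positions
#'
#' Positions use the usual R convention: integer coordinates hit pixel
#' centres, `img[1, 1]` is at (1, 1). Out-of-support positions return `fill`
#' (which may be `NA` so callers can mask invalid pixels).
#' @noRd
bilinear_sample <- function(img, row, col, fill = NA_real_) {
  nr <- nrow(img)
  nc <- ncol(img)
  r0 <- floor(row)
  c0 <- floor(col)
  fr <- row - r0
  fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # exact edge: allow positions on the last row/col with zero fraction
  edge_r <- r0 == nr & fr == 0 & c0 >= 1 & c0 + 1 <= nc
  edge_c <- c0 == nc & fc == 0 & r0 >= 1 & r0 + 1 <= nr
  corner <- r0 == nr & fr == 0 & c0 == nc & fc == 0
  out <- rep(fill, length(row))
  idx <- function(r, c) (c - 1L) * nr + r
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    out[ok] <- img[idx(r0k, c0k)] * (1 - frk) * (1 - fck) +
      img[idx(r0k + 1L, c0k)] * frk * (1 - fck) +
      img[idx(r0k, c0k + 1L)] * (1 - frk) * fck +
      img[idx(r0k + 1L, c0k + 1L)] * frk * fck
  }
  ew <- edge_r & !ok
  if (any(ew)) {
    out[ew] <- img[idx(r0[ew], c0[ew])] * (1 - fc[ew]) +
      img[idx(r0[ew], c0[ew] + 1L)] * fc[ew]
  }
  ec <- edge_c & !ok & !edge_r
  if (any(ec)) {
    out[ec] <- img[idx(r0[ec], c0[ec])] * (1 - fr[ec]) +
      img[idx(r0[ec] + 1L, c0[ec])] * fr[ec]
  }
  cw <- corner & !ok
  if (any(cw)) out[cw] <- img[idx(r0[cw], c0[cw])]
  out
}

#' Discrete isotropic 2D Gaussian, normalised to unit sum
#' @noRd
gaussian_kernel2 <- function(sigma, radius = ceiling(3.5 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}
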