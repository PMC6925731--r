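# Monogenic-signal local features.
#
# A difference-of-Gaussians (DoG) bandpass isolates one scale band and
# removes the DC component; the Riesz transform (2D Hilbert transform) then
# yields the two quadrature components. From (f, h_x*f, h_y*f) we obtain the
# local amplitude A, the local phase phi in [0, pi] (structure type: edge vs
# ridge), the local orientation theta in [0, pi] (axial direction, modulo
# pi), and a confidence sin^2(phi) that suppresses the orientation artifacts
# appearing along ridge centrelines where the phase is near 0 or pi. The
# combined image C = sin^2(phi) * theta carries both the structural and the
# geometric information and is the registration feature of the full method.

#' Monogenic feature configuration
#'
#' @param sigma1 Standard deviation (px) of the narrow Gaussian.
#' @param sigma2 Standard deviation of the wide Gaussian; default
#'   `sqrt(2) * sigma1`.
#' @param combine One of `"product"` (C = sin^2(phi) * theta, default) or
#'   `"embedding"` (two planes sin^2(phi) cos(2 theta), sin^2(phi)
#'   sin(2 theta)).
#' @return Object of class `monogenic_config`.
#' @export
monogenic_config <- function(sigma1 = 10, sigma2 = sqrt(2) * sigma1,
                             combine = c("product", "embedding")) {
  if (!(sigma1 > 0 && sigma2 > sigma1)) stop("need 0 < sigma1 < sigma2")
  structure(list(sigma1 = sigma1, sigma2 = sigma2,
                 combine = match.arg(combine)),
            class = "monogenic_config")
}

#' Difference-of-Gaussians bandpass filter
#'
#' Convolves with `G_sigma1 - G_sigma2` (2D isotropic, each discrete kernel
#' normalized to unit sum, so the DoG kernel has exactly zero DC gain).
#'
#' @param I Image matrix, larger than about `6 * sigma2` per dimension.
#' @param config A [monogenic_config()].
#' @return Zero-mean bandpassed image `f`.
#' @export
dog_bandpass <- function(I, config) {
  stopifnot(inherits(config, "monogenic_config"))
  if (min(dim(I)) < 6 * config$sigma2) {
    stop("image too small for sigma2 = ", signif(config$sigma2, 4),
         " (needs ~6 sigma2 = ", ceiling(6 * config$sigma2), " px)")
  }
  radius <- ceiling(3.5 * config$sigma2)
  # keep the kernel inside the image so circular convolution stays valid
  radius <- min(radius, (min(dim(I)) - 1L) %/% 2L)
  k1 <- gaussian_kernel2(config$sigma1, radius)
  k2 <- gaussian_kernel2(config$sigma2, radius)
  conv2_circular(I, k1 - k2)
}

#' Riesz transform
#'
#' Frequency-domain multiplication by `(-i u / |w|, -i v / |w|)` with the
#' undefined zero-frequency multiplier set to 0; `u` is the frequency along
#' columns (longitudinal axis), `v` along rows.
#'
#' @param f Real-valued (bandpassed) image.
#' @return List with matrices `rx` (column-axis component) and `ry`
#'   (row-axis component).
#' @export
riesz <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  v <- fft_freqs(nr)
  u <- fft_freqs(nc)
  V <- matrix(v, nr, nc)
  U <- matrix(u, nr, nc, byrow = TRUE)
  rho <- sqrt(U^2 + V^2)
  rho[1, 1] <- 1  # avoid 0/0; multiplier at DC is defined as 0 below
  Hu <- complex(real = 0, imaginary = -1) * U / rho
  Hv <- complex(real = 0, imaginary = -1) * V / rho
  Hu[1, 1] <- 0
  Hv[1, 1] <- 0
  # Nyquist rows/cols of even-sized grids have no conjugate partner, so an
  # imaginary multiplier there cannot produce a real output; zero them (the
  # bandpassed input carries no energy there anyway)
  if (nr %% 2 == 0) {
    Hu[nr / 2 + 1, ] <- 0
    Hv[nr / 2 + 1, ] <- 0
  }
  if (nc %% 2 == 0) {
    Hu[, nc / 2 + 1] <- 0
    Hv[, nc / 2 + 1] <- 0
  }
  Fw <- fft2(f)
  list(rx = Re(ifft2(Fw * Hu)), ry = Re(ifft2(Fw * Hv)))
}

fft_freqs <- function(n) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
  k / n
}

#' Local amplitude, phase, orientation and confidence
#'
#' @param f Bandpassed image.
#' @param rx,ry Riesz components from [riesz()].
#' @param eps_frac Pixels with amplitude below `eps_frac * max(A)` are
#'   degenerate: they get phase pi/2, orientation 0 and confidence 0.
#' @return Object of class `local_vector_image` with matrices `f`, `rx`,
#'   `ry`, `A`, `phi`, `theta`, `confidence`.
#' @export
local_features <- function(f, rx, ry, eps_frac = 1e-9) {
  stopifnot(identical(dim(f), dim(rx)), identical(dim(f), dim(ry)))
  A <- sqrt(f^2 + rx^2 + ry^2)
  rmag <- sqrt(rx^2 + ry^2)
  phi <- atan2(rmag, f)                 # in [0, pi] since rmag >= 0
  theta <- atan(ifelse(rx == 0, ifelse(ry == 0, 0, Inf), ry / rx))
  theta[theta < 0] <- theta[theta < 0] + pi
  conf <- sin(phi)^2
  deg <- A < eps_frac * max(A)
  phi[deg] <- pi / 2
  theta[deg] <- 0
  conf[deg] <- 0
  structure(list(f = f, rx = rx, ry = ry, A = A, phi = phi, theta = theta,
                 confidence = conf),
            class = "local_vector_image")
}

#' Confidence-weighted combination of phase and orientation
#'
#' Default: the single-plane product `C = sin^2(phi) * theta`. The
#' `"embedding"` mode returns the two-plane axial embedding
#' `(sin^2(phi) cos(2 theta), sin^2(phi) sin(2 theta))`.
#'
#' @param lvi A [local_features()] result.
#' @param mode `"product"` or `"embedding"`.
#' @return A matrix (product) or a list of two matrices (embedding).
#' @export
combine_features <- function(lvi, mode = c("product", "embedding")) {
  stopifnot(inherits(lvi, "local_vector_image"))
  mode <- match.arg(mode)
  if (mode == "product") {
    lvi$confidence * lvi$theta
  } else {
    list(c1 = lvi$confidence * cos(2 * lvi$theta),
         c2 = lvi$confidence * sin(2 * lvi$theta))
  }
}

# mirror (reflect) padding; pad must be < dim in each direction
pad_reflect <- function(I, pr, pc) {
  nr <- nrow(I); nc <- ncol(I)
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  I[ri, ci, drop = FALSE]
}

#' Feature image for registration
#'
#' The spectral operators (DoG, Riesz) are applied on a mirror-padded copy
#' of the image and the result is cropped back, so that the periodic FFT
#' boundary does not leak structure across the edges of narrow subimage
#' bands.
#'
#' @param I Image matrix.
#' @param config A [monogenic_config()].
#' @param mode One of `"intensity"`, `"phase"`, `"orientation"`,
#'   `"combined"`.
#' @return Feature matrix: the input itself (intensity), the phi plane,
#'   the theta plane, or the combined image C.
#' @export
make_feature_image <- function(I, config = monogenic_config(),
                               mode = c("intensity", "phase", "orientation",
                                        "combined")) {
  mode <- match.arg(mode)
  if (mode == "intensity") return(I)
  pr <- min(nrow(I) - 1L, ceiling(3.5 * config$sigma2) + 8L)
  pc <- min(ncol(I) - 1L, ceiling(3.5 * config$sigma2) + 8L)
  Ip <- pad_reflect(I, pr, pc)
  f <- dog_bandpass(Ip, config)
  r <- riesz(f)
  lvi <- local_features(f, r$rx, r$ry)
  out <- switch(mode,
                phase = lvi$phi,
                orientation = lvi$theta,
                combined = combine_features(lvi, config$combine))
  crop <- function(M) M[pr + seq_len(nrow(I)), pc + seq_len(ncol(I)),
                        drop = FALSE]
  if (is.list(out)) lapply(out, crop) else crop(out)
}
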