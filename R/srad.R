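# Speckle-reducing anisotropic diffusion (SRAD).
#
# The diffusivity is driven by the instantaneous coefficient of variation
# (ICOV) q, an edge detector for speckled images, relative to the speckle
# scale q0 measured in a homogeneous region. The explicit Jacobi scheme uses
# one-sided neighbour differences, reflective borders and an update constant
# dt/4. A longitudinally weighted variant (w = 2) doubles the column-axis
# first differences in the ICOV and the column-axis fluxes in the divergence,
# so that variation along the vessel axis registers more strongly and less
# smoothing is applied along it.

#' SRAD configuration
#'
#' @param time_step Dimensionless explicit time step (default 0.1).
#' @param n_iterations Number of diffusion iterations (default 100).
#' @param h Grid spacing in pixels (default 1).
#' @param region Homogeneous speckle region `c(row, col, height, width)`
#'   used to estimate the speckle scale q0 each iteration (default 20 x 20).
#' @param w Longitudinal weight: 1 = standard scheme, 2 = doubled
#'   longitudinal (column-axis) weighting.
#' @return Object of class `srad_config`.
#' @export
srad_config <- function(time_step = 0.1, n_iterations = 100L, h = 1,
                        region = c(1L, 1L, 20L, 20L), w = 1L) {
  stopifnot(time_step > 0, n_iterations >= 0, h > 0,
            length(region) == 4, region[3] >= 2, region[4] >= 2,
            w %in% c(1L, 2L))
  structure(list(time_step = time_step, n_iterations = as.integer(n_iterations),
                 h = h, region = as.integer(region), w = as.integer(w)),
            class = "srad_config")
}

# replicate-edge neighbour differences; at the border the difference is 0,
# which implements the reflective (zero normal derivative) boundary
srad_diffs <- function(I, h = 1) {
  m <- nrow(I); n <- ncol(I)
  list(dN = (I[c(1L, seq_len(m - 1L)), , drop = FALSE] - I) / h,
       dS = (I[c(seq_len(m - 1L) + 1L, m), , drop = FALSE] - I) / h,
       dW = (I[, c(1L, seq_len(n - 1L)), drop = FALSE] - I) / h,
       dE = (I[, c(seq_len(n - 1L) + 1L, n), drop = FALSE] - I) / h)
}

floor_positive <- function(I) {
  eps <- 1e-6 * max(I)
  if (eps <= 0) stop("image is nonpositive everywhere")
  I[I <= 0] <- eps
  I
}

#' Instantaneous coefficient of variation (ICOV)
#'
#' Edge detector for speckled images: high at edges, low in fully developed
#' speckle. Uses one-sided neighbour differences and the 4-neighbour
#' Laplacian; with `w = 2` the longitudinal (column) first differences are
#' doubled and the Laplacian takes coefficients 2,2,1,1 with centre -6.
#'
#' @param I Positive image matrix (zero/negative pixels are floored at
#'   `1e-6 * max(I)`).
#' @param h Grid spacing in px.
#' @param w Longitudinal weight, 1 or 2.
#' @return Matrix of q values (>= 0).
#' @export
icov <- function(I, h = 1, w = 1L) {
  stopifnot(w %in% c(1L, 2L))
  I <- floor_positive(I)
  d <- srad_diffs(I, h)
  if (w == 1L) {
    G2 <- (d$dN^2 + d$dS^2 + d$dW^2 + d$dE^2) / I^2
    L <- (d$dN + d$dS + d$dW + d$dE) / I
  } else {
    G2 <- (d$dN^2 + d$dS^2 + 4 * d$dW^2 + 4 * d$dE^2) / I^2
    L <- (d$dN + d$dS + 2 * d$dW + 2 * d$dE) / I
  }
  q2 <- (0.5 * G2 - (1 / 16) * L^2) / (1 + 0.25 * L)^2
  sqrt(pmax(q2, 0))
}

#' Speckle scale q0 from a homogeneous region
#'
#' Ratio of the population standard deviation to the mean of the intensities
#' inside the region: the ICOV level of fully developed speckle.
#'
#' @param I Image matrix.
#' @param region `c(row, col, height, width)`, at least 2 x 2.
#' @return Scalar q0 >= 0.
#' @export
speckle_scale <- function(I, region) {
  stopifnot(length(region) == 4, region[3] >= 2, region[4] >= 2)
  r <- region
  if (r[1] < 1 || r[2] < 1 || r[1] + r[3] - 1 > nrow(I) ||
      r[2] + r[4] - 1 > ncol(I)) {
    stop("region lies outside the image")
  }
  z <- I[r[1]:(r[1] + r[3] - 1), r[2]:(r[2] + r[4] - 1)]
  m <- mean(z)
  if (m == 0) stop("degenerate region: zero mean")
  v <- mean((z - m)^2)  # population variance
  sqrt(v) / m
}

#' SRAD diffusion coefficient
#'
#' `c(q) = 1 / (1 + (q^2 - q0^2) / (q0^2 (1 + q0^2)))`, clamped to `[0, 1]`
#' to keep the explicit scheme stable (the raw expression exceeds 1 where
#' q < q0).
#'
#' @param q ICOV values (matrix or vector).
#' @param q0 Speckle scale, > 0.
#' @return Values in `[0, 1]`, same shape as `q`.
#' @export
diffusion_coeff <- function(q, q0) {
  if (!is.numeric(q0) || length(q0) != 1 || q0 <= 0) stop("q0 must be > 0")
  cc <- 1 / (1 + (q^2 - q0^2) / (q0^2 * (1 + q0^2)))
  pmin(pmax(cc, 0), 1)
}

#' One explicit SRAD update step
#'
#' `I' = I + (dt/4) div(c grad I)` with the divergence discretized as
#' `(1/h^2) [cS (I_S - I) + c (I_N - I) + cE (I_E - I) + c (I_W - I)]`,
#' taking the south/east neighbour's diffusion coefficient for the forward
#' fluxes. Reflective borders: no flux crosses the image edge. The
#' longitudinal weight `w = 2` enters only through the ICOV edge detector:
#' longitudinal variation then registers more strongly in q, the diffusivity
#' drops there, and detail along the vessel axis is preserved (the flux
#' discretization itself is unchanged).
#'
#' @param I Positive image matrix.
#' @param q0 Speckle scale for this iteration.
#' @param config An [srad_config()].
#' @return Updated image matrix.
#' @export
srad_step <- function(I, q0, config) {
  I <- floor_positive(I)
  m <- nrow(I); n <- ncol(I)
  h <- config$h
  q <- icov(I, h, config$w)
  cc <- diffusion_coeff(q, q0)
  d <- srad_diffs(I, h)
  cS <- cc[c(seq_len(m - 1L) + 1L, m), , drop = FALSE]
  cE <- cc[, c(seq_len(n - 1L) + 1L, n), drop = FALSE]
  div <- (cS * d$dS + cc * d$dN + cE * d$dE + cc * d$dW) / h
  I + (config$time_step / 4) * div
}

#' SRAD filter
#'
#' Applies [srad_step()] `n_iterations` times, re-estimating the speckle
#' scale q0 from the homogeneous region before every step.
#'
#' @param I Image matrix (gray values; floored to be strictly positive).
#' @param config An [srad_config()]; `config$region` must lie inside `I`.
#' @return Filtered image matrix.
#' @export
srad_filter <- function(I, config) {
  stopifnot(inherits(config, "srad_config"))
  if (config$n_iterations == 0L) return(I)
  I <- floor_positive(I)
  for (it in seq_len(config$n_iterations)) {
    q0 <- speckle_scale(I, config$region)
    if (q0 == 0) break  # perfectly homogeneous: nothing left to smooth
    I <- srad_step(I, q0, config)
  }
  I
}

clip_region <- function(region, nr, nc) {
  region <- as.integer(round(region))
  r0 <- min(max(region[1], 1L), nr - region[3] + 1L)
  c0 <- min(max(region[2], 1L), nc - region[4] + 1L)
  clipped <- r0 != region[1] || c0 != region[2]
  list(region = c(r0, c0, region[3], region[4]), clipped = clipped)
}

# centroid (x = col, y = row) and principal-axis angle of the thresholded
# frame, used to follow the homogeneous region when offsets are unknown
frame_moments <- function(frame) {
  b <- frame > mean(frame)
  ys <- row(frame)[b]; xs <- col(frame)[b]
  cx <- mean(xs); cy <- mean(ys)
  mu20 <- mean((xs - cx)^2); mu02 <- mean((ys - cy)^2)
  mu11 <- mean((xs - cx) * (ys - cy))
  list(cx = cx, cy = cy, angle = 0.5 * atan2(2 * mu11, mu20 - mu02))
}

#' Propagate the homogeneous region through a sequence
#'
#' With known per-frame offsets (simulation), the frame-1 region is shifted
#' by the rounded offsets. In automatic mode the offset is estimated from the
#' centroid shift and the principal-axis angle change of each thresholded
#' frame relative to frame 1. Regions that would leave the image are clipped
#' with a warning.
#'
#' @param frames List of image matrices.
#' @param region_frame1 `c(row, col, height, width)` inside frame 1.
#' @param offsets `NULL` for automatic mode, otherwise a data frame with
#'   per-frame columns `d_row_px`, `d_col_px` (frame 1 must be zero).
#' @return List of per-frame regions `c(row, col, height, width)`.
#' @export
propagate_region <- function(frames, region_frame1, offsets = NULL) {
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  r1 <- as.integer(region_frame1)
  chk <- clip_region(r1, nr, nc)
  if (chk$clipped) stop("region_frame1 lies outside frame 1")
  nfr <- length(frames)
  if (!is.null(offsets)) {
    stopifnot(nrow(offsets) == nfr,
              all(c("d_row_px", "d_col_px") %in% names(offsets)))
    out <- vector("list", nfr)
    any_clip <- FALSE
    for (k in seq_len(nfr)) {
      reg <- c(r1[1] + round(offsets$d_row_px[k]),
               r1[2] + round(offsets$d_col_px[k]), r1[3], r1[4])
      ck <- clip_region(reg, nr, nc)
      any_clip <- any_clip || ck$clipped
      out[[k]] <- ck$region
    }
    if (any_clip) warning("some propagated regions were clipped to the image")
    return(out)
  }
  m1 <- frame_moments(frames[[1]])
  centre1 <- c(r1[2] + (r1[4] - 1) / 2, r1[1] + (r1[3] - 1) / 2)  # (x, y)
  out <- vector("list", nfr)
  any_clip <- FALSE
  for (k in seq_len(nfr)) {
    mk <- frame_moments(frames[[k]])
    dth <- mk$angle - m1$angle
    Rm <- matrix(c(cos(dth), sin(dth), -sin(dth), cos(dth)), 2L, 2L)
    ck_xy <- Rm %*% (centre1 - c(m1$cx, m1$cy)) + c(mk$cx, mk$cy)
    reg <- c(round(ck_xy[2] - (r1[3] - 1) / 2),
             round(ck_xy[1] - (r1[4] - 1) / 2), r1[3], r1[4])
    ck <- clip_region(reg, nr, nc)
    any_clip <- any_clip || ck$clipped
    out[[k]] <- ck$region
  }
  if (any_clip) warning("some propagated regions were clipped to the image")
  out
}
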