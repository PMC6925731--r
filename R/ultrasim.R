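# Synthetic B-mode sequence simulator.
#
# A persistent population of sub-resolution scatterers (positions in mm,
# echo amplitudes taken from a tissue template times vessel-layer
# multipliers) is rendered into B-mode frames by a convolutional speckle
# model: bilinear splatting onto the pixel grid, convolution with an axially
# oscillating complex point-spread function, envelope detection and log
# compression. Per frame, wall-band scatterers move with the preset wall
# trajectory (distension away from the lumen centre plus a longitudinal
# sliding component), then a global rigid disturbance (longitudinal shift,
# radial shift, rotation about the image centre) moves every scatterer.
# Partial speckle decorrelation between frames comes from a small
# elevational jitter of the scatterer positions combined with the Gaussian
# elevational sensitivity of the beam.

#' Two-interface pulsating vessel wall model
#'
#' The vessel runs horizontally (along columns); layer membership depends on
#' the radial (row) distance from the lumen centre line.
#'
#' @param center_row_mm Lumen centre depth (mm).
#' @param radius_mm Lumen radius at rest (mm), > 0.
#' @param thickness_mm Named layer thicknesses `c(intima, media,
#'   adventitia)` in mm, all > 0.
#' @param multipliers Echo multipliers `c(lumen, intima, media, adventitia,
#'   tissue)`.
#' @param couple_margin_mm Perivascular tissue beyond the adventitia that
#'   still moves rigidly with the wall (mm); keeps the tracking block on a
#'   coherently moving patch.
#' @param taper_mm Width of the cosine taper from full wall motion down to
#'   static tissue (mm).
#' @return Object of class `wall_model`.
#' @export
wall_model <- function(center_row_mm, radius_mm,
                       thickness_mm = c(intima = 0.15, media = 0.25,
                                        adventitia = 0.45),
                       multipliers = c(lumen = 0.05, intima = 1.6,
                                       media = 0.5, adventitia = 1.8,
                                       tissue = 1.0),
                       couple_margin_mm = 1.45, taper_mm = 0.3) {
  stopifnot(radius_mm > 0, all(thickness_mm > 0), length(thickness_mm) == 3,
            length(multipliers) == 5)
  structure(list(center_row_mm = center_row_mm, radius_mm = radius_mm,
                 thickness_mm = thickness_mm, multipliers = multipliers,
                 couple_margin_mm = couple_margin_mm, taper_mm = taper_mm),
            class = "wall_model")
}

# echo multiplier as a function of radial distance from the lumen centre
layer_multiplier <- function(wall, d_mm) {
  th <- wall$thickness_mm
  mu <- wall$multipliers
  r1 <- wall$radius_mm
  r2 <- r1 + th[1]
  r3 <- r2 + th[2]
  r4 <- r3 + th[3]
  out <- rep(mu[5], length(d_mm))
  out[d_mm < r4] <- mu[4]
  out[d_mm < r3] <- mu[3]
  out[d_mm < r2] <- mu[2]
  out[d_mm < r1] <- mu[1]
  out
}

# fraction of the wall motion carried at radial distance d from the centre:
# 1 across the wall layers plus a coupled margin, cosine-tapered to 0 in the
# far tissue, ramped from 0 inside the lumen
wall_motion_weight <- function(wall, d_mm) {
  r <- wall$radius_mm
  d1 <- r + sum(wall$thickness_mm) + wall$couple_margin_mm
  d2 <- d1 + wall$taper_mm
  a <- r - 0.5
  b <- r - 0.2
  w <- numeric(length(d_mm))
  ramp <- d_mm > a & d_mm < b
  w[ramp] <- 0.5 - 0.5 * cos(pi * (d_mm[ramp] - a) / (b - a))
  w[d_mm >= b & d_mm <= d1] <- 1
  tap <- d_mm > d1 & d_mm < d2
  w[tap] <- 0.5 + 0.5 * cos(pi * (d_mm[tap] - d1) / (d2 - d1))
  w
}

#' Preset pulsating wall trajectory
#'
#' Smooth periodic distension with `n_cardiac_cycles` pulses over
#' `duration_s` (one respiratory cycle); each pulse rises faster than it
#' falls and returns to baseline at the cycle end. Radial displacement is
#' outward from the lumen centre; longitudinal displacement is along the
#' vessel.
#'
#' @param n_frames Number of frames (>= 2).
#' @param duration_s Sequence duration (s), > 0.
#' @param n_cardiac_cycles Cardiac cycles per sequence (>= 1).
#' @param amp_rad_mm,amp_long_mm Peak displacements (mm), >= 0.
#' @return Data frame `frame`, `time_s`, `d_long_mm`, `d_rad_mm`
#'   (frame 1 is (0, 0)).
#' @export
make_wall_trajectory <- function(n_frames, duration_s, n_cardiac_cycles = 4L,
                                 amp_rad_mm = 0.25, amp_long_mm = 0.35) {
  stopifnot(n_frames >= 2, n_cardiac_cycles >= 1)
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (amp_rad_mm < 0 || amp_long_mm < 0) stop("amplitudes must be >= 0")
  t <- (seq_len(n_frames) - 1) * duration_s / n_frames
  tc <- duration_s / n_cardiac_cycles
  s <- (t %% tc) / tc
  d_rad <- amp_rad_mm * sin(pi * s^0.65)^2
  d_long <- amp_long_mm * sin(pi * s^0.8)^2
  data.frame(frame = seq_len(n_frames), time_s = t,
             d_long_mm = d_long, d_rad_mm = d_rad)
}

#' Preset rigid disturbance: respiratory drift plus probe-jitter glitches
#'
#' Each component (longitudinal shift mm, radial shift mm, rotation deg) is
#' a smooth low-frequency drift over the respiratory cycle, normalized to
#' the given peak amplitude, plus sparse short Gaussian-shaped glitches with
#' Poisson-distributed count (`glitch_rate` per second). Deterministic per
#' seed; frame 1 is exactly (0, 0, 0).
#'
#' @param n_frames Number of frames.
#' @param duration_s Duration (s).
#' @param drift_amp Peak drift amplitudes `c(long_mm, rad_mm, theta_deg)`
#'   (recycled), >= 0.
#' @param glitch_rate Expected glitches per second, >= 0.
#' @param glitch_amp Peak glitch amplitudes `c(long_mm, rad_mm, theta_deg)`
#'   (recycled), >= 0.
#' @param seed Integer seed (required for reproducibility).
#' @param glitch_sd_s Gaussian sd of one glitch (s).
#' @return Data frame `frame`, `time_s`, `d_long_mm`, `d_rad_mm`,
#'   `theta_deg`; attribute `glitch_times` holds the glitch centres.
#' @export
make_disturbance <- function(n_frames, duration_s, drift_amp = 0,
                             glitch_rate = 0, glitch_amp = 0, seed,
                             glitch_sd_s = 0.02) {
  stopifnot(n_frames >= 2, duration_s > 0, glitch_rate >= 0)
  drift_amp <- rep(drift_amp, length.out = 3L)
  glitch_amp <- rep(glitch_amp, length.out = 3L)
  stopifnot(all(drift_amp >= 0), all(glitch_amp >= 0))
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  t <- (seq_len(n_frames) - 1) * duration_s / n_frames
  comp <- matrix(0, n_frames, 3L)
  for (k in 1:3) {
    ph <- stats::runif(2, 0, 2 * pi)
    raw <- sin(2 * pi * t / duration_s + ph[1]) +
      0.4 * sin(4 * pi * t / duration_s + ph[2])
    raw <- raw - raw[1]
    m <- max(abs(raw))
    if (m > 0 && drift_amp[k] > 0) comp[, k] <- drift_amp[k] * raw / m
  }
  ng <- stats::rpois(1, glitch_rate * duration_s)
  centres <- numeric(0)
  if (ng > 0) {
    centres <- stats::runif(ng, 0.05 * duration_s, 0.95 * duration_s)
    for (g in seq_len(ng)) {
      shape <- exp(-(t - centres[g])^2 / (2 * glitch_sd_s^2))
      for (k in 1:3) {
        a <- glitch_amp[k] * sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1)
        comp[, k] <- comp[, k] + a * shape
      }
    }
    comp <- sweep(comp, 2L, comp[1, ])  # frame 1 exactly zero
  }
  out <- data.frame(frame = seq_len(n_frames), time_s = t,
                    d_long_mm = comp[, 1], d_rad_mm = comp[, 2],
                    theta_deg = comp[, 3])
  attr(out, "glitch_times") <- centres
  out
}

#' All-zero disturbance with the same schema as [make_disturbance()]
#' @param n_frames,duration_s Frame count and duration.
#' @export
zero_disturbance <- function(n_frames, duration_s) {
  t <- (seq_len(n_frames) - 1) * duration_s / n_frames
  data.frame(frame = seq_len(n_frames), time_s = t,
             d_long_mm = 0, d_rad_mm = 0, theta_deg = 0)
}

#' Procedural tissue echogenicity template
#'
#' Smooth anisotropic random field (structures elongated along the vessel
#' axis) plus a few soft horizontal fascia-like strata, on `[0.05, 1]`.
#' Stands in for the gray-level map of a filtered clinical seed image;
#' synthetic by construction.
#'
#' @param n_rows,n_cols Template size (px).
#' @param seed Integer seed.
#' @param n_strata Number of horizontal strata.
#' @param long_mod Amplitude of the longitudinal modulation of the strata;
#'   kept small by default because tissue layers in a longitudinal carotid
#'   view are nearly uniform along the vessel.
#' @return Matrix in `[0.05, 1]`.
#' @export
make_tissue_template <- function(n_rows, n_cols, seed, n_strata = 6L,
                                 long_mod = 0.08) {
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  gr <- gaussian_kernel2(3, radius = 10)
  gc <- gaussian_kernel2(9, radius = 28)
  k <- outer(rowSums(gr), rowSums(gc))  # separable anisotropic smoother
  k <- k / sum(k)
  sm <- conv2_circular(noise, k)
  sm <- sm / stats::sd(sm)
  strata <- numeric(n_rows)
  for (j in seq_len(n_strata)) {
    r0 <- stats::runif(1, 1, n_rows)
    w <- stats::runif(1, 4, 12)
    b <- stats::runif(1, -0.25, 0.3)
    strata <- strata + b * exp(-(seq_len(n_rows) - r0)^2 / (2 * w^2))
  }
  mod <- 1 + long_mod * sin(2 * pi * seq_len(n_cols) / n_cols *
                              stats::runif(1, 1, 3) +
                              stats::runif(1, 0, 2 * pi))
  tmpl <- 0.55 + 0.28 * sm + outer(strata, mod)
  pmin(pmax(tmpl, 0.05), 1)
}

#' Scatterer phantom from a template image
#'
#' Positions are uniform over the slab (image extent times the elevational
#' half-width); each amplitude is the template gray level at the initial
#' position times the vessel-layer multiplier.
#'
#' @param template Echogenicity matrix in `[0, 1]` (or a scalar for a flat
#'   slab, in which case `dim` gives the grid size).
#' @param wall A [wall_model()], or `NULL` for no vessel.
#' @param n_scatterers Number of scatterers (choose >= 10 per resolution
#'   cell for fully developed speckle).
#' @param seed Integer seed.
#' @param spacing_mm Pixel spacing of the template (mm/px).
#' @param elev_halfwidth_mm Slab half-thickness in elevation (mm).
#' @param dim `c(rows, cols)` when `template` is a scalar.
#' @return Object of class `scatterer_set` with vectors `row_mm`, `col_mm`,
#'   `elev_mm`, `amplitude`.
#' @export
make_phantom <- function(template, wall = NULL, n_scatterers, seed,
                         spacing_mm = 0.05, elev_halfwidth_mm = 0.5,
                         dim = NULL) {
  if (length(template) == 0) stop("empty template")
  if (length(template) == 1) {
    if (is.null(dim)) stop("scalar template needs dim = c(rows, cols)")
    template <- matrix(template, dim[1], dim[2])
  }
  stopifnot(is.matrix(template), n_scatterers >= 1)
  set.seed(as.integer(seed))
  nr <- nrow(template); nc <- ncol(template)
  row_mm <- stats::runif(n_scatterers, 0, nr * spacing_mm)
  col_mm <- stats::runif(n_scatterers, 0, nc * spacing_mm)
  elev_mm <- stats::runif(n_scatterers, -elev_halfwidth_mm, elev_halfwidth_mm)
  rp <- pmin(pmax(row_mm / spacing_mm + 0.5, 1), nr)
  cp <- pmin(pmax(col_mm / spacing_mm + 0.5, 1), nc)
  amp <- bilinear_sample(template, rp, cp, fill = 0)
  if (!is.null(wall)) {
    amp <- amp * layer_multiplier(wall, abs(row_mm - wall$center_row_mm))
  }
  structure(list(row_mm = row_mm, col_mm = col_mm, elev_mm = elev_mm,
                 amplitude = amp, spacing_mm = spacing_mm,
                 n_rows = nr, n_cols = nc,
                 elev_halfwidth_mm = elev_halfwidth_mm),
            class = "scatterer_set")
}

#' B-mode rendering configuration
#'
#' @param n_rows,n_cols Output frame size (px).
#' @param spacing_mm Pixel spacing (mm/px), > 0.
#' @param lambda_mm Axial carrier wavelength of the PSF (mm).
#' @param sigma_ax_mm,sigma_lat_mm Gaussian envelope sds of the PSF (mm).
#' @param sigma_elev_mm Elevational beam sensitivity sd (mm).
#' @param dynamic_range_db Log-compression dynamic range (dB), > 0.
#' @param bit_depth Output bit depth (default 8).
#' @param ref_level Envelope mapped to full brightness; `NULL` means the
#'   frame (or sequence calibration frame) maximum.
#' @return Object of class `render_config`.
#' @export
render_config <- function(n_rows, n_cols, spacing_mm = 0.05,
                          lambda_mm = 0.30, sigma_ax_mm = 0.12,
                          sigma_lat_mm = 0.25, sigma_elev_mm = 0.35,
                          dynamic_range_db = 50, bit_depth = 8L,
                          ref_level = NULL) {
  stopifnot(spacing_mm > 0, dynamic_range_db > 0, n_rows >= 8, n_cols >= 8)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 spacing_mm = spacing_mm, lambda_mm = lambda_mm,
                 sigma_ax_mm = sigma_ax_mm, sigma_lat_mm = sigma_lat_mm,
                 sigma_elev_mm = sigma_elev_mm,
                 dynamic_range_db = dynamic_range_db,
                 bit_depth = as.integer(bit_depth), ref_level = ref_level),
            class = "render_config")
}

# complex separable PSF: axial Gaussian times carrier, lateral Gaussian
psf_kernel <- function(config) {
  sp <- config$spacing_mm
  ra <- ceiling(3 * config$sigma_ax_mm / sp)
  rl <- ceiling(3 * config$sigma_lat_mm / sp)
  ya <- seq(-ra, ra) * sp
  yl <- seq(-rl, rl) * sp
  ax <- exp(-ya^2 / (2 * config$sigma_ax_mm^2)) *
    exp(complex(imaginary = 2 * pi * ya / config$lambda_mm))
  lat <- exp(-yl^2 / (2 * config$sigma_lat_mm^2))
  outer(ax, lat)
}

# bilinear splat of scatterer amplitudes onto the pixel grid
splat_scatterers <- function(row_mm, col_mm, amp, config) {
  sp <- config$spacing_mm
  nr <- config$n_rows; nc <- config$n_cols
  rp <- row_mm / sp + 0.5
  cp <- col_mm / sp + 0.5
  r0 <- floor(rp); c0 <- floor(cp)
  fr <- rp - r0; fc <- cp - c0
  ri <- c(r0, r0 + 1, r0, r0 + 1)
  ci <- c(c0, c0, c0 + 1, c0 + 1)
  wt <- c(amp * (1 - fr) * (1 - fc), amp * fr * (1 - fc),
          amp * (1 - fr) * fc, amp * fr * fc)
  keep <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & wt != 0
  if (!any(keep)) return(matrix(0, nr, nc))
  as.matrix(Matrix::sparseMatrix(i = ri[keep], j = ci[keep], x = wt[keep],
                                 dims = c(nr, nc)))
}

# smooth zero-mean random field (unit sd) emulating spatial gain
# inhomogeneity; corr_px sets the correlation length
smooth_gain_field <- function(n_rows, n_cols, corr_px) {
  g <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  sig <- corr_px / 2
  rad <- min(ceiling(2.5 * sig), (min(n_rows, n_cols) - 1L) %/% 2L)
  g <- conv2_circular(g, gaussian_kernel2(sig, rad))
  (g - mean(g)) / stats::sd(g)
}

#' Render one B-mode frame from a scatterer set
#'
#' Splats the (elevation-weighted) amplitudes onto the grid, convolves with
#' the complex PSF, takes the envelope and log-compresses over the dynamic
#' range. An optional spatial gain field (in dB) multiplies the envelope
#' before compression, emulating frame-to-frame brightness/contrast
#' inhomogeneity from probe contact and beam variations. The
#' pre-compression envelope is attached as attribute `"envelope"`, the
#' reference level as `"ref_level"`.
#'
#' @param scatterers A [make_phantom()] result, or a list with `row_mm`,
#'   `col_mm`, `elev_mm`, `amplitude`.
#' @param config A [render_config()].
#' @param ref_level Optional envelope reference overriding the config.
#' @param quantize Round gray values to integers (default TRUE).
#' @param gain_db Optional matrix (frame-sized) of gain offsets in dB.
#' @return Gray-value matrix in `[0, 2^bit_depth - 1]`.
#' @export
render_bmode <- function(scatterers, config, ref_level = NULL,
                         quantize = TRUE, gain_db = NULL) {
  stopifnot(inherits(config, "render_config"))
  wz <- exp(-scatterers$elev_mm^2 / (2 * config$sigma_elev_mm^2))
  splat <- splat_scatterers(scatterers$row_mm, scatterers$col_mm,
                            scatterers$amplitude * wz, config)
  env <- Mod(conv2_circular(splat, psf_kernel(config)))
  if (!is.null(gain_db)) env <- env * 10^(gain_db / 20)
  maxval <- 2^config$bit_depth - 1
  ref <- ref_level %||% config$ref_level %||% max(env)
  if (ref <= 0) {
    frame <- matrix(0, config$n_rows, config$n_cols)
  } else {
    db <- 20 * log10(pmax(env, 1e-300) / ref)
    frame <- maxval * (db + config$dynamic_range_db) / config$dynamic_range_db
    frame <- pmin(pmax(frame, 0), maxval)
    if (quantize) frame <- round(frame)
  }
  attr(frame, "envelope") <- env
  attr(frame, "ref_level") <- ref
  frame
}

#' Simulate a B-mode sequence with known motion and disturbance
#'
#' Per frame, wall-band scatterers move by the wall trajectory (weighted by
#' [wall_motion_weight()], so far tissue stays put), then the frame's rigid
#' disturbance moves all scatterers (rotation about the image centre), a
#' fresh elevational jitter decorrelates the speckle, and the frame is
#' rendered. The log-compression reference is calibrated on frame 1 and held
#' fixed. The returned ground truths are the inputs, untouched.
#'
#' @param wall_traj [make_wall_trajectory()] data frame.
#' @param disturbance [make_disturbance()] data frame (same frame count).
#' @param phantom A [make_phantom()] scatterer set.
#' @param wall The [wall_model()] used for the motion weights.
#' @param config A [render_config()].
#' @param seed Integer seed for the per-frame elevational jitter and gain
#'   fields.
#' @param elev_jitter_sd_mm Per-frame elevational jitter sd (mm),
#'   default 0.02.
#' @param gain_sd_db Sd of the per-frame smooth spatial gain field (dB);
#'   0 disables it.
#' @param gain_corr_px Correlation length of the gain field (px).
#' @return List with `sequence` (an [image_sequence()]), `motion`,
#'   `disturbance` (the inputs).
#' @export
simulate_sequence <- function(wall_traj, disturbance, phantom, wall, config,
                              seed, elev_jitter_sd_mm = 0.02,
                              gain_sd_db = 0, gain_corr_px = 40) {
  if (nrow(wall_traj) != nrow(disturbance)) {
    stop("wall_traj and disturbance must have equal frame counts")
  }
  nfr <- nrow(wall_traj)
  n <- length(phantom$row_mm)
  cx <- config$n_cols * config$spacing_mm / 2
  cy <- config$n_rows * config$spacing_mm / 2
  d0 <- abs(phantom$row_mm - wall$center_row_mm)
  sgn <- ifelse(phantom$row_mm >= wall$center_row_mm, 1, -1)
  wmot <- wall_motion_weight(wall, d0)
  frames <- vector("list", nfr)
  ref_level <- config$ref_level
  for (k in seq_len(nfr)) {
    rowk <- phantom$row_mm + sgn * wmot * wall_traj$d_rad_mm[k]
    colk <- phantom$col_mm + wmot * wall_traj$d_long_mm[k]
    th <- disturbance$theta_deg[k]
    if (th != 0 || disturbance$d_long_mm[k] != 0 ||
        disturbance$d_rad_mm[k] != 0) {
      Rm <- rot_mat(th)
      x <- colk - cx
      y <- rowk - cy
      colk <- Rm[1, 1] * x + Rm[1, 2] * y + cx + disturbance$d_long_mm[k]
      rowk <- Rm[2, 1] * x + Rm[2, 2] * y + cy + disturbance$d_rad_mm[k]
    }
    set.seed(as.integer(seed) + k)
    elev <- phantom$elev_mm + stats::rnorm(n, 0, elev_jitter_sd_mm)
    gain <- NULL
    if (gain_sd_db > 0) {
      gain <- gain_sd_db * smooth_gain_field(config$n_rows, config$n_cols,
                                             gain_corr_px)
    }
    sc <- list(row_mm = rowk, col_mm = colk, elev_mm = elev,
               amplitude = phantom$amplitude)
    frames[[k]] <- render_bmode(sc, config, ref_level = ref_level,
                                gain_db = gain)
    if (k == 1L && is.null(ref_level)) {
      ref_level <- attr(frames[[1]], "ref_level")
    }
    attr(frames[[k]], "envelope") <- NULL
  }
  dt <- wall_traj$time_s[2] - wall_traj$time_s[1]
  list(sequence = image_sequence(frames, config$spacing_mm, dt),
       motion = wall_traj, disturbance = disturbance)
}
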