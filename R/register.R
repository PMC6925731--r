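# Rigid registration of far-from-wall subimages.
#
# The probe/breathing disturbance is common-mode: it moves the whole frame,
# while the wall's own motion is confined to the vessel band. Two horizontal
# subimages (top and bottom of the frame, away from the wall) are therefore
# registered against frame 1 on feature images, and the upper/lower results
# are averaged component-wise. Because each band's rotation pivot sits off
# the image centre, a rotation about the image centre shows up in a single
# band as the same angle plus a spurious translation of opposite sign in the
# two bands; the average over symmetric bands cancels it exactly.

#' Subimage bands for disturbance registration
#'
#' @param upper_frac Fraction of the frame height forming the top band
#'   (default 0.30).
#' @param lower_frac Fraction forming the bottom band (default 0.30).
#' @param wall_rows Optional `c(first, last)` rows of the excluded wall
#'   band; the bands must not touch it.
#' @return Object of class `subimage_spec`.
#' @export
subimage_spec <- function(upper_frac = 0.30, lower_frac = 0.30,
                          wall_rows = NULL) {
  stopifnot(upper_frac > 0, lower_frac > 0, upper_frac + lower_frac <= 1)
  structure(list(upper_frac = upper_frac, lower_frac = lower_frac,
                 wall_rows = wall_rows),
            class = "subimage_spec")
}

band_rows <- function(n_rows, spec) {
  nu <- floor(n_rows * spec$upper_frac)
  nl <- floor(n_rows * spec$lower_frac)
  if (nu < 1 || nl < 1) stop("empty subimage band")
  list(upper = seq_len(nu), lower = seq.int(n_rows - nl + 1L, n_rows))
}

#' Cut the upper and lower subimages out of a frame
#'
#' Plain row slices, no resampling.
#' @param frame Image matrix.
#' @param spec A [subimage_spec()].
#' @return List with matrices `upper` and `lower`.
#' @export
extract_subimages <- function(frame, spec = subimage_spec()) {
  br <- band_rows(nrow(frame), spec)
  if (!is.null(spec$wall_rows)) {
    w <- spec$wall_rows
    if (max(br$upper) >= w[1] || min(br$lower) <= w[2]) {
      stop("subimage bands overlap the wall band")
    }
  }
  list(upper = frame[br$upper, , drop = FALSE],
       lower = frame[br$lower, , drop = FALSE])
}

#' Search bounds for rigid registration
#'
#' @param max_shift Maximum translation in px (scalar or `c(rows, cols)`),
#'   default 30.
#' @param max_theta Maximum |rotation| in degrees, default 5.
#' @param theta_step Coarse rotation grid step in degrees, default 0.5.
#' @export
register_bounds <- function(max_shift = 30L, max_theta = 5,
                            theta_step = 0.5) {
  max_shift <- as.integer(rep(max_shift, length.out = 2L))
  stopifnot(all(max_shift >= 1), max_theta >= 0, theta_step > 0)
  structure(list(max_shift = max_shift, max_theta = max_theta,
                 theta_step = theta_step),
            class = "register_bounds")
}

#' Rigid registration of a float image onto a reference
#'
#' Finds the transform `T = (d_col, d_row, theta)` maximizing the overlap
#' NCC between `float` and `warp_rigid(ref, T)`, i.e. the rigid motion of
#' the float content relative to the reference. Stage 1 scans a coarse
#' rotation grid, solving the translation exhaustively at each angle via
#' the FFT overlap-NCC map; stage 2 refines all three parameters with a
#' derivative-free (Nelder-Mead) search using bilinear interpolation.
#' Rotation pivot is the (sub)image centre.
#'
#' @param ref,flt Equal-size feature images (NAs treated as invalid).
#' @param bounds A [register_bounds()].
#' @return List with `transform` (a [rigid_transform()]) and `score` (NCC
#'   at the optimum).
#' @export
register_rigid <- function(ref, flt, bounds = register_bounds()) {
  stopifnot(identical(dim(ref), dim(flt)))
  if (stats::sd(ref[is.finite(ref)]) == 0 ||
      stats::sd(flt[is.finite(flt)]) == 0) {
    stop("degenerate input: zero-variance feature image")
  }
  thetas <- seq(-bounds$max_theta, bounds$max_theta, by = bounds$theta_step)
  if (!any(thetas == 0)) thetas <- sort(c(thetas, 0))
  best <- NULL
  for (th in thetas) {
    ref_th <- if (th == 0) ref else {
      warp_rigid(ref, rigid_transform(0, 0, th), fill = NA_real_)
    }
    map <- ncc_shift_map(ref_th, flt, bounds$max_shift[1], bounds$max_shift[2])
    pk <- ncc_argmax(map)
    if (is.null(pk)) next
    if (is.null(best) || pk$peak > best$score) {
      best <- list(d_col = pk$d_col, d_row = pk$d_row, theta = th,
                   score = pk$peak)
    }
  }
  if (is.null(best)) stop("registration failed: no scorable shift")
  if (best$score >= 1 - 1e-12) {  # exact integer match; nothing to refine
    return(list(transform = rigid_transform(best$d_col, best$d_row, best$theta),
                score = best$score))
  }
  neg_score <- function(par) {
    if (abs(par[1]) > bounds$max_shift[2] + 1 ||
        abs(par[2]) > bounds$max_shift[1] + 1 ||
        abs(par[3]) > bounds$max_theta + bounds$theta_step) {
      return(2)
    }
    s <- ncc_overlap(warp_rigid(ref, rigid_transform(par[1], par[2], par[3]),
                                fill = NA_real_), flt)
    if (is.na(s)) 2 else -s
  }
  opt <- stats::optim(c(best$d_col, best$d_row, best$theta), neg_score,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 250))
  if (-opt$value >= best$score) {
    list(transform = rigid_transform(opt$par[1], opt$par[2], opt$par[3]),
         score = -opt$value)
  } else {
    list(transform = rigid_transform(best$d_col, best$d_row, best$theta),
         score = best$score)
  }
}

# register a list of feature images (one band) against its first frame
register_feature_sequence <- function(feats, bounds) {
  nfr <- length(feats)
  out <- data.frame(frame = seq_len(nfr), d_col = 0, d_row = 0,
                    theta_deg = 0, score = 1)
  for (k in seq_len(nfr)[-1]) {
    rr <- register_rigid(feats[[1]], feats[[k]], bounds)
    out$d_col[k] <- rr$transform$d_col
    out$d_row[k] <- rr$transform$d_row
    out$theta_deg[k] <- rr$transform$theta_deg
    out$score[k] <- rr$score
  }
  out
}

#' Estimate the per-frame rigid disturbance of a sequence
#'
#' Cuts the two far-from-wall bands out of every frame, builds the feature
#' images prescribed by the method variant (optionally SRAD-filtered, then
#' intensity / phase / orientation / combined), registers each band against
#' frame 1 and averages the upper and lower transforms component-wise.
#'
#' @param seq An [image_sequence()].
#' @param variant Method variant name (see [variant_table()]), default
#'   `"SWPOM"`.
#' @param spec A [subimage_spec()].
#' @param bounds A [register_bounds()].
#' @param srad_cfg An [srad_config()] used when the variant filters
#'   (its `w` is overridden by the variant).
#' @param mono_cfg A [monogenic_config()] for the feature images.
#' @param region_offsets Optional per-frame `d_row_px`/`d_col_px` data frame
#'   for homogeneous-region propagation (e.g. the preset disturbance in a
#'   simulation); `NULL` uses automatic propagation.
#' @return Data frame with per-frame averaged `d_long_px`, `d_rad_px`,
#'   `theta_deg`, the per-band transforms (`*_up`, `*_lo`) and NCC scores.
#' @export
estimate_disturbance <- function(seq, variant = "SWPOM",
                                 spec = subimage_spec(),
                                 bounds = register_bounds(),
                                 srad_cfg = srad_config(),
                                 mono_cfg = monogenic_config(),
                                 region_offsets = NULL) {
  stopifnot(inherits(seq, "image_sequence"), length(seq$frames) >= 2)
  vs <- variant_spec(variant)
  bands <- lapply(seq$frames, extract_subimages, spec = spec)
  upper <- lapply(bands, `[[`, "upper")
  lower <- lapply(bands, `[[`, "lower")
  prep <- function(frames_band) {
    filt <- filter_band_sequence(frames_band, vs$filter, srad_cfg,
                                 region_offsets)
    lapply(filt, make_feature_image, config = mono_cfg, mode = vs$feature)
  }
  ru <- register_feature_sequence(prep(upper), bounds)
  rl <- register_feature_sequence(prep(lower), bounds)
  data.frame(frame = ru$frame,
             d_long_px = (ru$d_col + rl$d_col) / 2,
             d_rad_px = (ru$d_row + rl$d_row) / 2,
             theta_deg = (ru$theta_deg + rl$theta_deg) / 2,
             d_long_px_up = ru$d_col, d_rad_px_up = ru$d_row,
             theta_deg_up = ru$theta_deg, score_up = ru$score,
             d_long_px_lo = rl$d_col, d_rad_px_lo = rl$d_row,
             theta_deg_lo = rl$theta_deg, score_lo = rl$score)
}

#' Align a sequence by inverting per-frame rigid transforms
#'
#' Each frame is resampled through the inverse of its transform (rotation
#' about the image centre, bilinear interpolation, zero fill), so the
#' common-mode disturbance is removed; frame 1 passes through unchanged.
#'
#' @param seq An [image_sequence()].
#' @param disturbance Data frame with per-frame `d_long_px`, `d_rad_px`,
#'   `theta_deg` (e.g. from [estimate_disturbance()]).
#' @return Aligned [image_sequence()].
#' @export
align_sequence <- function(seq, disturbance) {
  stopifnot(inherits(seq, "image_sequence"),
            nrow(disturbance) == length(seq$frames))
  frames <- vector("list", length(seq$frames))
  for (k in seq_along(frames)) {
    tf <- rigid_transform(disturbance$d_long_px[k], disturbance$d_rad_px[k],
                          disturbance$theta_deg[k])
    if (tf$d_col == 0 && tf$d_row == 0 && tf$theta_deg == 0) {
      frames[[k]] <- seq$frames[[k]]
    } else {
      frames[[k]] <- warp_rigid(seq$frames[[k]], invert_rigid(tf), fill = 0)
    }
  }
  image_sequence(frames, seq$spacing_mm, seq$frame_interval_s)
}

#' Convert a pixel-unit disturbance estimate to physical units
#'
#' @param disturbance Data frame with `d_long_px`, `d_rad_px`, `theta_deg`.
#' @param spacing_mm Pixel spacing (mm/px).
#' @param times Optional per-frame times (s).
#' @return Data frame with `frame`, `time_s`, `d_long_mm`, `d_rad_mm`,
#'   `theta_deg`.
#' @export
disturbance_to_mm <- function(disturbance, spacing_mm, times = NULL) {
  data.frame(frame = disturbance$frame,
             time_s = times %||% rep(NA_real_, nrow(disturbance)),
             d_long_mm = disturbance$d_long_px * spacing_mm,
             d_rad_mm = disturbance$d_rad_px * spacing_mm,
             theta_deg = disturbance$theta_deg)
}
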