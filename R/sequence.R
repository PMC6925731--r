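# Image sequence container and file I/O.
#
# A sequence is a list of equally sized numeric matrices (gray values on the
# 0..255 scale), together with the pixel spacing (mm/px, isotropic) and the
# frame interval (s). Rows are the depth/radial axis, columns the
# vessel/longitudinal axis. On disk a sequence is an 8-bit multi-page TIFF
# plus a JSON sidecar carrying the spatio-temporal metadata; trajectories are
# plain CSV.

#' Build an image sequence
#'
#' @param frames List of numeric matrices with identical dimensions, gray
#'   values in `[0, 255]`.
#' @param spacing_mm Pixel spacing in mm/px (isotropic).
#' @param frame_interval_s Time between frames in seconds.
#' @return Object of class `image_sequence`.
#' @export
image_sequence <- function(frames, spacing_mm, frame_interval_s) {
  stopifnot(length(frames) >= 1, is.matrix(frames[[1]]))
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("all frames must share the same dimensions")
  }
  stopifnot(spacing_mm > 0, frame_interval_s > 0)
  structure(list(frames = frames, spacing_mm = spacing_mm,
                 frame_interval_s = frame_interval_s),
            class = "image_sequence")
}

#' @exportS3Method base::print
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "image_sequence: %d frames of %d x %d px, %.3f mm/px, %.4f s/frame (%.2f s)\n",
    length(x$frames), d[1], d[2], x$spacing_mm, x$frame_interval_s,
    length(x$frames) * x$frame_interval_s))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) length(x$frames)

frame_times <- function(seq) (seq_along(seq$frames) - 1) * seq$frame_interval_s

#' Write a sequence as 8-bit multi-page TIFF plus JSON sidecar
#'
#' @param seq An [image_sequence()].
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension appended.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  pages <- lapply(seq$frames, function(f) pmin(pmax(f, 0), 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(spacing_mm = seq$spacing_mm,
               frame_interval_s = seq$frame_interval_s,
               n_frames = length(seq$frames),
               dim = dim(seq$frames[[1]]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sequence written by [write_sequence()]
#'
#' @param path TIFF path; the `.json` sidecar must sit next to it. If the
#'   sidecar is missing, `spacing_mm` and `frame_interval_s` must be given.
#' @param spacing_mm,frame_interval_s Metadata overrides.
#' @return An [image_sequence()].
#' @export
read_sequence <- function(path, spacing_mm = NULL, frame_interval_s = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * 255
  })
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    spacing_mm <- spacing_mm %||% meta$spacing_mm
    frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
  }
  if (is.null(spacing_mm) || is.null(frame_interval_s)) {
    stop("no JSON sidecar found; supply spacing_mm and frame_interval_s")
  }
  image_sequence(frames, spacing_mm, frame_interval_s)
}

#' Write a wall-motion trajectory CSV
#'
#' Columns: `frame`, `time_s`, `d_long_mm`, `d_rad_mm`.
#' @param motion Data frame with those columns.
#' @param path Output CSV path.
#' @export
write_motion <- function(motion, path) {
  stopifnot(all(c("frame", "time_s", "d_long_mm", "d_rad_mm") %in% names(motion)))
  utils::write.csv(motion[, c("frame", "time_s", "d_long_mm", "d_rad_mm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a rigid-disturbance trajectory CSV
#'
#' Columns: `frame`, `time_s`, `d_long_mm`, `d_rad_mm`, `theta_deg`.
#' @param dist Data frame with those columns.
#' @param path Output CSV path.
#' @export
write_disturbance <- function(dist, path) {
  cols <- c("frame", "time_s", "d_long_mm", "d_rad_mm", "theta_deg")
  stopifnot(all(cols %in% names(dist)))
  utils::write.csv(dist[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_motion()] or [write_disturbance()]
#' @param path CSV path.
#' @export
read_trajectory <- function(path) utils::read.csv(path)
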