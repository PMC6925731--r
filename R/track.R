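# Speckle tracking of the arterial wall by NCC block matching.
#
# A reference block (ROI) straddling the blood/wall interface is fixed in
# frame 1 and never updated; every later frame is searched for the best
# matching block within an integer displacement bound. Tracking the aligned
# (disturbance-suppressed) sequence yields the differential-mode wall motion.

#' Region of interest for block matching
#'
#' @param row,col Top-left corner (1-based) of the block in frame 1.
#' @param height Rows (radial extent), default 60 px (~3 mm at 0.05 mm/px).
#' @param width Columns (longitudinal extent), default 80 px (~4 mm).
#' @return Integer vector `c(row, col, height, width)` of class `roi_spec`.
#' @export
roi_spec <- function(row, col, height = 60L, width = 80L) {
  stopifnot(row >= 1, col >= 1, height >= 2, width >= 2)
  structure(as.integer(c(row, col, height, width)), class = "roi_spec")
}

#' Search specification for block matching
#'
#' @param max_d Maximum displacement in px, one value for both axes or
#'   `c(rows, cols)`; default 20.
#' @param subpixel If `TRUE`, refine the integer peak with a 1D parabolic
#'   fit per axis.
#' @export
search_spec <- function(max_d = 20L, subpixel = FALSE) {
  max_d <- as.integer(rep(max_d, length.out = 2L))
  stopifnot(all(max_d >= 1))
  structure(list(max_d = max_d, subpixel = subpixel), class = "search_spec")
}

parabolic_refine <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den >= 0) return(0)
  d <- 0.5 * (ym1 - yp1) / den
  max(min(d, 0.5), -0.5)
}

#' Block matching of one frame against the reference block
#'
#' Exhaustive NCC over the integer search grid; ties are broken by the
#' smallest displacement magnitude, then row-major order. A positive
#' `d_row`/`d_col` means the matched block sits below/right of the ROI.
#'
#' @param ref_frame Frame holding the reference block.
#' @param float_frame Frame to search.
#' @param roi A [roi_spec()] (inside `ref_frame`; the ROI expanded by the
#'   search bound must fit inside `float_frame`).
#' @param search A [search_spec()].
#' @return List with `d_row`, `d_col` (px, possibly fractional when
#'   `subpixel`), `peak` (NCC at the integer optimum) and `on_boundary`
#'   (TRUE when the integer peak touches the search bound).
#' @export
block_match <- function(ref_frame, float_frame, roi, search = search_spec()) {
  stopifnot(identical(dim(ref_frame), dim(float_frame)))
  r <- as.integer(roi)
  s <- search$max_d
  nr <- nrow(float_frame); nc <- ncol(float_frame)
  if (r[1] - s[1] < 1 || r[2] - s[2] < 1 ||
      r[1] + r[3] - 1 + s[1] > nr || r[2] + r[4] - 1 + s[2] > nc) {
    stop("ROI plus search window does not fit inside the frame")
  }
  block <- ref_frame[r[1]:(r[1] + r[3] - 1), r[2]:(r[2] + r[4] - 1)]
  if (stats::sd(block) == 0) stop("degenerate block: zero variance")
  window <- float_frame[(r[1] - s[1]):(r[1] + r[3] - 1 + s[1]),
                        (r[2] - s[2]):(r[2] + r[4] - 1 + s[2])]
  ref_pad <- matrix(NA_real_, nrow(window), ncol(window))
  ref_pad[s[1] + seq_len(r[3]), s[2] + seq_len(r[4])] <- block
  map <- ncc_shift_map(ref_pad, window, s[1], s[2])
  pk <- ncc_argmax(map)
  if (is.null(pk)) stop("degenerate block: zero variance")
  d_row <- pk$d_row
  d_col <- pk$d_col
  on_boundary <- abs(pk$d_row) == s[1] || abs(pk$d_col) == s[2]
  if (search$subpixel && !on_boundary) {
    i <- pk$idx[1]; j <- pk$idx[2]
    v <- map$ncc
    if (i > 1 && i < nrow(v)) {
      d_row <- d_row + parabolic_refine(v[i - 1, j], v[i, j], v[i + 1, j])
    }
    if (j > 1 && j < ncol(v)) {
      d_col <- d_col + parabolic_refine(v[i, j - 1], v[i, j], v[i, j + 1])
    }
  }
  list(d_row = d_row, d_col = d_col, peak = pk$peak, on_boundary = on_boundary)
}

#' Track the wall ROI through a sequence
#'
#' Frame 1 holds the fixed reference block; every frame is matched against
#' it and displacements are converted to mm via the pixel spacing.
#'
#' @param seq An [image_sequence()] (typically the aligned sequence).
#' @param roi A [roi_spec()] placed across the blood/wall interface in
#'   frame 1.
#' @param search A [search_spec()].
#' @return Data frame with columns `frame`, `time_s`, `d_long_mm`,
#'   `d_rad_mm`, `d_long_px`, `d_rad_px`, `peak`, `on_boundary`; attribute
#'   `n_boundary` counts search-bound hits.
#' @export
track_sequence <- function(seq, roi, search = search_spec()) {
  stopifnot(inherits(seq, "image_sequence"))
  nfr <- length(seq$frames)
  times <- frame_times(seq)
  out <- data.frame(frame = seq_len(nfr), time_s = times,
                    d_long_mm = 0, d_rad_mm = 0,
                    d_long_px = 0, d_rad_px = 0, peak = 1,
                    on_boundary = FALSE)
  for (k in seq_len(nfr)[-1]) {
    bm <- block_match(seq$frames[[1]], seq$frames[[k]], roi, search)
    out$d_long_px[k] <- bm$d_col
    out$d_rad_px[k] <- bm$d_row
    out$d_long_mm[k] <- bm$d_col * seq$spacing_mm
    out$d_rad_mm[k] <- bm$d_row * seq$spacing_mm
    out$peak[k] <- bm$peak
    out$on_boundary[k] <- bm$on_boundary
  }
  attr(out, "n_boundary") <- sum(out$on_boundary)
  out
}

#' Motion amplitude series of a trajectory
#'
#' Euclidean norm of the (longitudinal, radial) displacement per frame, mm.
#' @param motion Trajectory data frame with `d_long_mm`, `d_rad_mm`.
#' @export
motion_amplitude <- function(motion) {
  sqrt(motion$d_long_mm^2 + motion$d_rad_mm^2)
}
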