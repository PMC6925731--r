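# Rigid (shift + rotation) transforms in pixel coordinates.
#
# A transform T = (d_col, d_row, theta_deg) moves image content: a feature at
# position p = (x = col, y = row) appears at A(p) = R(theta) (p - pivot) +
# pivot + t, with t = (d_col, d_row) and R the rotation matrix acting on
# (x, y). theta is in degrees; positive theta rotates towards increasing row
# for points right of the pivot (rows grow downwards). The same convention is
# used by the simulator when it displaces scatterers, so estimated and preset
# disturbances are directly comparable.

#' Rotation matrix for (x, y) column vectors
#' @noRd
rot_mat <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Create a rigid transform
#'
#' @param d_col,d_row Translation in pixels along columns (longitudinal) and
#'   rows (radial/depth).
#' @param theta_deg Rotation angle in degrees about `pivot`.
#' @param pivot Optional `(x, y)` rotation centre; `NULL` means the centre of
#'   whatever image the transform is applied to.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(d_col = 0, d_row = 0, theta_deg = 0, pivot = NULL) {
  stopifnot(is.finite(d_col), is.finite(d_row), is.finite(theta_deg))
  structure(list(d_col = d_col, d_row = d_row, theta_deg = theta_deg,
                 pivot = pivot),
            class = "rigid_transform")
}

#' @exportS3Method base::print
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: d_col = %.3f px, d_row = %.3f px, theta = %.3f deg\n",
              x$d_col, x$d_row, x$theta_deg))
  invisible(x)
}

image_pivot <- function(img) c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)

#' Invert a rigid transform
#'
#' Returns the transform T' with A' = A^{-1} about the same pivot.
#' @param tf A [rigid_transform()].
#' @export
invert_rigid <- function(tf) {
  Rm <- rot_mat(-tf$theta_deg)
  t2 <- -Rm %*% c(tf$d_col, tf$d_row)
  rigid_transform(t2[1], t2[2], -tf$theta_deg, tf$pivot)
}

#' Compose two rigid transforms (first `a`, then `b`)
#'
#' Both must share the pivot convention; the result satisfies
#' A_out = A_b o A_a.
#' @param a,b [rigid_transform()] objects.
#' @export
compose_rigid <- function(a, b) {
  Rb <- rot_mat(b$theta_deg)
  t2 <- Rb %*% c(a$d_col, a$d_row) + c(b$d_col, b$d_row)
  rigid_transform(t2[1], t2[2], a$theta_deg + b$theta_deg, a$pivot %||% b$pivot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a rigid transform to an image
#'
#' Content is moved by the transform (inverse mapping with bilinear
#' interpolation); pixels whose source falls outside the input are set to
#' `fill` (`NA` lets downstream code mask them, 0 mimics a dark border).
#'
#' @param img Numeric matrix.
#' @param tf A [rigid_transform()].
#' @param fill Value for out-of-support pixels.
#' @return Matrix of the same size.
#' @export
warp_rigid <- function(img, tf, fill = 0) {
  stopifnot(is.matrix(img))
  piv <- tf$pivot %||% image_pivot(img)
  nr <- nrow(img)
  nc <- ncol(img)
  x <- rep(seq_len(nc), each = nr)
  y <- rep(seq_len(nr), times = nc)
  Rm <- rot_mat(-tf$theta_deg)
  dx <- x - piv[1] - tf$d_col
  dy <- y - piv[2] - tf$d_row
  sx <- Rm[1, 1] * dx + Rm[1, 2] * dy + piv[1]
  sy <- Rm[2, 1] * dx + Rm[2, 2] * dy + piv[2]
  matrix(bilinear_sample(img, sy, sx, fill = fill), nr, nc)
}
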