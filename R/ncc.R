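# Normalized cross-correlation, both as a scalar block similarity and as an
# FFT-accelerated map over all integer shifts with overlap-only scoring
# (masked correlation: every sum entering the NCC is itself a
# cross-correlation of masked planes, so the map is exact, not an
# approximation).

#' Normalized correlation coefficient of two blocks
#'
#' `sum((R - mean R)(F - mean F)) / sqrt(sum((R - mean R)^2) sum((F - mean
#' F)^2))`; invariant to affine intensity changes of either block.
#'
#' @param R,F Equal-size numeric matrices with nonzero variance.
#' @return Scalar in `[-1, 1]`.
#' @export
ncc <- function(R, F) {
  stopifnot(identical(dim(R), dim(F)))
  r <- R - mean(R)
  f <- F - mean(F)
  vr <- sum(r^2)
  vf <- sum(f^2)
  if (vr == 0 || vf == 0) stop("degenerate block: zero variance")
  sum(r * f) / sqrt(vr * vf)
}

# overlap NCC of two same-size images restricted to jointly finite pixels;
# returns NA when the overlap is too small or degenerate
ncc_overlap <- function(A, B, min_frac = 0.25) {
  ok <- is.finite(A) & is.finite(B)
  n <- sum(ok)
  if (n < min_frac * length(A) || n < 16) return(NA_real_)
  a <- A[ok]; b <- B[ok]
  a <- a - mean(a); b <- b - mean(b)
  va <- sum(a^2); vb <- sum(b^2)
  if (va <= 0 || vb <= 0) return(NA_real_)
  sum(a * b) / sqrt(va * vb)
}

# cross-correlation X(s) = sum_y A(y) B(y + s) for all wrapped lags,
# computed with zero padding to at least size + max lag in each dimension
xcorr_terms <- function(Alist, Blist, pr, pc) {
  pad <- function(M) {
    P <- matrix(0, pr, pc)
    P[seq_len(nrow(M)), seq_len(ncol(M))] <- M
    P
  }
  FA <- lapply(Alist, function(M) Conj(fft2(pad(M))))
  FB <- lapply(Blist, function(M) fft2(pad(M)))
  list(FA = FA, FB = FB)
}

lag_index <- function(lag, p) ((lag %% p) + 1L)

#' Overlap NCC over a grid of integer shifts
#'
#' Computes, for every integer shift `(d_row, d_col)` within the given
#' bounds, the NCC between `ref` and `flt` shifted by that amount, scored
#' over the pixels where both (shifted) images are valid. Non-finite pixels
#' count as invalid, so rotated images with `NA` margins are handled
#' exactly. A positive shift means the float content sits down/right of the
#' reference content.
#'
#' @param ref,flt Equal-size numeric matrices (NAs allowed).
#' @param max_d_row,max_d_col Shift bounds in px.
#' @param min_frac Minimum overlap fraction for a shift to be scored.
#' @return List with `ncc` (a `(2 max_d_row + 1) x (2 max_d_col + 1)`
#'   matrix, NA where unscored), `d_rows`, `d_cols` (the lag axes).
#' @export
ncc_shift_map <- function(ref, flt, max_d_row, max_d_col, min_frac = 0.25) {
  stopifnot(identical(dim(ref), dim(flt)))
  m <- nrow(ref); n <- ncol(ref)
  stopifnot(max_d_row < m, max_d_col < n)
  MR <- is.finite(ref) * 1
  MF <- is.finite(flt) * 1
  R0 <- ifelse(is.finite(ref), ref, 0)
  F0 <- ifelse(is.finite(flt), flt, 0)
  pr <- next_fast_size(m + max_d_row)
  pc <- next_fast_size(n + max_d_col)
  tm <- xcorr_terms(list(MR, R0, R0^2), list(MF, F0, F0^2), pr, pc)
  xc <- function(ia, ib) Re(ifft2(tm$FA[[ia]] * tm$FB[[ib]]))
  n_ov <- xc(1, 1)
  s_f  <- xc(1, 2)
  s_f2 <- xc(1, 3)
  s_r  <- xc(2, 1)
  s_r2 <- xc(3, 1)
  s_rf <- xc(2, 2)
  d_rows <- seq.int(-max_d_row, max_d_row)
  d_cols <- seq.int(-max_d_col, max_d_col)
  ri <- lag_index(d_rows, pr)
  ci <- lag_index(d_cols, pc)
  take <- function(M) M[ri, ci, drop = FALSE]
  n_ov <- take(n_ov); s_f <- take(s_f); s_f2 <- take(s_f2)
  s_r <- take(s_r); s_r2 <- take(s_r2); s_rf <- take(s_rf)
  num <- s_rf - s_r * s_f / n_ov
  var_r <- s_r2 - s_r^2 / n_ov
  var_f <- s_f2 - s_f^2 / n_ov
  den2 <- var_r * var_f
  out <- num / sqrt(pmax(den2, 0))
  bad <- n_ov < pmax(min_frac * sum(MR), 16) | den2 <= 1e-12 * (s_r2 * s_f2 + 1e-300)
  out[bad] <- NA_real_
  out[out > 1] <- 1
  out[out < -1] <- -1
  list(ncc = out, d_rows = d_rows, d_cols = d_cols)
}

# deterministic argmax over an NCC map: best score, ties broken by smallest
# displacement magnitude, then row-major order; returns NULL if all NA
ncc_argmax <- function(map, tol = 1e-9) {
  v <- map$ncc
  if (all(is.na(v))) return(NULL)
  best <- max(v, na.rm = TRUE)
  cand <- which(!is.na(v) & v >= best - tol, arr.ind = TRUE)
  dr <- map$d_rows[cand[, 1]]
  dc <- map$d_cols[cand[, 2]]
  ord <- order(dr^2 + dc^2, cand[, 1], cand[, 2])
  i <- ord[1]
  list(d_row = dr[i], d_col = dc[i], peak = v[cand[i, 1], cand[i, 2]],
       idx = cand[i, , drop = TRUE])
}
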