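# Evaluation statistics: normalized RMSE between trajectories, ordinary
# least-squares regression with Pearson correlation, and Bland-Altman
# agreement (mean difference and 95% limits of agreement).

#' Normalized root-mean-square error
#'
#' RMSE of `estimate - reference`, normalized by a scale of the reference.
#' The default scale is the reference peak-to-peak range; the RMS value or
#' mean magnitude of the reference can be selected instead.
#'
#' @param estimate,reference Equal-length numeric vectors (length >= 2).
#' @param normalization One of `"range"` (default), `"rms"`, `"mean"`.
#' @return Nonnegative scalar.
#' @export
nrmse <- function(estimate, reference, normalization = c("range", "rms", "mean")) {
  normalization <- match.arg(normalization)
  stopifnot(length(estimate) == length(reference), length(reference) >= 2)
  scale <- switch(normalization,
                  range = diff(range(reference)),
                  rms = sqrt(mean(reference^2)),
                  mean = mean(abs(reference)))
  if (!is.finite(scale) || scale <= 0) {
    stop("degenerate reference: ", normalization, " scale is zero")
  }
  sqrt(mean((estimate - reference)^2)) / scale
}

#' Plain (unnormalized) RMSE
#' @param estimate,reference Equal-length numeric vectors.
#' @export
rmse <- function(estimate, reference) {
  stopifnot(length(estimate) == length(reference))
  sqrt(mean((estimate - reference)^2))
}

#' Ordinary least-squares regression and Pearson correlation
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; `x` must not be
#'   constant.
#' @return List with `slope`, `intercept`, `r`.
#' @export
regression_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("zero variance in x")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  syy <- sum((y - mean(y))^2)
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else 0
  list(slope = slope, intercept = intercept, r = r)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; reports the mean difference, the sample standard
#' deviation of the differences (n-1 denominator) and the 95% limits of
#' agreement `mean +/- 1.96 SD`.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return List with `mean_diff`, `sd_diff`, `lower`, `upper`, `means`,
#'   `diffs` (the per-sample means and differences, for plotting).
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       lower = m - 1.96 * s, upper = m + 1.96 * s,
       means = (a + b) / 2, diffs = d)
}

#' Full agreement report between two trajectories
#'
#' Convenience bundle of [regression_corr()], [bland_altman()] and [nrmse()]
#' for one pair of series (e.g. motion amplitude of an estimate vs the
#' disturbance-free reference).
#'
#' @param estimate,reference Equal-length numeric vectors.
#' @param normalization Passed to [nrmse()].
#' @return List with fields `mean_diff`, `sd_diff`, `lower`, `upper`,
#'   `slope`, `intercept`, `r`, `nrmse`.
#' @export
agreement_report <- function(estimate, reference, normalization = "range") {
  ba <- bland_altman(estimate, reference)
  rc <- regression_corr(reference, estimate)
  list(mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
       lower = ba$lower, upper = ba$upper,
       slope = rc$slope, intercept = rc$intercept, r = rc$r,
       nrmse = nrmse(estimate, reference, normalization))
}
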