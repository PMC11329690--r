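#' Weighted moment helpers
#'
#' Survey-weighted mean, population variance/SD, covariance, correlation and
#' quantiles used throughout the pipeline. All variances are population-style
#' (denominator \code{sum(w)}, not \code{sum(w) - 1}), matching the convention
#' used for standardization before the factor analysis.
#'
#' @param x,y numeric vectors.
#' @param w positive weights, recycled to \code{length(x)}.
#' @return A numeric scalar (or vector for \code{wtd_quantile}).
#' @keywords internal
#' @name weighted-moments
NULL

wtd_mean <- function(x, w) {
  sum(w * x) / sum(w)
}

wtd_var <- function(x, w) {
  m <- wtd_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

wtd_sd <- function(x, w) sqrt(wtd_var(x, w))

wtd_cov <- function(x, y, w) {
  mx <- wtd_mean(x, w)
  my <- wtd_mean(y, w)
  sum(w * (x - mx) * (y - my)) / sum(w)
}

wtd_cor <- function(x, y, w) {
  sx <- wtd_sd(x, w)
  sy <- wtd_sd(y, w)
  if (sx == 0 || sy == 0) return(NA_real_)
  wtd_cov(x, y, w) / (sx * sy)
}

# Weighted quantile of type "left-continuous CDF inverse": the smallest x with
# cumulative weight >= p * sum(w). With unit weights this reproduces the
# order-statistic quantile used for right-closed score bins (ties fall in the
# lower bin).
wtd_quantile <- function(x, w, probs) {
  ok <- is.finite(x) & is.finite(w)
  x <- x[ok]; w <- w[ok]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

check_weights <- function(w, n) {
  if (is.null(w)) w <- rep(1, n)
  w <- as.numeric(w)
  if (length(w) == 1L) w <- rep(w, n)
  if (length(w) != n) stop("weights must have length ", n)
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  w
}
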