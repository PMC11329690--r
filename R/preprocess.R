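#' Energy adjustment by the residual method
#'
#' Each analysis variable is regressed (weighted least squares, survey
#' weights) on total energy intake; the adjusted value is the regression
#' residual plus the value predicted at the weighted mean energy, so adjusted
#' variables keep their original units and typical magnitudes while being
#' uncorrelated with energy. The per-variable slope, intercept and the
#' reference energy are stored as attributes.
#'
#' @param X numeric matrix or data.frame of variables (persons in rows).
#' @param energy total energy intake vector, kJ/day, all positive.
#' @param weights survey weights (default unit weights).
#' @return A numeric matrix of class \code{"adjusted_matrix"} with attributes
#'   \code{slope}, \code{intercept}, \code{reference_energy}.
#' @export
energy_adjust_residual <- function(X, energy, weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(energy) != n) stop("energy must match rows of X")
  if (any(energy <= 0)) stop("energy must be > 0 for every person")
  w <- check_weights(weights, n)
  ve <- wtd_var(energy, w)
  if (ve < .Machine$double.eps) stop("zero-variance energy: regression undefined")
  me <- wtd_mean(energy, w)
  mx <- as.vector(crossprod(X, w)) / sum(w)
  b <- as.vector(crossprod(sweep(X, 2, mx), w * (energy - me))) / sum(w) / ve
  a <- mx - b * me
  # residual + prediction at mean energy; the latter equals the weighted mean
  adj <- X - outer(energy - me, b)
  attr(adj, "slope") <- stats::setNames(b, colnames(X))
  attr(adj, "intercept") <- stats::setNames(a, colnames(X))
  attr(adj, "reference_energy") <- me
  class(adj) <- c("adjusted_matrix", class(adj))
  adj
}

#' Scale variables to unit weighted standard deviation
#'
#' Divides each column by its survey-weighted population SD (denominator
#' \code{sum(w)}); values are not centered here - centering happens inside
#' the factor analysis. Scaling factors are stored in
#' \code{attr(, "scale")}.
#'
#' @param X numeric matrix (typically an energy-adjusted matrix).
#' @param weights survey weights.
#' @return The scaled matrix with attribute \code{scale}.
#' @export
scale_to_sd <- function(X, weights = NULL) {
  X <- as.matrix(X)
  w <- check_weights(weights, nrow(X))
  s <- apply(X, 2, wtd_sd, w = w)
  zero <- s < .Machine$double.eps
  if (any(zero))
    stop("zero weighted SD in column(s): ",
         paste(colnames(X)[zero] %||% which(zero), collapse = ", "))
  out <- sweep(unclass(X), 2, s, `/`)
  attr(out, "scale") <- stats::setNames(s, colnames(X))
  out
}
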