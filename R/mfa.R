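#' Weighted multiple factor analysis
#'
#' Multiple factor analysis of several groups of active variables with
#' row (survey) weights as masses. The procedure follows the definition of
#' the method: (1) for each active group, a weighted PCA of the centered
#' group submatrix yields the group's first eigenvalue; (2) every column of
#' the group is rescaled by one over the square root of that eigenvalue, so
#' no single group can dominate the first global axis (each group's
#' contribution to the first-axis inertia is at most one); (3) a weighted PCA
#' of the concatenated rescaled matrix gives the global axes, person scores
#' and eigenvalues. Supplementary quantitative and categorical variables can
#' be projected onto the fitted axes afterwards without influencing them.
#'
#' Eigenvector signs are fixed deterministically: each dimension is oriented
#' so its largest-magnitude active loading is positive.
#'
#' @param X numeric matrix of active variables (persons x variables),
#'   already scaled to unit weighted SD (see \code{\link{scale_to_sd}}).
#' @param groups named list of character vectors partitioning
#'   \code{colnames(X)} into active variable groups.
#' @param weights survey weights (need not be normalised).
#' @param ndim number of dimensions to retain for scores (default 5).
#' @return An object of class \code{"mfa"}: \code{eigenvalues} (all, with
#'   \code{percent}), \code{group_lambda1}, \code{scores} (n x ndim),
#'   \code{var_cor} (weighted correlation of each active variable with each
#'   retained dimension), \code{loadings}, \code{group_contrib} (per-group
#'   inertia contribution per axis), \code{weights} (normalised to sum 1),
#'   \code{total_inertia}, and the centering/rescaling needed to project new
#'   data.
#' @export
mfa <- function(X, groups, weights = NULL, ndim = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) stop("X must have column names")
  all_cols <- unlist(groups)
  if (anyDuplicated(all_cols)) stop("active groups must be disjoint")
  if (!all(all_cols %in% colnames(X)))
    stop("group columns missing from X: ",
         paste(setdiff(all_cols, colnames(X)), collapse = ", "))
  X <- X[, all_cols, drop = FALSE]
  w <- check_weights(weights, n)
  w <- w / sum(w)

  ctr <- as.vector(crossprod(X, w))
  Xc <- sweep(X, 2, ctr)

  group_of <- rep(names(groups), lengths(groups))
  lambda1 <- vapply(names(groups), function(g) {
    Xg <- Xc[, groups[[g]], drop = FALSE]
    ev <- eigen(crossprod(Xg, Xg * w), symmetric = TRUE, only.values = TRUE)$values
    ev[1]
  }, numeric(1))
  if (any(lambda1 < .Machine$double.eps))
    stop("active group with zero first eigenvalue: ",
         paste(names(groups)[lambda1 < .Machine$double.eps], collapse = ", "))

  col_scale <- 1 / sqrt(lambda1[group_of])
  Z <- sweep(Xc, 2, col_scale, `*`)

  C <- crossprod(Z, Z * w)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  ndim <- min(ndim, sum(ev > 1e-12))
  V <- eig$vectors[, seq_len(ndim), drop = FALSE]

  # deterministic orientation: largest-|loading| variable positive per axis
  for (d in seq_len(ndim)) {
    i <- which.max(abs(V[, d]))
    if (V[i, d] < 0) V[, d] <- -V[, d]
  }
  rownames(V) <- colnames(Z)
  scores <- Z %*% V
  colnames(scores) <- paste0("dim", seq_len(ndim))

  var_cor <- vapply(seq_len(ndim), function(d)
    vapply(seq_len(ncol(Xc)), function(j) wtd_cor(Xc[, j], scores[, d], w),
           numeric(1)), numeric(ncol(Xc)))
  var_cor <- matrix(var_cor, nrow = ncol(Xc), ncol = ndim,
                    dimnames = list(colnames(Xc), colnames(scores)))

  group_contrib <- rowsum(V^2, group_of)
  colnames(group_contrib) <- colnames(scores)

  res <- list(
    eigenvalues = data.frame(dim = seq_along(ev), eigenvalue = ev,
                             percent = 100 * ev / sum(ev)),
    group_lambda1 = lambda1,
    scores = scores,
    loadings = V,
    var_cor = var_cor,
    group_contrib = group_contrib,
    groups = groups,
    center = ctr,
    col_scale = col_scale,
    weights = w,
    ndim = ndim,
    total_inertia = sum(diag(C))
  )
  class(res) <- "mfa"
  res
}

#' @export
print.mfa <- function(x, ...) {
  cat("Weighted multiple factor analysis\n")
  cat("  active groups:", paste(sprintf("%s (%d vars, lambda1 = %.3f)",
                                        names(x$groups), lengths(x$groups),
                                        x$group_lambda1), collapse = ", "), "\n")
  top <- utils::head(x$eigenvalues, x$ndim)
  cat("  retained dimensions:", x$ndim, "\n")
  cat(sprintf("  dim %d: eigenvalue %.4f (%.1f%% of inertia)\n",
              top$dim, top$eigenvalue, top$percent), sep = "")
  invisible(x)
}

#' @export
summary.mfa <- function(object, ...) {
  print(object)
  cat("\nVariable-dimension correlations (strongest on dim 1):\n")
  o <- order(-abs(object$var_cor[, 1]))
  print(round(object$var_cor[utils::head(o, 10), , drop = FALSE], 3))
  invisible(object)
}

#' @export
plot.mfa <- function(x, dims = c(1, 2), ...) {
  if (x$ndim < 2) stop("need at least two retained dimensions to plot")
  cc <- x$var_cor[, dims]
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 xlab = sprintf("dim %d (%.1f%%)", dims[1],
                                x$eigenvalues$percent[dims[1]]),
                 ylab = sprintf("dim %d (%.1f%%)", dims[2],
                                x$eigenvalues$percent[dims[2]]),
                 main = "Correlation circle")
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
  graphics::arrows(0, 0, cc[, 1], cc[, 2], length = 0.05, col = "grey40")
  graphics::text(cc[, 1], cc[, 2], rownames(cc), cex = 0.6)
  invisible(x)
}

#' Project supplementary variables onto fitted MFA axes
#'
#' Quantitative supplementary variables are summarised by their weighted
#' correlation with each retained dimension's scores. Categorical variables
#' get, per category and dimension, the weighted mean score (the category
#' coordinate) and a v-test comparing it with the overall mean of zero under
#' the random-sampling null.
#'
#' @param object a fitted \code{\link{mfa}}.
#' @param sup_quant data.frame/matrix of quantitative supplementary
#'   variables (rows aligned with the fitted data), or \code{NULL}.
#' @param sup_cat data.frame of categorical supplementary variables, or
#'   \code{NULL}.
#' @return list with \code{quant} (variable x dimension correlation matrix)
#'   and \code{cat} (data.frame: variable, category, weighted size, per-dim
#'   coordinate and v-test).
#' @export
project_supplementary <- function(object, sup_quant = NULL, sup_cat = NULL) {
  stopifnot(inherits(object, "mfa"))
  w <- object$weights
  S <- object$scores
  out <- list()
  if (!is.null(sup_quant)) {
    Q <- as.matrix(sup_quant)
    qc <- vapply(seq_len(ncol(S)), function(d)
      vapply(seq_len(ncol(Q)), function(j) wtd_cor(Q[, j], S[, d], w),
             numeric(1)), numeric(ncol(Q)))
    out$quant <- matrix(qc, nrow = ncol(Q), ncol = ncol(S),
                        dimnames = list(colnames(Q), colnames(S)))
  }
  if (!is.null(sup_cat)) {
    N <- sum(w)  # = 1 after normalisation; use effective counts on mean-1 scale
    wt <- w / mean(w)
    Ne <- sum(wt)
    lam <- object$eigenvalues$eigenvalue[seq_len(object$ndim)]
    rows <- list()
    for (v in names(sup_cat)) {
      f <- as.character(sup_cat[[v]])
      for (lev in sort(unique(f))) {
        sel <- f == lev & f != "missing"
        nj <- sum(wt[sel])
        if (nj <= 0) {
          warning("category with zero weight skipped: ", v, "=", lev)
          next
        }
        coord <- as.vector(crossprod(S[sel, , drop = FALSE], w[sel])) / sum(w[sel])
        se <- sqrt((lam / nj) * (Ne - nj) / (Ne - 1))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, category = lev, n_w = nj,
          t(stats::setNames(coord, paste0("coord_dim", seq_along(coord)))),
          t(stats::setNames(coord / se, paste0("v_dim", seq_along(coord)))),
          stringsAsFactors = FALSE)
      }
    }
    out$cat <- do.call(rbind, rows)
  }
  out
}
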