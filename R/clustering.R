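#' Ward hierarchical clustering with survey-weight masses
#'
#' Agglomerative hierarchical clustering of persons in factor-score space
#' using Ward's minimum-variance criterion with the survey weights as
#' masses. The pairwise dissimilarity fed to the Lance-Williams recurrence is
#' the Ward cost of merging two singletons,
#' \code{w_i w_j / (w_i + w_j) * ||x_i - x_j||^2}, so every merge height is
#' the increase in within-cluster inertia caused by that merge and the
#' heights of all merges sum to the total inertia of the cloud.
#'
#' @param scores numeric matrix (persons x retained dimensions).
#' @param weights survey weights used as masses (default unit).
#' @return An \code{hclust} object (heights are inertia gains) with the
#'   weights stored in \code{attr(, "weights")}.
#' @export
ward_tree <- function(scores, weights = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2) stop("need at least two persons")
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores contain NaN/Inf")
  w <- check_weights(weights, n)
  d2 <- as.matrix(stats::dist(scores))^2
  ww <- outer(w, w) / outer(w, w, `+`)
  hc <- stats::hclust(stats::as.dist(ww * d2), method = "ward.D", members = w)
  attr(hc, "weights") <- w
  hc
}

#' Suggest a cluster count from the inertia-gain curve
#'
#' The between-cluster inertia gained when moving from \code{k - 1} to
#' \code{k} clusters is the height of the merge undone by that split. The
#' suggested \code{k} maximises the ratio of successive gains
#' \code{gain(k) / gain(k + 1)} (the elbow criterion); the full gain curve is
#' returned so the final choice can be overridden on interpretability
#' grounds. When the largest ratio is below 1.5 the curve is flagged as a
#' weak elbow.
#'
#' @param tree an \code{hclust} from \code{\link{ward_tree}}.
#' @param k_range integer candidates, all within \code{[2, n - 1]}.
#' @return list: \code{k} (suggested), \code{gains} (data.frame k, gain,
#'   ratio), \code{weak_elbow}.
#' @export
suggest_k <- function(tree, k_range = 2:8) {
  n <- length(tree$order)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n - 1]")
  h <- tree$height                       # ascending; h[m] merges n-m+1 -> n-m clusters
  gain <- function(k) h[n - k + 1]       # inertia gained splitting k-1 -> k
  ks <- sort(unique(as.integer(k_range)))
  g <- vapply(ks, gain, numeric(1))
  g_next <- vapply(ks + 1L, gain, numeric(1))
  ratio <- g / pmax(g_next, .Machine$double.eps)
  best <- ks[which.max(ratio)]
  # a convincing elbow stands well above the typical successive-gain ratio;
  # near-flat curves (max close to the median) are flagged
  weak <- max(ratio) < 2 * stats::median(ratio)
  list(k = best,
       gains = data.frame(k = ks, gain = g, ratio = ratio),
       weak_elbow = weak)
}

within_inertia <- function(scores, labels, w) {
  tot <- 0
  for (k in unique(labels)) {
    sel <- labels == k
    c_k <- as.vector(crossprod(scores[sel, , drop = FALSE], w[sel])) / sum(w[sel])
    tot <- tot + sum(w[sel] * rowSums(sweep(scores[sel, , drop = FALSE], 2, c_k)^2))
  }
  tot
}

weighted_centroids <- function(scores, labels, w, k) {
  cent <- matrix(0, k, ncol(scores))
  for (j in seq_len(k)) {
    sel <- labels == j
    cent[j, ] <- as.vector(crossprod(scores[sel, , drop = FALSE], w[sel])) /
      sum(w[sel])
  }
  cent
}

#' Cut the tree and consolidate with weighted k-means
#'
#' Cuts the hierarchy at \code{k} clusters, then runs a weighted k-means
#' (Lloyd) refinement initialised at the hierarchical cluster centroids, at
#' most \code{max_iter} iterations. Consolidation can only decrease the
#' within-cluster inertia. A cluster emptied during refinement is re-seeded
#' with the point nearest its previous centroid (with a warning).
#'
#' @param tree \code{hclust} from \code{\link{ward_tree}}.
#' @param k number of clusters, \code{2 <= k <= n}.
#' @param scores the score matrix the tree was built on.
#' @param weights the same weights used for the tree.
#' @param max_iter maximum k-means iterations (default 10).
#' @return Object of class \code{"cluster_solution"}: \code{labels}
#'   (consolidated), \code{labels_tree} (before consolidation), \code{k},
#'   \code{centroids}, weighted \code{sizes} and \code{shares},
#'   \code{within_inertia}, \code{within_inertia_tree},
#'   \code{between_inertia}, \code{total_inertia}, \code{reassigned} (count
#'   of label changes), and the \code{tree}.
#' @export
cut_and_consolidate <- function(tree, k, scores, weights = NULL, max_iter = 10) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k < 2 || k > n) stop("k must be in [2, n]")
  w <- attr(tree, "weights") %||% check_weights(weights, n)
  labels0 <- stats::cutree(tree, k)
  wi0 <- within_inertia(scores, labels0, w)

  labels <- labels0
  cent <- weighted_centroids(scores, labels, w, k)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(scores^2), rep(1, k)) - 2 * scores %*% t(cent) +
      outer(rep(1, n), rowSums(cent^2))
    new_labels <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        warning("cluster ", j, " emptied during consolidation; re-seeding with nearest point")
        cand <- which.min(ifelse(seq_len(n) %in% which(new_labels == j), Inf, d2[, j]))
        new_labels[cand] <- j
      }
    }
    if (all(new_labels == labels) && it > 1) break
    changed <- !all(new_labels == labels)
    labels <- new_labels
    cent <- weighted_centroids(scores, labels, w, k)
    if (!changed) break
  }

  wi <- within_inertia(scores, labels, w)
  gc_all <- as.vector(crossprod(scores, w)) / sum(w)
  tot <- sum(w * rowSums(sweep(scores, 2, gc_all)^2))
  sizes <- vapply(seq_len(k), function(j) sum(w[labels == j]), numeric(1))
  res <- list(labels = labels, labels_tree = labels0, k = k,
              centroids = cent, sizes = sizes, shares = sizes / sum(w),
              within_inertia = wi, within_inertia_tree = wi0,
              between_inertia = tot - wi, total_inertia = tot,
              reassigned = sum(labels != labels0), tree = tree)
  class(res) <- "cluster_solution"
  res
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Diet cluster solution: k =", x$k, "\n")
  cat(sprintf("  cluster %d: weighted share %.1f%%\n",
              seq_len(x$k), 100 * x$shares), sep = "")
  cat(sprintf("  within-inertia %.4f (tree cut %.4f, %d persons reassigned)\n",
              x$within_inertia, x$within_inertia_tree, x$reassigned))
  cat(sprintf("  between/total inertia: %.1f%%\n",
              100 * x$between_inertia / x$total_inertia))
  invisible(x)
}

#' @export
plot.cluster_solution <- function(x, ...) {
  graphics::plot(x$tree, labels = FALSE, main = "Ward tree (inertia-gain heights)",
                 xlab = "", sub = "", ...)
  stats::rect.hclust(x$tree, k = x$k)
  invisible(x)
}

#' One-call clustering of MFA scores
#'
#' Convenience wrapper: builds the Ward tree, suggests \code{k} from the
#' inertia-gain curve when not supplied, and consolidates with weighted
#' k-means. The final \code{k} remains a user decision; the suggestion is
#' advisory.
#'
#' @param scores person x dimension score matrix (e.g. \code{mfa()$scores}).
#' @param weights survey weights.
#' @param k cluster count; \code{NULL} to use the suggestion.
#' @param k_range candidates for the suggestion.
#' @return A \code{cluster_solution} with the suggestion attached as
#'   \code{$suggestion}.
#' @export
diet_clusters <- function(scores, weights = NULL, k = NULL, k_range = 2:8) {
  tree <- ward_tree(scores, weights)
  sug <- suggest_k(tree, k_range)
  sol <- cut_and_consolidate(tree, k %||% sug$k, scores,
                             attr(tree, "weights"))
  sol$suggestion <- sug
  sol
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same persons,
#' from the contingency-table closed form: 1 for identical partitions (up to
#' label permutation), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
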