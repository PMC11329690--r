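#' Cluster characterization statistics
#'
#' v-tests compare a cluster's mean (or a category's frequency inside the
#' cluster) with the whole-sample value under the null that the cluster is a
#' random sample of its size drawn without replacement; |v| > 1.96
#' corresponds to the 5% two-sided level. Post-hoc comparisons between
#' clusters use the non-parametric Kruskal-Wallis test followed by Dunn's
#' pairwise z tests; Levene and Shapiro-Wilk diagnostics document why the
#' parametric alternatives are not used. Non-ordinal categorical variables
#' are compared by an omnibus chi-square followed by Marascuilo-style
#' pairwise proportion comparisons with Bonferroni-adjusted critical values.
#'
#' @name characterize
NULL

#' Quantitative v-test per cluster
#'
#' \code{v_k = (xbar_k - xbar) / sqrt((s2 / n_k) * (N - n_k) / (N - 1))}
#' with \code{s2} the weighted population variance, \code{n_k} the weighted
#' cluster size and \code{N} the weighted total; weights are normalised to
#' mean one so weighted and unweighted totals coincide.
#'
#' @param x numeric variable.
#' @param labels cluster labels.
#' @param weights survey weights.
#' @param alpha two-sided significance level (default 0.05).
#' @return data.frame: cluster, cluster_mean, sample_mean, v, significant.
#' @export
vtest_quant <- function(x, labels, weights = NULL, alpha = 0.05) {
  n <- length(x)
  w <- check_weights(weights, n)
  w <- w / mean(w)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("v-test undefined with a single cluster")
  N <- sum(w)
  m <- wtd_mean(x, w)
  s2 <- wtd_var(x, w)
  zc <- stats::qnorm(1 - alpha / 2)
  out <- lapply(ks, function(k) {
    sel <- labels == k
    nk <- sum(w[sel])
    mk <- wtd_mean(x[sel], w[sel])
    v <- (mk - m) / sqrt((s2 / nk) * (N - nk) / (N - 1))
    data.frame(cluster = k, cluster_mean = mk, sample_mean = m, v = v,
               significant = abs(v) > zc)
  })
  do.call(rbind, out)
}

#' Categorical v-test per cluster and category
#'
#' Normal approximation of the hypergeometric null:
#' \code{v = (n_kj - n_k n_j / N) / sqrt(n_k (n_j/N)(1 - n_j/N)(N - n_k)/(N - 1))}
#' with weighted counts (weights normalised to mean one).
#'
#' @param category factor/character vector; the level \code{"missing"} is
#'   excluded.
#' @inheritParams vtest_quant
#' @return data.frame: cluster, category, cluster_prop, sample_prop, v,
#'   significant.
#' @export
vtest_cat <- function(category, labels, weights = NULL, alpha = 0.05) {
  category <- as.character(category)
  keep <- category != "missing"
  category <- category[keep]
  labels <- labels[keep]
  w <- check_weights(weights, length(keep))[keep]
  w <- w / mean(w)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("v-test undefined with a single cluster")
  N <- sum(w)
  zc <- stats::qnorm(1 - alpha / 2)
  rows <- list()
  for (lev in sort(unique(category))) {
    nj <- sum(w[category == lev])
    if (nj <= 0 || nj >= N) next  # degenerate category, skipped
    pj <- nj / N
    for (k in ks) {
      sel <- labels == k
      nk <- sum(w[sel])
      nkj <- sum(w[sel & category == lev])
      v <- (nkj - nk * pj) / sqrt(nk * pj * (1 - pj) * (N - nk) / (N - 1))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, category = lev, cluster_prop = nkj / nk,
        sample_prop = pj, v = v, significant = abs(v) > zc)
    }
  }
  do.call(rbind, rows)
}

#' Kruskal-Wallis omnibus test with Dunn pairwise post-hoc
#'
#' The omnibus H statistic (tie-corrected) comes from
#' \code{stats::kruskal.test}. Dunn's pairwise z is
#' \code{(Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))}
#' with \code{T = sum(t^3 - t)} over tie groups; two-sided p-values are
#' adjusted for the number of pairs (Bonferroni by default).
#'
#' @param x numeric variable (post-hoc tests run unweighted on raw values).
#' @param labels cluster labels.
#' @param p_adjust \code{"bonferroni"}, \code{"holm"} or \code{"none"}.
#' @param alpha significance level for the per-pair decision.
#' @return list: \code{kw} (statistic, df, p.value), \code{dunn}
#'   (data.frame pair i/j, z, p, p_adj, significant).
#' @export
kruskal_dunn <- function(x, labels, p_adjust = c("bonferroni", "holm", "none"),
                         alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least two clusters")
  N <- length(x)
  if (length(unique(x)) == 1L) {
    kw <- list(statistic = 0, parameter = nlevels(labels) - 1, p.value = 1)
  } else {
    kt <- stats::kruskal.test(x, labels)
    kw <- list(statistic = unname(kt$statistic), parameter = unname(kt$parameter),
               p.value = kt$p.value)
  }
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  var_term <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  ks <- levels(labels)
  pairs <- utils::combn(ks, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ni <- sum(labels == i); nj <- sum(labels == j)
    z <- if (var_term <= 0) 0 else
      (mean(r[labels == i]) - mean(r[labels == j])) /
        sqrt(var_term * (1 / ni + 1 / nj))
    data.frame(cluster_i = i, cluster_j = j, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  dunn <- do.call(rbind, rows)
  dunn$p_adj <- pmin(1, stats::p.adjust(dunn$p, method = if (p_adjust == "none") "none" else p_adjust))
  dunn$significant <- dunn$p_adj < alpha
  list(kw = kw, dunn = dunn)
}

#' Variance and normality diagnostics per cluster
#'
#' Levene's test (mean-centered, via \code{car::leveneTest}) for
#' heteroscedasticity across clusters and Shapiro-Wilk per cluster for
#' non-normality. These diagnostics justify the non-parametric post-hoc
#' path; clusters with fewer than 3 observations (or constant values) are
#' skipped for Shapiro-Wilk.
#'
#' @param x numeric variable.
#' @param labels cluster labels.
#' @return list: \code{levene} (F, df, p), \code{shapiro} (data.frame
#'   cluster, W, p; skipped clusters absent).
#' @export
variance_normality_diag <- function(x, labels) {
  labels <- as.factor(labels)
  lev <- car::leveneTest(x, labels, center = mean)
  rows <- list()
  for (k in levels(labels)) {
    xi <- x[labels == k]
    if (length(xi) < 3 || length(unique(xi)) == 1L) next
    if (length(xi) > 5000) xi <- xi[seq(1, length(xi), length.out = 5000)]
    sw <- stats::shapiro.test(xi)
    rows[[k]] <- data.frame(cluster = k, W = unname(sw$statistic),
                            p = sw$p.value)
  }
  list(levene = list(F = lev$`F value`[1], df = c(lev$Df), p = lev$`Pr(>F)`[1]),
       shapiro = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Pairwise proportion comparisons for a categorical variable
#'
#' Runs the omnibus chi-square test of independence on the cluster x
#' category table; when significant, compares for every cluster pair the
#' maximum absolute difference in category proportions against the
#' Marascuilo-style critical value
#' \code{sqrt(qchisq(1 - alpha/m, df)) * sqrt(p_i(1-p_i)/n_i + p_j(1-p_j)/n_j)}
#' where \code{m} is the number of pairs (Bonferroni correction).
#'
#' @param category factor/character vector (>= 2 levels).
#' @param labels cluster labels (>= 2 clusters).
#' @param alpha significance level.
#' @return list: \code{omnibus} (statistic, df, p, expected_ok),
#'   \code{pairs} (data.frame with the max difference, its category, the
#'   critical value and the decision; NULL when the omnibus is not
#'   significant).
#' @export
chisq_pairwise_props <- function(category, labels, alpha = 0.05) {
  category <- as.factor(category)
  labels <- as.factor(labels)
  if (nlevels(category) < 2 || nlevels(labels) < 2)
    stop("need >= 2 categories and >= 2 clusters")
  tab <- table(labels, category)
  suppressWarnings(ct <- stats::chisq.test(tab))
  omnibus <- list(statistic = unname(ct$statistic),
                  df = unname(ct$parameter), p = ct$p.value,
                  expected_ok = all(ct$expected >= 1))
  if (!omnibus$expected_ok)
    warning("omnibus chi-square has expected cell counts below 1")
  if (omnibus$p >= alpha)
    return(list(omnibus = omnibus, pairs = NULL))
  props <- prop.table(tab, 1)
  ns <- rowSums(tab)
  ks <- levels(labels)
  pr <- utils::combn(ks, 2)
  m <- ncol(pr)
  df <- ct$parameter
  rows <- lapply(seq_len(m), function(p) {
    i <- pr[1, p]; j <- pr[2, p]
    diffs <- abs(props[i, ] - props[j, ])
    cat_max <- names(which.max(diffs))
    crit <- sqrt(stats::qchisq(1 - alpha / m, df)) *
      sqrt(props[i, cat_max] * (1 - props[i, cat_max]) / ns[i] +
             props[j, cat_max] * (1 - props[j, cat_max]) / ns[j])
    data.frame(cluster_i = i, cluster_j = j, category = cat_max,
               max_diff = unname(max(diffs)), critical = unname(crit),
               significant = max(diffs) > crit)
  })
  list(omnibus = omnibus, pairs = do.call(rbind, rows))
}
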