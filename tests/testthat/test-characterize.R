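test_that("quantitative v-test matches the hand-computed oracle", {
  x <- c(0, 0, 10, 10)
  labels <- c(1, 1, 2, 2)
  got <- vtest_quant(x, labels)
  # cluster 2: (10 - 5) / sqrt((25/2) * (4-2)/(4-1)) = 5/sqrt(25/3) = sqrt(3)
  expect_equal(got$v[got$cluster == 2], sqrt(3), tolerance = 1e-9)
  expect_equal(got$v[got$cluster == 1], -sqrt(3), tolerance = 1e-9)
})

test_that("v is zero when the cluster mean equals the sample mean", {
  x <- c(1, 3, 1, 3)
  got <- vtest_quant(x, c(1, 1, 2, 2))
  expect_equal(got$v, c(0, 0), tolerance = 1e-12)
  expect_error(vtest_quant(x, rep(1, 4)), "single cluster")
})

test_that("duplicating the data scales |v| by about sqrt(2)", {
  set.seed(1)
  x <- rnorm(40)
  labels <- rep(1:2, each = 20)
  v1 <- vtest_quant(x, labels)$v[1]
  v2 <- vtest_quant(c(x, x), c(labels, labels))$v[1]
  # exact formula consequence: ratio = sqrt(2 * ((N-n_k)/(N-1)) / ((2N-2n_k)/(2N-1)))
  expect_equal(v2 / v1, sqrt(79 / 39), tolerance = 1e-9)
  expect_gt(abs(v2), abs(v1))
})

test_that("categorical v-test matches the hand-computed hypergeometric value", {
  # N = 10, n_k = 5, n_j = 4, n_kj = 4 -> v = 2 / 0.8165 = 2.449
  category <- c(rep("yes", 4), "no", rep("no", 5))
  labels <- c(rep(1, 5), rep(2, 5))
  got <- vtest_cat(category, labels)
  v <- got$v[got$cluster == 1 & got$category == "yes"]
  expect_equal(v, 2 / sqrt(5 * 0.4 * 0.6 * 5 / 9), tolerance = 1e-9)
  # complement category has equal magnitude and opposite sign
  v_no <- got$v[got$cluster == 1 & got$category == "no"]
  expect_equal(v_no, -v, tolerance = 1e-9)
})

test_that("identically distributed categories give v = 0 everywhere", {
  category <- rep(c("a", "b"), 10)
  labels <- rep(1:2, each = 10)
  got <- vtest_cat(category, labels)
  expect_true(all(abs(got$v) < 1e-12))
})

test_that("Kruskal-Wallis/Dunn agree with a brute-force rank oracle", {
  x <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  labels <- rep(1:3, each = 3)
  got <- kruskal_dunn(x, labels)
  expect_equal(got$kw$statistic, kruskal.test(x, factor(labels))$statistic,
               ignore_attr = TRUE)
  # oracle: direct mean-rank computation, no ties
  r <- rank(x)
  N <- 9
  for (i in seq_len(nrow(got$dunn))) {
    gi <- got$dunn$cluster_i[i]; gj <- got$dunn$cluster_j[i]
    z_oracle <- (mean(r[labels == gi]) - mean(r[labels == gj])) /
      sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 3))
    expect_equal(got$dunn$z[i], z_oracle, tolerance = 1e-12)
  }
  # fully separated extreme pair is significant after Bonferroni
  expect_true(got$dunn$significant[got$dunn$cluster_i == 1 &
                                     got$dunn$cluster_j == 3])
})

test_that("Dunn handles ties through the tie-corrected variance", {
  set.seed(2)
  x <- sample(1:5, 30, replace = TRUE)   # many ties
  labels <- rep(1:3, each = 10)
  got <- kruskal_dunn(x, labels)
  r <- rank(x)
  ties <- table(x)
  var_term <- 30 * 31 / 12 - sum(ties^3 - ties) / (12 * 29)
  z_oracle <- (mean(r[labels == 1]) - mean(r[labels == 2])) /
    sqrt(var_term * (1 / 10 + 1 / 10))
  expect_equal(got$dunn$z[1], z_oracle, tolerance = 1e-12)
})

test_that("identical values give H = 0 with p = 1 and no significant pairs", {
  got <- kruskal_dunn(rep(5, 12), rep(1:3, each = 4))
  expect_equal(got$kw$statistic, 0)
  expect_equal(got$kw$p.value, 1)
  expect_false(any(got$dunn$significant))
})

test_that("H is invariant under label permutation", {
  set.seed(3)
  x <- rnorm(30)
  labels <- rep(1:3, 10)
  h1 <- kruskal_dunn(x, labels)$kw$statistic
  perm <- c(2, 3, 1)[labels]
  h2 <- kruskal_dunn(x, perm)$kw$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("Bonferroni decisions are never more liberal than unadjusted", {
  set.seed(4)
  x <- c(rnorm(15), rnorm(15, 1), rnorm(15, 2))
  labels <- rep(1:3, each = 15)
  adj <- kruskal_dunn(x, labels, p_adjust = "bonferroni")$dunn
  raw <- kruskal_dunn(x, labels, p_adjust = "none")$dunn
  expect_true(all(adj$p_adj >= raw$p_adj - 1e-15))
  expect_true(all(!adj$significant | raw$significant))
})

test_that("Levene detects a tenfold SD difference at n = 200", {
  set.seed(5)
  x <- c(rnorm(100, sd = 1), rnorm(100, sd = 10))
  labels <- rep(1:2, each = 100)
  d <- variance_normality_diag(x, labels)
  expect_lt(d$levene$p, 0.001)
})

test_that("Shapiro-Wilk is skipped for tiny or constant clusters", {
  x <- c(rnorm(20), rep(1, 5), rnorm(2))
  labels <- c(rep(1, 20), rep(2, 5), rep(3, 2))
  d <- variance_normality_diag(x, labels)
  expect_identical(d$shapiro$cluster, "1")
})

test_that("pairwise proportion comparisons follow the Marascuilo rule", {
  # 2 clusters, proportions 0.9 vs 0.1, n = 100 each -> clearly significant
  category <- c(rep("a", 90), rep("b", 10), rep("a", 10), rep("b", 90))
  labels <- rep(1:2, each = 100)
  got <- chisq_pairwise_props(category, labels)
  expect_lt(got$omnibus$p, 1e-10)
  expect_true(got$pairs$significant[1])
  expect_equal(got$pairs$max_diff[1], 0.8, tolerance = 1e-12)
  # hand-computed critical value: m = 1 pair, df = 1
  crit <- sqrt(qchisq(0.95, 1)) * sqrt(0.9 * 0.1 / 100 + 0.1 * 0.9 / 100)
  expect_equal(got$pairs$critical[1], crit, tolerance = 1e-9)
})

test_that("identical proportions stop at a non-significant omnibus", {
  category <- rep(c("a", "b"), 50)
  labels <- rep(1:2, each = 50)
  got <- chisq_pairwise_props(category, labels)
  expect_gt(got$omnibus$p, 0.05)
  expect_null(got$pairs)
})

test_that("v-test agrees with a permutation z-score on small samples", {
  set.seed(6)
  n <- 50
  x <- rlnorm(n)
  labels <- sample(rep(1:2, c(20, 30)))
  v <- vtest_quant(x, labels)$v[1]
  perm <- replicate(4000, {
    l <- sample(labels)
    mean(x[l == 1])
  })
  z_perm <- (mean(x[labels == 1]) - mean(perm)) / sd(perm)
  expect_lt(abs(v - z_perm), 0.25)
})
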