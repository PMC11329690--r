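std_matrix <- function(n, p, w, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", seq_len(p))))
  scale_to_sd(X, w)
}

test_that("a single one-variable group yields one dimension with all variance", {
  w <- runif(30, 0.5, 2)
  X <- std_matrix(30, 1, w)
  f <- mfa(X, groups = list(g = "v1"), weights = w, ndim = 3)
  expect_equal(f$eigenvalues$percent[1], 100, tolerance = 1e-9)
  expect_equal(f$ndim, 1L)
})

test_that("two duplicated one-variable groups give first eigenvalue = number of groups", {
  w <- runif(50, 0.5, 2)
  x <- std_matrix(50, 1, w, seed = 3)
  X <- cbind(a1 = x[, 1], b1 = x[, 1])
  f <- mfa(X, groups = list(g1 = "a1", g2 = "b1"), weights = w, ndim = 2)
  expect_equal(unname(f$group_lambda1), c(1, 1), tolerance = 1e-9)
  expect_equal(f$eigenvalues$eigenvalue[1], 2, tolerance = 1e-9)
  expect_equal(f$eigenvalues$percent[1], 100, tolerance = 1e-9)
})

test_that("single-group MFA equals an independent weighted PCA up to sign/scale", {
  n <- 200; p <- 10
  w <- runif(n, 0.5, 2)
  X <- std_matrix(n, p, w, seed = 4)
  f <- mfa(X, groups = list(all = colnames(X)), weights = w, ndim = 4)
  # independent oracle: direct eigen-decomposition of the weighted covariance
  wn <- w / sum(w)
  Xc <- sweep(X, 2, colSums(X * wn))
  e <- eigen(crossprod(Xc, Xc * wn), symmetric = TRUE)
  oracle_scores <- Xc %*% e$vectors
  for (d in 1:4) {
    r <- cor(f$scores[, d], oracle_scores[, d])
    expect_equal(abs(r), 1, tolerance = 1e-9)
    # eigenvalues proportional through the 1/lambda1 group rescaling
    expect_equal(f$eigenvalues$eigenvalue[d] * f$group_lambda1[[1]],
                 e$values[d], tolerance = 1e-9)
  }
})

test_that("eigenvalue sum reconstructs total inertia and percentages sum to 100", {
  n <- 120
  w <- runif(n, 0.5, 2)
  X <- std_matrix(n, 8, w, seed = 5)
  f <- mfa(X, groups = list(g1 = paste0("v", 1:5), g2 = paste0("v", 6:8)),
           weights = w, ndim = 5)
  expect_equal(sum(f$eigenvalues$eigenvalue), f$total_inertia,
               tolerance = 1e-9)
  expect_equal(sum(f$eigenvalues$percent), 100, tolerance = 1e-9)
  expect_true(all(diff(f$eigenvalues$eigenvalue) <= 1e-12))
})

test_that("no active group contributes more than 1 to the first-axis inertia", {
  for (seed in 1:3) {
    w <- runif(150, 0.5, 2)
    X <- std_matrix(150, 12, w, seed = seed)
    f <- mfa(X, groups = list(g1 = paste0("v", 1:7), g2 = paste0("v", 8:12)),
             weights = w, ndim = 3)
    contrib_dim1 <- f$group_contrib[, 1] * f$eigenvalues$eigenvalue[1]
    expect_true(all(contrib_dim1 <= 1 + 1e-9))
  }
})

test_that("results are deterministic across repeated fits", {
  w <- runif(80, 0.5, 2)
  X <- std_matrix(80, 6, w, seed = 7)
  f1 <- mfa(X, groups = list(g = colnames(X)), weights = w)
  f2 <- mfa(X, groups = list(g = colnames(X)), weights = w)
  expect_identical(f1$scores, f2$scores)
  # sign convention: the largest-|loading| variable loads positively
  for (d in seq_len(f1$ndim)) {
    i <- which.max(abs(f1$loadings[, d]))
    expect_gt(f1$loadings[i, d], 0)
  }
})

test_that("supplementary projections are consistent with active correlations", {
  n <- 100
  w <- runif(n, 0.5, 2)
  X <- std_matrix(n, 5, w, seed = 8)
  f <- mfa(X, groups = list(g = colnames(X)), weights = w, ndim = 2)
  sup <- project_supplementary(f, sup_quant = cbind(copy = X[, "v1"]))
  expect_equal(unname(sup$quant["copy", ]), unname(f$var_cor["v1", 1:2]),
               tolerance = 1e-9)
  # orthogonal supplementary variable: residual of projection on scores
  set.seed(9)
  z <- rnorm(n)
  wn <- f$weights
  s1 <- f$scores[, 1]
  z <- z - sum(wn * z) - sum(wn * (z - sum(wn * z)) * s1) /
    sum(wn * s1^2) * s1
  sup2 <- project_supplementary(f, sup_quant = cbind(orth = z))
  expect_lt(abs(sup2$quant["orth", 1]), 1e-10)
})

test_that("a two-category split by score sign gets opposite category coordinates", {
  n <- 100
  w <- runif(n, 0.5, 2)
  X <- std_matrix(n, 5, w, seed = 10)
  f <- mfa(X, groups = list(g = colnames(X)), weights = w, ndim = 2)
  side <- ifelse(f$scores[, 1] > 0, "pos", "neg")
  sup <- project_supplementary(f, sup_cat = data.frame(side = side))
  co <- sup$cat$coord_dim1
  expect_true(prod(co) < 0)
  # oracle: direct weighted mean of scores per category
  wn <- f$weights
  expect_equal(sup$cat$coord_dim1[sup$cat$category == "pos"],
               sum(wn[side == "pos"] * f$scores[side == "pos", 1]) /
                 sum(wn[side == "pos"]), tolerance = 1e-12)
})
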