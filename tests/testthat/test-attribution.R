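test_that("hotspot thresholding keeps the dominant-sign high-magnitude ids", {
  map <- c(a = 10, b = 9, c = 0.1)
  expect_equal(select_hotspot(map, 0.5)$ids, c("a", "b"))
  expect_equal(select_hotspot(map, 1.0)$ids, "a")
  # scale invariance under positive rescaling
  expect_equal(select_hotspot(map * 17.3, 0.5)$ids,
               select_hotspot(map, 0.5)$ids)
  # dominant sign wins even when negative
  neg <- c(a = -10, b = -9, c = 4)
  expect_equal(select_hotspot(neg, 0.5)$ids, c("a", "b"))
  explicit <- select_hotspot(map, ids = c("b", "c"))
  expect_equal(explicit$provenance, "explicit-list")
  expect_error(select_hotspot(c(a = 0, b = 0)), "zero")
})

test_that("regional means equal brute-force row means over the mask", {
  set.seed(47)
  m <- matrix(stats::rnorm(60), 12, 5,
              dimnames = list(NULL, sprintf("C%d", 1:5)))
  m[3, 2] <- NA
  mask <- select_hotspot(c(C2 = 5, C4 = 4, C1 = 0.1), 0.5)
  got <- regional_mean_series(m, mask)
  want <- apply(m[, c("C2", "C4")], 1, mean, na.rm = TRUE)
  expect_equal(got, want)
  expect_equal(regional_mean_series(m, "C3"), m[, "C3"])
  two <- cbind(A = m[, 1], B = m[, 1])
  expect_equal(regional_mean_series(two, c("A", "B")), m[, 1],
               ignore_attr = TRUE)
  expect_error(regional_mean_series(m, "Z9"), "not in field")
})

test_that("field PCA matches its spectral definition", {
  set.seed(49)
  a <- stats::rnorm(100)
  rank1 <- outer(a, c(1, 2, 3))
  p1 <- field_pca(rank1, n_components = 1)
  expect_equal(p1$explained[1], 1, tolerance = 1e-10)

  # two exactly uncorrelated unit-variance columns split evenly
  Z <- qr.Q(qr(scale(matrix(stats::rnorm(200), 100, 2), scale = FALSE)))
  Z <- Z * sqrt(99)
  p2 <- field_pca(Z, n_components = 2)
  expect_equal(p2$explained, c(0.5, 0.5), tolerance = 1e-9)

  # independent eigen-decomposition oracle
  M <- matrix(stats::rnorm(500), 100, 5)
  p3 <- field_pca(M, n_components = 3)
  eig <- eigen(stats::cov(scale(M, scale = FALSE)))
  expect_equal(p3$explained, (eig$values / sum(eig$values))[1:3],
               tolerance = 1e-8)
  for (k in 1:3)
    expect_equal(abs(sum(p3$loadings[, k] * eig$vectors[, k])), 1,
                 tolerance = 1e-8)
  expect_error(field_pca(rank1, n_components = 2), "rank")
})

test_that("attribution recovers an exactly explanatory regressor", {
  set.seed(53)
  x1 <- stats::rnorm(96, 0, 3)
  x2 <- stats::rnorm(96)
  fit <- suppressWarnings(fit_attribution(x1, cbind(a = x1, b = x2)))  # perfect fit
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$table$coefficient[1], stats::sd(x1), tolerance = 1e-8)

  # symmetric orthogonal split: equal LMG halves of R^2
  Z <- qr.Q(qr(scale(matrix(stats::rnorm(200), 100, 2), scale = FALSE)))
  y <- Z[, 1] + Z[, 2]
  fit2 <- suppressWarnings(fit_attribution(y, cbind(u = Z[, 1], v = Z[, 2])))
  expect_equal(fit2$table$lmg, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(sum(fit2$table$lmg), fit2$r_squared, tolerance = 1e-10)

  expect_error(fit_attribution(y, cbind(p = Z[, 1], q = 2 * Z[, 1])),
               "collinear")
  expect_error(fit_attribution(y, cbind(p = Z[, 1], q = rep(1, 100))),
               "constant")
})

test_that("VIF follows its closed form", {
  X <- regressors_with_cor(96, 0.6, seed = 57)
  expect_equal(stats::cor(X)[1, 2], 0.6, tolerance = 1e-12)
  vif <- compute_vif(X)
  expect_equal(unname(vif), c(1.5625, 1.5625), tolerance = 1e-10,
               ignore_attr = TRUE)

  Xo <- regressors_with_cor(96, 0, seed = 59)
  expect_equal(unname(compute_vif(Xo)), c(1, 1), tolerance = 1e-10,
               ignore_attr = TRUE)

  Xc <- cbind(a = X[, 1], b = X[, 1])
  expect_equal(unname(compute_vif(Xc)), c(Inf, Inf), ignore_attr = TRUE)
  expect_true(attr(compute_vif(Xc), "collinear"))
})

test_that("LMG equals the brute-force ordering average", {
  for (seed in 1:5) {
    set.seed(seed + 60)
    n <- 96
    L <- matrix(stats::rnorm(16), 4, 4)
    X <- matrix(stats::rnorm(n * 4), n, 4) %*% L  # correlated design
    colnames(X) <- letters[1:4]
    y <- X %*% c(1, 0.5, -0.3, 0) + stats::rnorm(n)
    lmg <- compute_lmg(y, X)
    expect_equal(unname(lmg), brute_lmg(y, X), tolerance = 1e-10)
    expect_equal(sum(lmg), r2_lm(y, X), tolerance = 1e-10)
    # invariances: labeling permutation and affine rescaling
    perm <- c(3, 1, 4, 2)
    expect_equal(unname(compute_lmg(y, X[, perm])), unname(lmg)[perm],
                 tolerance = 1e-10)
    Xr <- sweep(X, 2, c(2, 0.5, 10, 1), `*`)
    expect_equal(unname(compute_lmg(y, Xr)), unname(lmg), tolerance = 1e-10)
  }
})

test_that("single and orthogonal regressors reduce LMG to simple R^2", {
  set.seed(67)
  x <- stats::rnorm(50)
  y <- 2 * x + stats::rnorm(50)
  expect_equal(unname(compute_lmg(y, cbind(x = x))), r2_lm(y, cbind(x)),
               tolerance = 1e-12)
  Z <- qr.Q(qr(scale(matrix(stats::rnorm(300), 100, 3), scale = FALSE)))
  y2 <- Z %*% c(1, 2, 0.5) + stats::rnorm(100, 0, 0.3)
  lmg <- compute_lmg(y2, Z)
  simple <- apply(Z, 2, function(col) stats::cor(y2, col)^2)
  expect_equal(unname(lmg), unname(simple), tolerance = 1e-10)
})

test_that("semi-partial gains bracket the LMG share", {
  set.seed(71)
  X <- matrix(stats::rnorm(96 * 4), 96, 4) %*% matrix(stats::rnorm(16), 4)
  colnames(X) <- letters[1:4]
  y <- X %*% c(1, -0.5, 0.3, 0.1) + stats::rnorm(96)
  spr <- compute_spr(y, X)
  lmg <- compute_lmg(y, X)
  gains <- sequential_gains(y, X)
  for (j in 1:4) {
    expect_equal(spr$l_spr[j], r2_lm(y, X) - r2_lm(y, X[, -j]),
                 tolerance = 1e-10)
    expect_equal(spr$f_spr[j], r2_lm(y, X[, j, drop = FALSE]),
                 tolerance = 1e-10)
    expect_gte(lmg[[j]], min(gains[, j]) - 1e-10)
    expect_lte(lmg[[j]], max(gains[, j]) + 1e-10)
  }
  # orthogonal design: first-in and last-in gains coincide
  Zo <- qr.Q(qr(scale(matrix(stats::rnorm(300), 100, 3), scale = FALSE)))
  yo <- Zo %*% c(1, 2, 3) + stats::rnorm(100, 0, 0.5)
  so <- compute_spr(yo, Zo)
  expect_equal(so$l_spr, so$f_spr, tolerance = 1e-10)
})
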