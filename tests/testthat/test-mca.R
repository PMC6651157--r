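test_that("a self-coupled rank-one field yields a single perfect mode", {
  set.seed(19)
  a <- stats::rnorm(40)
  u <- c(3, 1, -2) / sqrt(14)
  X <- outer(a, u)
  m <- compute_mca(X, X, K = 1)
  expect_equal(m$scf[1], 1.0, tolerance = 1e-12)
  expect_equal(m$left_patterns[, 1], m$right_patterns[, 1])
  expect_equal(abs(sum(m$left_patterns[, 1] * u)), 1, tolerance = 1e-10)
})

test_that("leading singular value equals the maximized projection covariance", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(stats::rnorm(50 * 3), 50, 3)
    Y <- matrix(stats::rnorm(50 * 4), 50, 4)
    m <- compute_mca(X, Y, K = 1)
    oracle <- oracle_max_cov(X, Y, seed = seed)
    expect_equal(m$singular_values[1], oracle, tolerance = 1e-6)
  }
})

test_that("squared covariance is conserved across the spectrum", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:60, 1); p <- sample(3:8, 1); q <- sample(3:8, 1)
    X <- matrix(stats::rnorm(n * p), n, p)
    Y <- matrix(stats::rnorm(n * q), n, q)
    m <- compute_mca(X, Y, K = min(p, q))
    expect_equal(sum(m$scf), 1, tolerance = 1e-10)
    C <- crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE)) / (n - 1)
    expect_equal(sum(m$singular_values^2), sum(C^2), tolerance = 1e-10)
    expect_equal(crossprod(m$left_patterns), diag(min(p, q)),
                 tolerance = 1e-8)
  }
})

test_that("expansion coefficients and covariance maps are consistent", {
  cf <- generate_coupled_fields(80, 5, 4, 2, c(6, 2), noise_sd = 0.5,
                                seed = 23)
  m <- compute_mca(cf$X, cf$Y, K = 2)
  expect_equal(m$left_ec, cf$X %*% m$left_patterns, tolerance = 1e-10)
  # homogeneous map = cov(EC_k, same field's columns)
  expect_equal(m$homo_left[1, ],
               apply(cf$X, 2, function(col) stats::cov(m$left_ec[, 1], col)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(m$hetero_left[2, ],
               apply(cf$Y, 2, function(col) stats::cov(m$left_ec[, 2], col)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # sign convention: dominant left loading positive, ECs strongly coupled
  expect_gt(max(m$left_patterns[, 1]), 0)
  expect_gt(m$ec_correlation[1], 0.9)
})

test_that("station reordering permutes patterns without changing the spectrum", {
  cf <- generate_coupled_fields(60, 6, 5, 2, c(4, 2), noise_sd = 0.3,
                                seed = 29)
  m <- compute_mca(cf$X, cf$Y, K = 2)
  perm <- c(3, 1, 6, 2, 5, 4)
  m2 <- compute_mca(cf$X[, perm], cf$Y, K = 2)
  expect_equal(m2$scf, m$scf, tolerance = 1e-12)
  expect_equal(m2$left_patterns[, 1], m$left_patterns[perm, 1],
               tolerance = 1e-8)
})

test_that("a dominant planted mode is declared significant", {
  cf <- generate_coupled_fields(96, 8, 8, 2, c(10, 1), noise_sd = 0.8,
                                seed = 31)
  res <- permutation_significance(cf$X, cf$Y, K = 2, B = 99, seed = 1)
  expect_true(res$significant[1])
  expect_true(all(res$scf[seq_len(res$K)][res$significant] >
                    res$upci[res$significant]))
  expect_error(permutation_significance(cf$X, cf$Y, K = 2, B = 10), "B must")
})

test_that("permutation null is calibrated near the nominal level", {
  rejections <- 0; n_rep <- 40
  for (seed in seq_len(n_rep)) {
    set.seed(seed + 500)
    X <- matrix(stats::rnorm(96 * 10), 96, 10)
    Y <- matrix(stats::rnorm(96 * 10), 96, 10)
    res <- permutation_significance(X, Y, K = 1, B = 99, seed = seed)
    if (res$significant[1]) rejections <- rejections + 1
  }
  expect_lte(rejections / n_rep, 0.15)
})

test_that("permuting either field gives equivalent null quantiles", {
  cf <- generate_coupled_fields(96, 6, 6, 2, c(5, 2), noise_sd = 1, seed = 37)
  d <- sapply(1:5, function(s) {
    a <- permutation_significance(cf$X, cf$Y, K = 1, B = 199, seed = s,
                                  permute = "right")$upci
    b <- permutation_significance(cf$X, cf$Y, K = 1, B = 199, seed = s,
                                  permute = "left")$upci
    a - b
  })
  expect_lt(abs(mean(d)), 0.05)
})

test_that("expansion-coefficient standardization is exact and invertible", {
  set.seed(41)
  x <- stats::rnorm(50, 0, 4)
  z <- standardize_ec(x)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(z * stats::sd(x), x)
  expect_equal(standardize_ec(z), z)
  expect_error(standardize_ec(rep(1, 10)), "zero-SD")
})

test_that("missing anomaly cells follow the fill-or-drop rule", {
  cf <- generate_coupled_fields(60, 6, 5, 1, 5, noise_sd = 0.5, seed = 43)
  X <- cf$X
  X[1:3, 2] <- NA          # sparse: zero-filled
  X[1:30, 5] <- NA         # gap-heavy: dropped
  expect_warning(expect_warning(m <- compute_mca(X, cf$Y, K = 1),
                                "dropped"), "zero-filling")
  expect_equal(length(m$left_ids), 5)
})
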