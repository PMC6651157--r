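quiet_config <- function(...) {
  # all stochastic components off unless overridden
  defaults <- list(
    n_clusters = 1, stations_per_cluster = 1, years = 2,
    seasonal_amplitude = c(PM25 = 0, SO2 = 0, NO2 = 0),
    shared_mode = list(loadings = NULL, ar1 = 0.6, sd = 0),
    regional = list(ar1 = 0.5, sd = 0),
    common = list(diurnal_amplitude = 0, ar1 = 0.95, sd = 0),
    noise = list(ar1 = 0.6, sd = 0),
    outlier_rate = 0, missing_rate = 0)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(n_clusters = 2, stations_per_cluster = 2,
                          years = 1, seed = 42)
  a <- generate_network(cfg)
  b <- generate_network(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$stations, b$stations)
  expect_identical(a$truth$latent, b$truth$latent)
})

test_that("noiseless series equal their deterministic skeleton", {
  cfg <- quiet_config(trend_by_pollutant = c(PM25 = 2, SO2 = 2, NO2 = 2))
  net <- generate_network(cfg)
  pm <- net$records[net$records$pollutant == "PM25", ]
  t_years <- as.numeric(pm$timestamp - pm$timestamp[1],
                        units = "days") / 365.25
  est <- fit_trend(pm$value, t_years)
  expect_equal(est$slope, 2, tolerance = 1e-6)
  expect_equal(est$ci_halfwidth, 0, tolerance = 1e-6)
  # exact skeleton: baseline + trend only
  expect_equal(pm$value, 60 + 2 * t_years, tolerance = 1e-10)
})

test_that("planted spike count falls in the Poisson 99% band", {
  rate <- 1e-4
  cfg <- synthetic_config(n_clusters = 5, stations_per_cluster = 2,
                          years = 1, outlier_rate = rate,
                          missing_rate = 0, seed = 8)
  net <- generate_network(cfg)
  n_sh <- 10 * length(net$truth$timestamps) * 3
  expected <- rate * n_sh
  band <- stats::qpois(c(0.005, 0.995), expected)
  expect_gte(nrow(net$truth$outliers), band[1])
  expect_lte(nrow(net$truth$outliers), band[2])
})

test_that("planted trends are recovered on clean aggregated series", {
  # station noise only; the semi-monthly means are then close to iid, so
  # the OLS slope should fall within 2 SE of the planted value nearly always
  hits <- 0; n_rep <- 40
  for (seed in seq_len(n_rep)) {
    cfg <- quiet_config(noise = list(ar1 = 0.6, sd = 4),
                        trend_by_pollutant = c(PM25 = -4, SO2 = 0, NO2 = 0),
                        seed = seed)
    net <- generate_network(cfg)
    cl <- stats::setNames("C01", net$stations$station_id)
    panel <- integrate_semimonthly(net$records, cl, pollutant = "PM25")
    est <- fit_trend(panel$values_all[, 1], period_time(panel$periods))
    se <- est$ci_halfwidth / stats::qt(0.975, est$n_used - 2)
    if (abs(est$slope - (-4)) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("coupled-field generator plants exact singular structure", {
  cf1 <- generate_coupled_fields(50, 3, 4, 1, 5, noise_sd = 0, seed = 1)
  m1 <- compute_mca(cf1$X, cf1$Y, K = 1, center = FALSE)
  expect_equal(m1$scf[1], 1.0, tolerance = 1e-12)

  cf2 <- generate_coupled_fields(50, 3, 4, 2, c(4, 1), noise_sd = 0, seed = 2)
  m2 <- compute_mca(cf2$X, cf2$Y, K = 2, center = FALSE)
  expect_equal(m2$singular_values[1:2], c(4, 1), tolerance = 1e-10)
  expect_equal(m2$scf[1], 16 / 17, tolerance = 1e-12)

  # planted patterns are orthonormal and X, Y column-centered
  expect_equal(crossprod(cf2$left_patterns), diag(2), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(cf2$X))), 1e-12)
})

test_that("planted patterns are recovered under moderate noise", {
  hits <- 0
  for (seed in 1:20) {
    cf <- generate_coupled_fields(200, 8, 6, 2, c(5, 1), noise_sd = 0.5,
                                  seed = seed)
    m <- compute_mca(cf$X, cf$Y, K = 1)
    cosine <- abs(sum(m$left_patterns[, 1] * cf$left_patterns[, 1]))
    if (cosine > 0.95) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("degenerate configurations are rejected", {
  expect_error(synthetic_config(n_clusters = 0), "at least one")
  expect_error(synthetic_config(years = 0), "year")
  expect_error(synthetic_config(missing_rate = 1.5), "rates")
  expect_error(generate_coupled_fields(50, 3, 4, 5, rep(1, 5)), "k_modes")
  expect_error(generate_coupled_fields(50, 3, 4, 2, c(1, 4)),
               "non-increasing")
})
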