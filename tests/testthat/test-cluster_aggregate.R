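test_that("stations merge below the distance cutoff and not above", {
  far <- data.frame(station_id = c("A", "B"),
                    lat = c(30, 34.5), lon = c(110, 110))  # ~500 km
  ca <- cluster_stations(far, cutoff_km = 10)
  expect_equal(nrow(ca$centroids), 2)

  near <- data.frame(station_id = c("A", "B"),
                     lat = c(30, 30.009), lon = c(110, 110))  # ~1 km
  ca2 <- cluster_stations(near, cutoff_km = 10)
  expect_equal(nrow(ca2$centroids), 1)
  expect_equal(ca2$centroids$n_stations, 2)

  expect_error(cluster_stations(data.frame(station_id = "A", lat = 91,
                                           lon = 0), 10), "coordinates")
})

test_that("cluster count is monotone non-increasing in the cutoff", {
  set.seed(9)
  st <- data.frame(station_id = sprintf("S%02d", 1:30),
                   lat = stats::runif(30, 30, 35),
                   lon = stats::runif(30, 110, 115))
  counts <- sapply(c(1, 5, 20, 50, 100, 500),
                   function(h) nrow(cluster_stations(st, h)$centroids))
  expect_true(all(diff(counts) <= 0))
  # deterministic in input order
  perm <- st[sample(30), ]
  expect_identical(cluster_stations(st, 20)$cluster_of,
                   cluster_stations(perm, 20)$cluster_of)
})

test_that("fourth-quartile mean follows the interpolated-quantile rule", {
  expect_equal(fourth_quartile_mean(1:8), 7.5)    # Q3 = 6.25 -> mean(7, 8)
  expect_equal(fourth_quartile_mean(c(0, 0, 0, 100)), 100)
  expect_equal(fourth_quartile_mean(rep(10, 5)), 10)  # degenerate fallback
  expect_equal(fourth_quartile_mean(c(NA, 1, NA, 2)), 2)
  expect_error(fourth_quartile_mean(c(NA_real_, NA_real_)), "no values")
})

test_that("semi-monthly integration pools member hours per window", {
  ts <- hourly_timestamps(2015, 1)
  jan1 <- ts[1:(15 * 24)]  # first semi-month of January
  rec <- data.frame(station_id = "A", lat = 30, lon = 110,
                    pollutant = "PM25", timestamp = jan1, value = 50)
  panel <- integrate_semimonthly(rec, c(A = "C1"), min_completeness = 0)
  row <- which(panel$periods$period_index == 1)
  expect_equal(unname(panel$values_all[row, 1]), 50)
  expect_equal(unname(panel$values_q4[row, 1]), 50)
  expect_equal(unname(panel$completeness[row, 1]), 1.0)

  # eight valid hours 1..8 in one window -> q4 = mean(7, 8) = 7.5
  rec2 <- rec
  rec2$value <- NA_real_
  rec2$value[1:8] <- 1:8
  panel2 <- integrate_semimonthly(rec2, c(A = "C1"), min_completeness = 0)
  expect_equal(unname(panel2$values_q4[row, 1]), 7.5)
  expect_equal(unname(panel2$values_all[row, 1]), mean(1:8))
  expect_equal(unname(panel2$completeness[row, 1]), 8 / (15 * 24))

  # below the completeness threshold the cell goes missing in both variants
  panel3 <- integrate_semimonthly(rec2, c(A = "C1"), min_completeness = 0.5)
  expect_true(is.na(panel3$values_all[row, 1]))
  expect_true(is.na(panel3$values_q4[row, 1]))
})

test_that("a cluster of identical stations matches any single member", {
  ts <- hourly_timestamps(2015, 1)
  set.seed(11)
  v <- stats::rnorm(length(ts), 40, 8)
  rec1 <- data.frame(station_id = "A", lat = 30, lon = 110,
                     pollutant = "PM25", timestamp = ts, value = v)
  rec3 <- do.call(rbind, lapply(c("A", "B", "C"), function(s) {
    r <- rec1; r$station_id <- s; r
  }))
  p1 <- integrate_semimonthly(rec1, c(A = "C1"))
  p3 <- integrate_semimonthly(rec3, c(A = "C1", B = "C1", C = "C1"))
  expect_equal(p3$values_all, p1$values_all)
  expect_equal(p3$values_q4, p1$values_q4)
})

test_that("the top-quartile mean dominates the full mean cell-wise", {
  cfg <- synthetic_config(n_clusters = 3, stations_per_cluster = 2,
                          years = 1, seed = 13)
  net <- generate_network(cfg)
  cl <- cluster_stations(net$stations)
  panel <- integrate_semimonthly(net$records, cl, pollutant = "PM25")
  both <- !is.na(panel$values_all) & !is.na(panel$values_q4)
  expect_true(all(panel$values_q4[both] >= panel$values_all[both]))
})

test_that("gappy clusters are excluded with a report", {
  periods <- data.frame(year = rep(2015:2016, each = 24),
                        period_index = rep(1:24, 2))
  full <- matrix(50, 48, 2)
  gappy <- full
  gappy[1:24, 2] <- NA
  p <- semimonthly_panel(c("C1", "C2"), periods, gappy, gappy,
                         matrix(1, 48, 2))
  out <- exclude_gappy(p, 0.2)
  expect_equal(out$cluster_ids, "C1")
  expect_equal(attr(out, "dropped"), "C2")

  p_ok <- semimonthly_panel(c("C1", "C2"), periods, full, full,
                            matrix(1, 48, 2))
  expect_equal(exclude_gappy(p_ok, 0.2)$cluster_ids, c("C1", "C2"))
  expect_equal(exclude_gappy(p, 1.0)$cluster_ids, c("C1", "C2"))
  p_bad <- semimonthly_panel(c("C1", "C2"), periods,
                             matrix(NA_real_, 48, 2), gappy,
                             matrix(1, 48, 2))
  expect_error(exclude_gappy(p_bad, 0.2), "threshold")
})
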