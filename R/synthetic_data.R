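#' Configuration for the synthetic air-quality network generator
#'
#' Defaults emulate a national monitoring network observed hourly over four
#' calendar years (2015-2018): clusters of co-located urban stations, a
#' winter-peaking annual cycle, multi-year linear trends of a few ug/m3 per
#' year, a shared latent mode coupling PM2.5 and SO2 over a subset of
#' clusters with NO2 left uncoupled, AR(1) measurement noise, occasional
#' sensor spikes and random missing hours.
#'
#' @param n_clusters number of station clusters.
#' @param stations_per_cluster stations in each cluster (scalar or vector
#'   of length `n_clusters`).
#' @param cluster_centers optional data.frame(lat, lon); by default drawn
#'   uniformly in a continental bounding box (lat 25-45, lon 100-122).
#' @param years number of calendar years simulated.
#' @param start_year first simulated calendar year.
#' @param baseline_by_pollutant named numeric, mean level in ug/m3.
#' @param seasonal_amplitude named numeric, annual-cycle amplitude in ug/m3
#'   (cosine peaking mid-January).
#' @param trend_by_pollutant named numeric, linear trend in ug/(m3 a).
#' @param shared_mode list: `loadings` (n_clusters x 3 matrix, columns
#'   PM25/SO2/NO2; default couples PM2.5 and SO2 over the first half of the
#'   clusters and leaves NO2 at zero), `ar1` (latent AR(1) coefficient at
#'   the semi-monthly scale), `sd` (stationary latent SD, ug/m3).
#' @param regional per-cluster slow background, independent across
#'   clusters: an AR(1) series at the semi-monthly scale (held constant
#'   within each window), with `ar1` and named stationary `sd` (ug/m3).
#'   Each cluster-city has its own emission and weather history beyond the
#'   single shared mode; this is what keeps deseasonalized fields from
#'   collapsing to rank one.
#' @param common within-cluster shared short-term variability, seen
#'   identically by every station of a cluster: `diurnal_amplitude` (named,
#'   ug/m3; fixed 24-h cycle, traffic-peaked for NO2), `ar1` and `sd`
#'   (named, ug/m3) of a slowly varying synoptic AR(1) term. This is what
#'   makes the cluster reference series fluctuate on the 24-h scale the
#'   way real hourly records do; station-level `noise` rides on top of it.
#' @param noise list: `ar1` (hourly AR(1) coefficient) and `sd`
#'   (stationary SD of the AR(1) noise, ug/m3), independent per station.
#' @param outlier_rate spike probability per station-hour.
#' @param outlier_magnitude spike height as a multiple of the stationary
#'   noise SD.
#' @param outlier_sign "positive", "negative" or "both".
#' @param missing_rate probability that a station-hour is unobserved.
#' @param seed integer; fixes the full output bit-exactly.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 12,
                             stations_per_cluster = 4,
                             cluster_centers = NULL,
                             years = 4,
                             start_year = 2015,
                             baseline_by_pollutant = c(PM25 = 60, SO2 = 25, NO2 = 35),
                             seasonal_amplitude = c(PM25 = 20, SO2 = 8, NO2 = 8),
                             trend_by_pollutant = c(PM25 = -4, SO2 = -2, NO2 = 0.5),
                             shared_mode = list(loadings = NULL, ar1 = 0.6, sd = 8),
                             regional = list(ar1 = 0.5,
                                             sd = c(PM25 = 4, SO2 = 2.5, NO2 = 3)),
                             common = list(diurnal_amplitude = c(PM25 = 6, SO2 = 2, NO2 = 7),
                                           ar1 = 0.95,
                                           sd = c(PM25 = 5, SO2 = 2, NO2 = 4.5)),
                             noise = list(ar1 = 0.6, sd = 4),
                             outlier_rate = 1e-4,
                             outlier_magnitude = 10,
                             outlier_sign = "positive",
                             missing_rate = 0.05,
                             seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              stations_per_cluster = stations_per_cluster,
              cluster_centers = cluster_centers,
              years = as.integer(years), start_year = as.integer(start_year),
              baseline_by_pollutant = baseline_by_pollutant,
              seasonal_amplitude = seasonal_amplitude,
              trend_by_pollutant = trend_by_pollutant,
              shared_mode = shared_mode, regional = regional,
              common = common, noise = noise,
              outlier_rate = outlier_rate,
              outlier_magnitude = outlier_magnitude,
              outlier_sign = match.arg(outlier_sign,
                                       c("positive", "negative", "both")),
              missing_rate = missing_rate, seed = as.integer(seed))
  if (cfg$n_clusters < 1 || any(cfg$stations_per_cluster < 1))
    stop("need at least one cluster and one station per cluster")
  if (cfg$years < 1) stop("need at least one simulated year")
  for (r in c(cfg$outlier_rate, cfg$missing_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (cfg$noise$sd < 0 || cfg$shared_mode$sd < 0 || any(cfg$common$sd < 0) ||
      any(cfg$regional$sd < 0))
    stop("SDs must be >= 0")
  if (abs(cfg$noise$ar1) >= 1 || abs(cfg$shared_mode$ar1) >= 1 ||
      abs(cfg$common$ar1) >= 1 || abs(cfg$regional$ar1) >= 1)
    stop("AR(1) coefficients must have |phi| < 1")
  for (nm in POLLUTANTS) {
    if (is.na(cfg$baseline_by_pollutant[nm]))
      stop("baseline_by_pollutant must name ", nm)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# stationary AR(1) path with given marginal sd (exact at sd = 0)
ar1_series <- function(n, phi, sd_marginal) {
  if (sd_marginal == 0) return(numeric(n))
  innov_sd <- sd_marginal * sqrt(1 - phi^2)
  e <- stats::rnorm(n, sd = innov_sd)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, sd = sd_marginal)
  if (n > 1) for (t in 2:n) x[t] <- phi * x[t - 1] + e[t]
  x
}

hourly_timestamps <- function(start_year, years) {
  from <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC")
  to <- as.POSIXct(sprintf("%d-12-31 23:00:00", start_year + years - 1),
                   tz = "UTC")
  seq(from, to, by = "hour")
}

#' Semi-month-of-year index (1..24) for timestamps
#'
#' Days 1-15 form the first half of a month, day 16 to month end the
#' second, giving 24 windows per calendar year.
#'
#' @param timestamps POSIXct vector.
#' @return list with integer vectors `year` and `period_index`.
#' @export
semimonth_of <- function(timestamps) {
  lt <- as.POSIXlt(timestamps)
  list(year = lt$year + 1900L,
       period_index = (lt$mon * 2L) + ifelse(lt$mday <= 15L, 1L, 2L))
}

#' Generate a synthetic hourly multi-station pollutant network
#'
#' Each station-hour value is built as baseline + trend x elapsed years +
#' seasonal cycle + cluster loading x shared latent mode + AR(1) noise,
#' with optional additive spikes and missing hours; negative values are
#' truncated at zero. The shared latent mode is AR(1) at the semi-monthly
#' scale, held constant within each semi-month (step upsampling to hours).
#'
#' @param config a [synthetic_config()].
#' @return list with `stations` (data.frame station_id, lat, lon,
#'   cluster_id), `records` (long data.frame as in [read_hourly()]) and
#'   `truth` (planted trends, loadings, latent series, spike and missing
#'   positions, per station-hour).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nc <- config$n_clusters
  spc <- rep_len(config$stations_per_cluster, nc)
  centers <- config$cluster_centers
  if (is.null(centers))
    centers <- data.frame(lat = stats::runif(nc, 25, 45),
                          lon = stats::runif(nc, 100, 122))
  n_stations <- sum(spc)
  cluster_of <- rep(seq_len(nc), spc)
  stations <- data.frame(
    station_id = sprintf("S%03d", seq_len(n_stations)),
    lat = centers$lat[cluster_of] + stats::rnorm(n_stations, sd = 0.01),
    lon = centers$lon[cluster_of] + stats::rnorm(n_stations, sd = 0.01),
    cluster_id = sprintf("C%02d", cluster_of),
    stringsAsFactors = FALSE)

  ts <- hourly_timestamps(config$start_year, config$years)
  nh <- length(ts)
  t_years <- as.numeric(ts - ts[1], units = "days") / 365.25
  doy <- as.POSIXlt(ts)$yday
  seas_shape <- cos(2 * pi * (doy - 15) / 365.25)
  sm <- semimonth_of(ts)
  period_key <- (sm$year - config$start_year) * 24L + sm$period_index
  n_periods <- max(period_key)

  loadings <- config$shared_mode$loadings
  if (is.null(loadings)) {
    loadings <- matrix(0, nc, 3, dimnames = list(NULL, POLLUTANTS))
    coupled <- seq_len(ceiling(nc / 2))
    loadings[coupled, "PM25"] <- 1
    loadings[coupled, "SO2"] <- 0.8
  }
  z <- ar1_series(n_periods, config$shared_mode$ar1, config$shared_mode$sd)
  z_hourly <- z[period_key]

  # shared within-cluster short-term variability: fixed diurnal cycle plus
  # a slow synoptic AR(1) term, identical for all stations of a cluster
  per_poll <- function(x, g) {
    if (is.null(names(x))) x[[1]] else if (g %in% names(x)) x[[g]] else 0
  }
  hod <- as.POSIXlt(ts)$hour
  diurnal_shape <- cos(2 * pi * (hod - 8) / 24)
  common_term <- vector("list", nc)
  for (cl in seq_len(nc)) {
    common_term[[cl]] <- lapply(stats::setNames(POLLUTANTS, POLLUTANTS),
      function(g) {
        amp <- per_poll(config$common$diurnal_amplitude, g)
        csd <- per_poll(config$common$sd, g)
        rsd <- per_poll(config$regional$sd, g)
        amp * diurnal_shape + ar1_series(nh, config$common$ar1, csd) +
          ar1_series(n_periods, config$regional$ar1, rsd)[period_key]
      })
  }

  n_total <- n_stations * 3L * nh
  rec_station <- rep(stations$station_id, each = 3L * nh)
  rec_poll <- rep(rep(POLLUTANTS, each = nh), n_stations)
  value <- numeric(n_total)
  truth_noise_sd <- config$noise$sd
  out_rows <- vector("list", n_stations * 3L)
  idx <- 0L
  for (s in seq_len(n_stations)) {
    cl <- cluster_of[s]
    for (g in POLLUTANTS) {
      idx <- idx + 1L
      base <- config$baseline_by_pollutant[[g]] +
        config$trend_by_pollutant[[g]] * t_years +
        config$seasonal_amplitude[[g]] * seas_shape +
        loadings[cl, g] * z_hourly + common_term[[cl]][[g]]
      noise <- ar1_series(nh, config$noise$ar1, truth_noise_sd)
      v <- base + noise
      spikes <- integer(0)
      if (config$outlier_rate > 0) {
        spikes <- which(stats::runif(nh) < config$outlier_rate)
        if (length(spikes)) {
          sign_v <- switch(config$outlier_sign,
                           positive = rep(1, length(spikes)),
                           negative = rep(-1, length(spikes)),
                           both = sample(c(-1, 1), length(spikes), TRUE))
          v[spikes] <- v[spikes] +
            sign_v * config$outlier_magnitude * truth_noise_sd
        }
      }
      v <- pmax(v, 0)
      miss <- integer(0)
      if (config$missing_rate > 0) {
        miss <- which(stats::runif(nh) < config$missing_rate)
        v[miss] <- NA_real_
      }
      off <- (idx - 1L) * nh
      value[off + seq_len(nh)] <- v
      out_rows[[idx]] <- list(station = stations$station_id[s], pollutant = g,
                              spikes = setdiff(spikes, miss), missing = miss)
    }
  }
  records <- data.frame(
    station_id = rec_station,
    lat = stations$lat[match(rec_station, stations$station_id)],
    lon = stations$lon[match(rec_station, stations$station_id)],
    pollutant = rec_poll,
    timestamp = rep(ts, n_stations * 3L),
    value = value, stringsAsFactors = FALSE)

  outliers <- do.call(rbind, lapply(out_rows, function(r)
    if (length(r$spikes))
      data.frame(station_id = r$station, pollutant = r$pollutant,
                 hour_index = r$spikes, stringsAsFactors = FALSE)))
  if (is.null(outliers))
    outliers <- data.frame(station_id = character(), pollutant = character(),
                           hour_index = integer(), stringsAsFactors = FALSE)
  truth <- list(trend_by_pollutant = config$trend_by_pollutant,
                baseline_by_pollutant = config$baseline_by_pollutant,
                loadings = loadings, latent = z,
                noise_sd = truth_noise_sd,
                outliers = outliers,
                n_missing = sum(is.na(value)),
                cluster_of = stats::setNames(stations$cluster_id,
                                             stations$station_id),
                timestamps = ts)
  list(stations = stations, records = records, truth = truth)
}

#' Generate a pair of coupled time x space fields with planted SVD structure
#'
#' Builds column-centered matrices X (n x p) and Y (n x q) whose sample
#' cross-covariance X'Y/(n-1) equals U diag(s) V' exactly when
#' `noise_sd = 0`, with orthonormal planted patterns U, V and shared latent
#' time scores. Used to validate maximum covariance analysis against known
#' truth.
#'
#' @param n_time number of time steps (>= k_modes + 1).
#' @param p,q number of left/right spatial points.
#' @param k_modes number of planted modes.
#' @param singular_values non-increasing positive vector, length `k_modes`.
#' @param noise_sd SD of added white noise.
#' @param seed integer RNG seed.
#' @return list(X, Y, left_patterns, right_patterns, scores).
#' @export
generate_coupled_fields <- function(n_time, p, q, k_modes, singular_values,
                                    noise_sd = 0, seed = 1L) {
  k <- as.integer(k_modes)
  if (k > min(p, q)) stop("k_modes must not exceed min(p, q)")
  if (length(singular_values) != k)
    stop("need one singular value per planted mode")
  if (any(singular_values <= 0) || is.unsorted(rev(singular_values)))
    stop("singular_values must be positive and non-increasing")
  if (n_time < k + 1) stop("n_time too small for ", k, " modes")
  set.seed(seed)
  U <- qr.Q(qr(matrix(stats::rnorm(p * k), p, k)))
  V <- qr.Q(qr(matrix(stats::rnorm(q * k), q, k)))
  Z <- matrix(stats::rnorm(n_time * k), n_time, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Tm <- qr.Q(qr(Z)) * sqrt(n_time - 1)  # centered, T'T = (n-1) I
  S <- Tm %*% diag(sqrt(singular_values), k)
  X <- S %*% t(U)
  Y <- S %*% t(V)
  if (noise_sd > 0) {
    X <- X + matrix(stats::rnorm(n_time * p, sd = noise_sd), n_time, p)
    Y <- Y + matrix(stats::rnorm(n_time * q, sd = noise_sd), n_time, q)
    X <- scale(X, center = TRUE, scale = FALSE)
    Y <- scale(Y, center = TRUE, scale = FALSE)
    attr(X, "scaled:center") <- attr(Y, "scaled:center") <- NULL
  }
  list(X = X, Y = Y, left_patterns = U, right_patterns = V, scores = S)
}
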