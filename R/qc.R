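#' Quality-control configuration
#'
#' Parameters of the two-stage outlier screen: a deviation screen against a
#' cluster reference series (flag when the absolute deviation exceeds a
#' pollutant-specific multiple of the trailing 24-h reference SD) followed
#' by a second-difference (quadratic gradient) screen.
#'
#' @param deviation_multiplier_default multiplier for the deviation screen
#'   (3 by default).
#' @param deviation_multiplier_by_pollutant named overrides; SO2 uses 6
#'   because of its larger natural variation.
#' @param sd_window trailing window length in hours for the reference SD.
#' @param gradient_bounds closed interval of admissible second differences,
#'   ug/m3.
#' @param sd_floor lower bound on the reference SD, ug/m3; guards against
#'   zero-variance references.
#' @return a validated list of class `qc_config`.
#' @export
qc_config <- function(deviation_multiplier_default = 3,
                      deviation_multiplier_by_pollutant = c(SO2 = 6),
                      sd_window = 24L,
                      gradient_bounds = c(-100, 100),
                      sd_floor = 1.0) {
  if (deviation_multiplier_default <= 0 ||
      any(deviation_multiplier_by_pollutant <= 0))
    stop("deviation multipliers must be positive")
  if (gradient_bounds[1] >= gradient_bounds[2])
    stop("gradient_bounds must be an interval (lower < upper)")
  if (sd_floor < 0) stop("sd_floor must be >= 0")
  if (sd_window < 2) stop("sd_window must be >= 2 hours")
  structure(list(deviation_multiplier_default = deviation_multiplier_default,
                 deviation_multiplier_by_pollutant =
                   deviation_multiplier_by_pollutant,
                 sd_window = as.integer(sd_window),
                 gradient_bounds = gradient_bounds,
                 sd_floor = sd_floor),
            class = "qc_config")
}

deviation_multiplier <- function(config, pollutant) {
  m <- config$deviation_multiplier_by_pollutant
  if (!is.null(names(m)) && pollutant %in% names(m)) m[[pollutant]]
  else config$deviation_multiplier_default
}

#' Cluster reference series (element-wise median across stations)
#'
#' @param series_matrix hours x stations numeric matrix sharing one hourly
#'   index; a plain vector is treated as a single station.
#' @return numeric vector: the per-hour median over stations, ignoring
#'   missing values; missing where all stations are missing.
#' @export
reference_series <- function(series_matrix) {
  if (is.null(series_matrix) ||
      (is.matrix(series_matrix) && ncol(series_matrix) == 0))
    stop("empty cluster: no station series")
  if (!is.matrix(series_matrix)) series_matrix <- cbind(series_matrix)
  if (ncol(series_matrix) == 1) return(as.numeric(series_matrix[, 1]))
  out <- apply(series_matrix, 1, stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

# trailing-window SD, missing-aware; windows at the start of the series use
# the partial window available; NA where fewer than 2 valid points
rolling_sd <- function(x, window) {
  n <- length(x)
  ok <- !is.na(x)
  v <- ifelse(ok, x, 0)
  lagged <- function(cs) c(rep(0, window), cs[seq_len(n - window)])
  cs <- cumsum(v); cs2 <- cumsum(v * v); cn <- cumsum(ok)
  if (n <= window) {
    s <- cs; s2 <- cs2; m <- cn
  } else {
    s <- cs - lagged(cs); s2 <- cs2 - lagged(cs2); m <- cn - lagged(cn)
  }
  out <- rep(NA_real_, n)
  have <- m >= 2
  varw <- (s2[have] - s[have]^2 / m[have]) / (m[have] - 1)
  out[have] <- sqrt(pmax(varw, 0))
  out
}

#' Deviation screen against a cluster reference
#'
#' Flags hour `t` when `|x(t) - ref(t)|` exceeds the pollutant multiplier
#' times `max(SD24(t), sd_floor)`, where `SD24(t)` is the SD of the
#' reference over the trailing window ending at `t`.
#'
#' @param series numeric hourly series of one station.
#' @param reference reference series on the same hourly index.
#' @param config a [qc_config()].
#' @param pollutant pollutant code (selects the multiplier).
#' @return logical outlier mask, `FALSE` where either series is missing.
#' @export
screen_deviation <- function(series, reference, config = qc_config(),
                             pollutant = "PM25") {
  if (length(series) != length(reference))
    stop("series and reference must share one index")
  if (length(series) < config$sd_window)
    stop("SD window (", config$sd_window, " h) longer than the series")
  m <- deviation_multiplier(config, pollutant)
  sd24 <- rolling_sd(reference, config$sd_window)
  thr <- m * pmax(sd24, config$sd_floor)
  thr[is.na(thr)] <- m * config$sd_floor
  flag <- !is.na(series) & !is.na(reference) &
    abs(series - reference) > thr
  flag
}

#' Quadratic-gradient (second difference) screen
#'
#' Second differences `d(i) = x(i+1) - 2 x(i) + x(i-1)` are computed within
#' each contiguous run of non-missing values. Indices whose `d` falls
#' outside the closed admissible interval form candidate runs; within each
#' maximal contiguous candidate run only the index of maximum `|d|` is
#' flagged, so an isolated spike is flagged once rather than together with
#' its neighbours.
#'
#' @param series numeric hourly series.
#' @param bounds closed interval of admissible second differences.
#' @return logical outlier mask.
#' @export
screen_gradient <- function(series, bounds = c(-100, 100)) {
  n <- length(series)
  flag <- logical(n)
  if (n < 3) return(flag)
  runs <- rle(!is.na(series))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values & runs$lengths >= 3L)) {
    i0 <- starts[r]; i1 <- ends[r]
    x <- series[i0:i1]
    k <- length(x)
    d <- x[3:k] - 2 * x[2:(k - 1)] + x[1:(k - 2)]  # at interior 2..k-1
    cand <- d < bounds[1] | d > bounds[2]
    if (!any(cand)) next
    cruns <- rle(cand)
    cends <- cumsum(cruns$lengths)
    cstarts <- cends - cruns$lengths + 1L
    for (cr in which(cruns$values)) {
      seg <- cstarts[cr]:cends[cr]
      pick <- seg[which.max(abs(d[seg]))]
      flag[i0 + pick] <- TRUE  # interior index pick maps to position pick+1
    }
  }
  flag
}

#' Apply the two-stage outlier screen to an hourly record set
#'
#' Per cluster and pollutant, a reference series (station median) is
#' formed, the deviation screen is applied to each member station, and the
#' gradient screen is then run on the deviation-screened series. Flagged
#' values are set to missing.
#'
#' @param records long data.frame as returned by [read_hourly()].
#' @param clusters station-to-cluster assignment: a
#'   [cluster_stations()] result, or a named character vector
#'   (station_id -> cluster_id).
#' @param config a [qc_config()].
#' @return list with `records` (cleaned copy) and `report`
#'   (per-pollutant counts and removal fractions).
#' @export
apply_qc <- function(records, clusters, config = qc_config()) {
  cluster_of <- as_cluster_map(clusters)
  unknown <- setdiff(unique(records$station_id), names(cluster_of))
  if (length(unknown))
    stop("stations without cluster assignment: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  grid <- sort(unique(records$timestamp))
  cleaned <- records$value
  report <- list()
  for (g in intersect(POLLUTANTS, unique(records$pollutant))) {
    rows_g <- which(records$pollutant == g)
    sub <- records[rows_g, , drop = FALSE]
    n_dev <- 0L; n_grad <- 0L
    for (cl in unique(cluster_of[sub$station_id])) {
      members <- names(cluster_of)[cluster_of == cl]
      members <- intersect(members, unique(sub$station_id))
      if (!length(members)) next
      in_cl <- sub$station_id %in% members
      hi <- match(sub$timestamp[in_cl], grid)
      si <- match(sub$station_id[in_cl], members)
      mat <- matrix(NA_real_, length(grid), length(members))
      mat[cbind(hi, si)] <- sub$value[in_cl]
      if (all(is.na(mat))) next
      ref <- reference_series(mat)
      for (j in seq_along(members)) {
        x <- mat[, j]
        if (all(is.na(x))) next
        dev_mask <- screen_deviation(x, ref, config, g)
        x[dev_mask] <- NA_real_
        grad_mask <- screen_gradient(x, config$gradient_bounds)
        x[grad_mask] <- NA_real_
        n_dev <- n_dev + sum(dev_mask)
        n_grad <- n_grad + sum(grad_mask)
        mat[, j] <- x
      }
      idx_cl <- rows_g[in_cl]
      cleaned[idx_cl] <- mat[cbind(hi, si)]
    }
    n_valid <- sum(!is.na(sub$value))
    report[[g]] <- list(n_values = n_valid,
                        n_flagged_deviation = n_dev,
                        n_flagged_gradient = n_grad,
                        removed_fraction =
                          if (n_valid > 0) (n_dev + n_grad) / n_valid else 0)
  }
  out <- records
  out$value <- cleaned
  list(records = out, report = report)
}

as_cluster_map <- function(clusters) {
  if (inherits(clusters, "cluster_assignment")) return(clusters$cluster_of)
  if (is.character(clusters) && !is.null(names(clusters))) return(clusters)
  if (is.data.frame(clusters) &&
      all(c("station_id", "cluster_id") %in% names(clusters)))
    return(stats::setNames(as.character(clusters$cluster_id),
                           clusters$station_id))
  stop("unrecognized cluster assignment")
}
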