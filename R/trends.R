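#' Fractional-year time axis of a panel's periods
#'
#' Each semi-monthly window is placed at its mid-point,
#' `year + (period_index - 0.5) / 24`.
#'
#' @param periods data.frame(year, period_index).
#' @return numeric vector of fractional years.
#' @export
period_time <- function(periods) {
  periods$year + (periods$period_index - 0.5) / 24
}

#' Remove the annual cycle from a semi-monthly panel matrix
#'
#' The climatology is the mean over years of each of the 24
#' semi-month-of-year windows (missing-aware); anomalies are the values
#' minus their window climatology, so the annual cycle is removed before
#' covariance analysis.
#'
#' @param values periods x ids matrix (e.g. `panel$values_all`).
#' @param periods data.frame(year, period_index) matching the rows.
#' @param ids column identifiers.
#' @param pollutant pollutant code stored on the result.
#' @return an [anomaly_field()].
#' @export
deseasonalize <- function(values, periods, ids = colnames(values),
                          pollutant = "PM25") {
  stopifnot(nrow(values) == nrow(periods))
  if (is.null(ids)) ids <- sprintf("V%02d", seq_len(ncol(values)))
  n_years <- length(unique(periods$year))
  if (n_years < 2)
    stop("need >= 2 years so every semi-month window has >= 2 observations")
  clim <- matrix(NA_real_, 24, ncol(values))
  anom <- values
  for (k in 1:24) {
    rows <- which(periods$period_index == k)
    if (!length(rows)) next
    clim[k, ] <- colMeans(values[rows, , drop = FALSE], na.rm = TRUE)
    anom[rows, ] <- sweep(values[rows, , drop = FALSE], 2, clim[k, ])
  }
  if (anyNA(clim)) {
    clim[is.nan(clim)] <- NA_real_
    warning("some semi-month windows have no observations; ",
            "their anomalies are set missing")
  }
  anom[is.nan(anom)] <- NA_real_
  anomaly_field(pollutant, periods, ids, anom, clim)
}

#' Least-squares linear trend with 95% confidence interval
#'
#' Ordinary least squares of concentration on fractional-year time. The
#' half-width of the 95% interval is `t(0.975, n - 2) * SE(slope)` and the
#' p-value is the two-sided t-test of zero slope.
#'
#' @param values numeric series (ug/m3), missing allowed.
#' @param time_years fractional-year time axis of the same length.
#' @param variant label stored on the estimate ("all" or "q4").
#' @return list of class `trend_estimate`: `slope`, `ci_halfwidth`,
#'   `p_value`, `n_used`, `variant` (slope and half-width in ug/(m3 a)).
#' @export
fit_trend <- function(values, time_years, variant = "all") {
  stopifnot(length(values) == length(time_years))
  ok <- !is.na(values) & !is.na(time_years)
  n <- sum(ok)
  if (n < 3) stop("need >= 3 non-missing points to fit a trend")
  x <- time_years[ok]; y <- values[ok]
  if (stats::var(x) == 0) stop("zero time variance")
  # closed-form simple OLS: robust to zero-residual degenerate fits
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  resid <- y - mean(y) - slope * xc
  se <- sqrt(max(sum(resid^2), 0) / (n - 2) / sxx)
  if (!is.finite(se)) se <- 0
  if (se > 0) {
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  } else {
    p <- if (abs(slope) < 1e-12) 1 else 0
  }
  structure(list(slope = slope,
                 ci_halfwidth = stats::qt(0.975, n - 2) * se,
                 p_value = p, n_used = n, variant = variant),
            class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("trend (%s): %.3f +/- %.3f ug/(m3 a), p = %.3g, n = %d\n",
              x$variant, x$slope, x$ci_halfwidth, x$p_value, x$n_used))
  invisible(x)
}

#' Per-cluster trends for a panel
#'
#' @param panel a [semimonthly_panel()].
#' @param variant "all" or "q4", selecting the all-value or
#'   fourth-quartile-averaged matrix.
#' @param deseasonalized if `TRUE`, fit on anomalies rather than raw
#'   values. With complete multi-year records the annual cycle does not
#'   bias the slope, so the default fits the raw series.
#' @return data.frame: cluster_id, slope, ci_halfwidth, p_value, n_used,
#'   significant (95% level).
#' @export
panel_trends <- function(panel, variant = c("all", "q4"),
                         deseasonalized = FALSE) {
  variant <- match.arg(variant)
  values <- if (variant == "all") panel$values_all else panel$values_q4
  if (deseasonalized)
    values <- deseasonalize(values, panel$periods, panel$cluster_ids)$anomalies
  tt <- period_time(panel$periods)
  rows <- lapply(seq_along(panel$cluster_ids), function(j) {
    est <- fit_trend(values[, j], tt, variant)
    data.frame(cluster_id = panel$cluster_ids[j], slope = est$slope,
               ci_halfwidth = est$ci_halfwidth, p_value = est$p_value,
               n_used = est$n_used, significant = est$p_value < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Region-level trends
#'
#' The region series is the missing-aware mean across member clusters per
#' period, fitted with [fit_trend()]. This yields a Table-1-shaped
#' summary: one `slope +/- ci_halfwidth` per region and variant.
#'
#' @param panel a [semimonthly_panel()].
#' @param region_map named character vector cluster_id -> region name.
#' @param variant "all" or "q4".
#' @return data.frame: region, variant, n_clusters, slope, ci_halfwidth,
#'   p_value, significant.
#' @export
regional_trend <- function(panel, region_map, variant = c("all", "q4")) {
  variant <- match.arg(variant)
  missing_cl <- setdiff(names(region_map), panel$cluster_ids)
  if (length(missing_cl))
    stop("region map references unknown clusters: ",
         paste(utils::head(missing_cl, 3), collapse = ", "))
  values <- if (variant == "all") panel$values_all else panel$values_q4
  tt <- period_time(panel$periods)
  regions <- unique(region_map)
  rows <- lapply(regions, function(rg) {
    members <- names(region_map)[region_map == rg]
    if (!length(members)) stop("empty region: ", rg)
    cols <- match(members, panel$cluster_ids)
    series <- rowMeans(values[, cols, drop = FALSE], na.rm = TRUE)
    series[is.nan(series)] <- NA_real_
    est <- fit_trend(series, tt, variant)
    data.frame(region = rg, variant = variant, n_clusters = length(members),
               slope = est$slope, ci_halfwidth = est$ci_halfwidth,
               p_value = est$p_value, significant = est$p_value < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
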