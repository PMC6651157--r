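#' Spatial hierarchical clustering of monitoring stations
#'
#' Agglomerative clustering (average linkage) on great-circle (haversine)
#' distances, with the tree cut at `cutoff_km`. Stations are processed in
#' lexicographic `station_id` order so the assignment is deterministic.
#' Singleton clusters are kept as independent stations.
#'
#' @param stations data.frame with columns `station_id`, `lat`, `lon`.
#' @param cutoff_km tree cut height in kilometres (default 10, merging
#'   co-located urban sites while leaving isolated sites independent).
#' @return an object of class `cluster_assignment`: list with
#'   `cluster_of` (named character vector station_id -> cluster_id) and
#'   `centroids` (data.frame cluster_id, lat, lon, n_stations).
#' @export
cluster_stations <- function(stations, cutoff_km = 10) {
  stopifnot(all(c("station_id", "lat", "lon") %in% names(stations)),
            cutoff_km > 0)
  if (nrow(stations) < 1) stop("need at least one station")
  if (any(is.na(stations$lat)) || any(is.na(stations$lon)) ||
      any(abs(stations$lat) > 90) || any(abs(stations$lon) > 180))
    stop("invalid station coordinates")
  st <- stations[order(stations$station_id), , drop = FALSE]
  if (nrow(st) == 1) {
    memb <- stats::setNames(1L, st$station_id)
  } else {
    d_km <- geosphere::distm(cbind(st$lon, st$lat),
                             fun = geosphere::distHaversine) / 1000
    hc <- stats::hclust(stats::as.dist(d_km), method = "average")
    memb <- stats::cutree(hc, h = cutoff_km)
    names(memb) <- st$station_id
  }
  # relabel clusters by order of first member (lexicographic station order)
  first_seen <- memb[!duplicated(memb)]
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  memb <- relabel[as.character(memb)]
  ids <- sprintf("C%03d", memb)
  cluster_of <- stats::setNames(ids, st$station_id)
  centroids <- do.call(rbind, lapply(sort(unique(ids)), function(cl) {
    m <- st[ids == cl, , drop = FALSE]
    data.frame(cluster_id = cl, lat = mean(m$lat), lon = mean(m$lon),
               n_stations = nrow(m), stringsAsFactors = FALSE)
  }))
  structure(list(cluster_of = cluster_of, centroids = centroids),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  n <- length(x$cluster_of)
  k <- nrow(x$centroids)
  cat("Cluster assignment:", n, "stations ->", k, "clusters (",
      sum(x$centroids$n_stations == 1), "independent )\n")
  invisible(x)
}

#' Mean of the values above the fourth quartile
#'
#' Mean of values strictly greater than the 75th percentile (linear
#' interpolation between order statistics). When no value exceeds the
#' quartile (all values tie at the maximum), the mean of the maximal
#' values is returned.
#'
#' @param values numeric vector, at least one non-missing value.
#' @return the fourth-quartile-averaged mean.
#' @export
fourth_quartile_mean <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to average")
  q3 <- stats::quantile(values, 0.75, names = FALSE, type = 7)
  top <- values[values > q3]
  if (!length(top)) top <- values[values == max(values)]
  mean(top)
}

#' Integrate quality-controlled hourly records into a semi-monthly panel
#'
#' For each cluster and semi-monthly window, all valid hours of all member
#' stations are pooled into one sample: `values_all` is the pooled mean,
#' `values_q4` the [fourth_quartile_mean()] of the pooled hours, and
#' completeness the fraction of expected station-hours that were valid.
#' Cells below `min_completeness` are set missing in both variants.
#'
#' @param records cleaned long data.frame (one pollutant, or pass
#'   `pollutant` to filter).
#' @param clusters a [cluster_stations()] result or named vector.
#' @param pollutant optional pollutant code filter.
#' @param min_completeness completeness threshold in \[0, 1\].
#' @return a [semimonthly_panel()].
#' @export
integrate_semimonthly <- function(records, clusters, pollutant = NULL,
                                  min_completeness = 0.5) {
  cluster_of <- as_cluster_map(clusters)
  if (!is.null(pollutant))
    records <- records[records$pollutant == pollutant, , drop = FALSE]
  if (length(unique(records$pollutant)) > 1)
    stop("records span several pollutants; pass `pollutant` to select one")
  sm <- semimonth_of(records$timestamp)
  years <- sort(unique(sm$year))
  periods <- data.frame(year = rep(years, each = 24L),
                        period_index = rep(1:24, length(years)))
  pkey <- match(paste(sm$year, sm$period_index),
                paste(periods$year, periods$period_index))
  cl <- cluster_of[records$station_id]
  cluster_ids <- sort(unique(cl))
  ckey <- match(cl, cluster_ids)
  cell <- (ckey - 1L) * nrow(periods) + pkey
  ncell <- nrow(periods) * length(cluster_ids)

  valid <- !is.na(records$value)
  sums <- rowsum_full(records$value[valid], cell[valid], ncell)
  counts <- rowsum_full(rep(1, sum(valid)), cell[valid], ncell)
  station_hours <- rowsum_full(rep(1, length(cell)), cell, ncell)

  values_all <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  values_q4 <- rep(NA_real_, ncell)
  have <- which(counts > 0)
  split_vals <- split(records$value[valid], cell[valid])
  q4 <- vapply(split_vals, fourth_quartile_mean, numeric(1))
  values_q4[as.integer(names(split_vals))] <- q4
  completeness <- ifelse(station_hours > 0, counts / station_hours, 0)

  dim(values_all) <- dim(values_q4) <- dim(completeness) <-
    c(nrow(periods), length(cluster_ids))
  low <- completeness < min_completeness
  values_all[low] <- NA_real_
  values_q4[low] <- NA_real_
  semimonthly_panel(cluster_ids, periods, values_all, values_q4, completeness)
}

rowsum_full <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Drop clusters with salient data gaps from a panel
#'
#' @param panel a [semimonthly_panel()].
#' @param max_missing_fraction clusters whose missing-cell fraction in the
#'   all-value matrix exceeds this are removed.
#' @return the reduced panel, with attribute `dropped` listing removed
#'   cluster ids.
#' @export
exclude_gappy <- function(panel, max_missing_fraction = 0.2) {
  frac <- colMeans(is.na(panel$values_all))
  keep <- frac <= max_missing_fraction
  if (!any(keep))
    stop("all clusters exceed the gap threshold (",
         max_missing_fraction, "); raise max_missing_fraction")
  out <- semimonthly_panel(panel$cluster_ids[keep], panel$periods,
                           panel$values_all[, keep, drop = FALSE],
                           panel$values_q4[, keep, drop = FALSE],
                           panel$completeness[, keep, drop = FALSE])
  attr(out, "dropped") <- panel$cluster_ids[!keep]
  out
}
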