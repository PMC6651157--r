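# Independent oracles and small fixture builders used across the suite.

# Numerical maximization of the sample covariance between projections:
# max over unit vectors u, v of cov(X u, Y v). Independent of the SVD
# route: uses stats::cov and general-purpose optimization with restarts.
oracle_max_cov <- function(X, Y, n_restarts = 5, seed = 1) {
  C <- stats::cov(X, Y)
  p <- nrow(C); q <- ncol(C)
  f <- function(par) {
    a <- par[1:p]; b <- par[(p + 1):(p + q)]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) return(0)
    -as.numeric(crossprod(a, C %*% b)) / (na * nb)
  }
  gr <- function(par) {
    a <- par[1:p]; b <- par[(p + 1):(p + q)]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    val <- as.numeric(crossprod(a, C %*% b))
    da <- as.numeric(C %*% b) / (na * nb) - val * a / (na^3 * nb)
    db <- as.numeric(crossprod(C, a)) / (na * nb) - val * b / (na * nb^3)
    -c(da, db)
  }
  set.seed(seed)
  best <- -Inf
  for (r in seq_len(n_restarts)) {
    par0 <- stats::rnorm(p + q)
    opt <- stats::optim(par0, f, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- max(best, -opt$value)
  }
  best
}

# R^2 of OLS with intercept, via lm (independent of the package's
# pseudoinverse route)
r2_lm <- function(y, X) {
  if (NCOL(X) == 0) return(0)
  summary(stats::lm(y ~ ., data = data.frame(y = y, as.data.frame(X))))$r.squared
}

# All permutations of 1..p (p small)
all_orderings <- function(p) {
  g <- as.matrix(expand.grid(rep(list(seq_len(p)), p)))
  g[apply(g, 1, function(r) length(unique(r)) == p), , drop = FALSE]
}

# LMG by direct averaging of sequential R^2 gains over all p! orderings
brute_lmg <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  ords <- all_orderings(p)
  gains <- matrix(0, nrow(ords), p)
  for (i in seq_len(nrow(ords))) {
    ord <- ords[i, ]
    prev <- 0
    for (k in seq_len(p)) {
      cur <- r2_lm(y, X[, ord[1:k], drop = FALSE])
      gains[i, ord[k]] <- cur - prev
      prev <- cur
    }
  }
  colMeans(gains)
}

# sequential gain of regressor j in a given ordering, for bracket checks
sequential_gains <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  ords <- all_orderings(p)
  gains <- matrix(0, nrow(ords), p)
  for (i in seq_len(nrow(ords))) {
    ord <- ords[i, ]
    prev <- 0
    for (k in seq_len(p)) {
      cur <- r2_lm(y, X[, ord[1:k], drop = FALSE])
      gains[i, ord[k]] <- cur - prev
      prev <- cur
    }
  }
  gains
}

# small long-format hourly fixture writer
write_hourly_fixture <- function(rows, path) {
  header <- "station_id,lat,lon,pollutant,timestamp,value"
  writeLines(c(header, rows), path)
  path
}

# a pair of regressors with an exact given sample correlation
regressors_with_cor <- function(n, r, seed = 1) {
  set.seed(seed)
  Z <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * 2), n, 2))))[, 2:3]
  x1 <- Z[, 1]
  x2 <- r * Z[, 1] + sqrt(1 - r^2) * Z[, 2]
  cbind(x1 = x1 * sqrt(n - 1), x2 = x2 * sqrt(n - 1))
}

# QC operating characteristics on one seeded synthetic network
qc_operating_stats <- function(seed, n_clusters = 4, years = 2,
                               outlier_rate = 5e-4) {
  cfg <- synthetic_config(n_clusters = n_clusters, years = years,
                          outlier_rate = outlier_rate, seed = seed)
  net <- generate_network(cfg)
  qc <- apply_qc(net$records, cluster_stations(net$stations))
  tr <- net$truth$outliers
  grid <- sort(unique(net$records$timestamp))
  flagged <- is.na(qc$records$value) & !is.na(net$records$value)
  key <- paste(net$records$station_id, net$records$pollutant,
               match(net$records$timestamp, grid))
  planted <- paste(tr$station_id, tr$pollutant, tr$hour_index)
  hit <- planted %in% key[flagged]
  list(n_planted = nrow(tr), recall = mean(hit),
       fpr = (sum(flagged) - sum(hit)) / sum(!is.na(net$records$value)))
}

# end-to-end coupled-scenario pipeline run; returns the qualitative pattern
scenario_run <- function(seed, B = 199, coupled = TRUE) {
  loadings <- NULL
  if (!coupled) {
    loadings <- matrix(0, 24, 3, dimnames = list(NULL, c("PM25", "SO2", "NO2")))
  }
  res <- run_pipeline(list(
    seed = seed,
    simulate = list(n_clusters = 24, stations_per_cluster = 1, years = 4,
                    outlier_rate = 0, missing_rate = 0.03,
                    trend_by_pollutant = c(PM25 = 0, SO2 = 0, NO2 = 0),
                    shared_mode = list(loadings = loadings, ar1 = 0.3, sd = 8),
                    regional = list(ar1 = 0.3,
                                    sd = c(PM25 = 4, SO2 = 2.5, NO2 = 3))),
    mca = list(K = 4, B = B)), outdir = tempfile(), quiet = TRUE)
  list(pm_so_sig = unname(res$mca$PM25_SO2$significant[1]),
       pm_no_sig = unname(res$mca$PM25_NO2$significant[1]),
       top_lmg = res$attribution$table$regressor[
         which.max(res$attribution$table$lmg)],
       res = res)
}
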