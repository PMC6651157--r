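PIPELINE_KEYS <- list(
  top = c("seed", "simulate", "input", "qc", "aggregate", "trends", "mca",
          "attribution", "artifacts"),
  simulate = c("n_clusters", "stations_per_cluster", "years", "start_year",
               "baseline_by_pollutant", "seasonal_amplitude",
               "trend_by_pollutant", "shared_mode", "regional", "common",
               "noise",
               "outlier_rate",
               "outlier_magnitude", "outlier_sign", "missing_rate"),
  qc = c("deviation_multiplier_default", "deviation_multiplier_by_pollutant",
         "sd_window", "gradient_bounds", "sd_floor"),
  aggregate = c("cutoff_km", "min_completeness", "max_missing_fraction"),
  trends = c("region_map", "deseasonalized"),
  mca = c("K", "B"),
  attribution = c("tau", "n_components"))

#' Validate a pipeline configuration
#'
#' Structural and range validation of every stage block; unknown keys are
#' rejected.
#'
#' @param config a nested list, or the path of a YAML file holding one.
#' @return character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  errs <- character()
  say <- function(...) errs[[length(errs) + 1]] <<- paste0(...)
  unknown <- setdiff(names(config), PIPELINE_KEYS$top)
  for (k in unknown) say("unknown top-level key: ", k)
  for (block in intersect(names(PIPELINE_KEYS), names(config))) {
    bad <- setdiff(names(config[[block]]), PIPELINE_KEYS[[block]])
    for (k in bad) say("unknown key in '", block, "': ", k)
  }
  num_in <- function(block, key, lo, hi, lo_open = FALSE) {
    v <- config[[block]][[key]]
    if (is.null(v)) return(invisible())
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < lo || v > hi || (lo_open && v <= lo))
      say(block, "$", key, " out of range [", lo, ", ", hi, "]: ",
          paste(v, collapse = ","))
  }
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed)))
    say("seed must be an integer")
  num_in("simulate", "n_clusters", 1, 1e6)
  num_in("simulate", "years", 1, 100)
  num_in("simulate", "outlier_rate", 0, 1)
  num_in("simulate", "missing_rate", 0, 1)
  m <- config$qc$deviation_multiplier_default
  if (!is.null(m) && (!is.numeric(m) || m <= 0))
    say("qc$deviation_multiplier_default must be positive")
  gb <- config$qc$gradient_bounds
  if (!is.null(gb) && (length(gb) != 2 || gb[1] >= gb[2]))
    say("qc$gradient_bounds must be an interval (lower < upper)")
  num_in("qc", "sd_floor", 0, Inf)
  num_in("aggregate", "cutoff_km", 0, Inf, lo_open = TRUE)
  num_in("aggregate", "min_completeness", 0, 1)
  num_in("aggregate", "max_missing_fraction", 0, 1)
  num_in("mca", "K", 1, 1e3)
  num_in("mca", "B", 19, 1e6)
  num_in("attribution", "tau", 0, 1, lo_open = TRUE)
  num_in("attribution", "n_components", 1, 100)
  errs
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}

#' Run the full analysis chain
#'
#' simulate (or load) -> QC -> cluster/aggregate -> trends -> MCA ->
#' attribution, writing every stage artifact (panels, anomaly fields,
#' trend tables, MCA and attribution results) plus a manifest with the
#' config hash and seed under `outdir`. Reruns with the same config are
#' bit-identical.
#'
#' @param config nested configuration list or YAML path (see
#'   [validate_config()]); all blocks optional, defaults applied.
#' @param outdir output directory, created if needed.
#' @param quiet suppress per-stage messages.
#' @return invisible list with every stage result (`stations`,
#'   `clusters`, `qc_report`, `panels`, `trend_table`, `mca`,
#'   `attribution`, `manifest`).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("aqmca_run_"),
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (!quiet) message("[aqmca] ", ...)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # --- simulate or load -------------------------------------------------
  if (!is.null(config$input$hourly_csv)) {
    records <- read_hourly(config$input$hourly_csv)
    stations <- unique(records[c("station_id", "lat", "lon")])
    truth <- NULL
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- stage_seed(seed, 1)
    cfg <- do.call(synthetic_config, sim_args)
    net <- generate_network(cfg)
    records <- net$records; stations <- net$stations; truth <- net$truth
  }
  log_msg("records: ", nrow(records), " rows, ",
          length(unique(records$station_id)), " stations")
  utils::write.csv(stations, file.path(outdir, "stations.csv"),
                   row.names = FALSE)

  # --- cluster + qc -----------------------------------------------------
  agg <- config$aggregate
  cutoff <- agg$cutoff_km %||% 10
  clusters <- cluster_stations(stations, cutoff)
  log_msg("clusters: ", nrow(clusters$centroids))
  qc_args <- config$qc %||% list()
  qc_cfg <- do.call(qc_config, qc_args)
  qc_out <- apply_qc(records, clusters, qc_cfg)
  for (g in names(qc_out$report))
    log_msg("qc ", g, ": removed ",
            sprintf("%.2f%%", 100 * qc_out$report[[g]]$removed_fraction))
  write_result_json(qc_out$report, file.path(outdir, "qc_report.json"))

  # --- integrate --------------------------------------------------------
  pollutants <- intersect(POLLUTANTS, unique(records$pollutant))
  panels <- list()
  for (g in pollutants) {
    p <- integrate_semimonthly(qc_out$records, clusters, pollutant = g,
                               min_completeness = agg$min_completeness %||% 0.5)
    p <- exclude_gappy(p, agg$max_missing_fraction %||% 0.2)
    panels[[g]] <- p
    write_panel(p, file.path(outdir, paste0("panel_", g, ".csv")))
  }

  # --- trends -----------------------------------------------------------
  region_map <- config$trends$region_map
  trend_rows <- list()
  for (g in pollutants) for (v in c("all", "q4")) {
    rm_g <- if (is.null(region_map))
      stats::setNames(rep("ALL", length(panels[[g]]$cluster_ids)),
                      panels[[g]]$cluster_ids)
    else unlist(region_map)[panels[[g]]$cluster_ids]
    tr <- regional_trend(panels[[g]], rm_g, v)
    tr$pollutant <- g
    trend_rows[[paste(g, v)]] <- tr
  }
  trend_table <- do.call(rbind, trend_rows)
  rownames(trend_table) <- NULL
  utils::write.csv(trend_table, file.path(outdir, "trend_table.csv"),
                   row.names = FALSE)

  # --- mca --------------------------------------------------------------
  anoms <- lapply(pollutants, function(g)
    deseasonalize(panels[[g]]$values_all, panels[[g]]$periods,
                  panels[[g]]$cluster_ids, g))
  names(anoms) <- pollutants
  mca_cfg <- config$mca
  mca_out <- list()
  if (all(c("PM25", "SO2", "NO2") %in% pollutants)) {
    for (other in c("SO2", "NO2")) {
      K <- min(mca_cfg$K %||% 6, length(anoms$PM25$ids),
               length(anoms[[other]]$ids))
      res <- permutation_significance(
        anoms$PM25, anoms[[other]], K = K, B = mca_cfg$B %||% 499,
        seed = stage_seed(seed, if (other == "SO2") 2 else 3))
      mca_out[[paste0("PM25_", other)]] <- res
      log_msg("MCA PM25~", other, ": SCF1 = ",
              sprintf("%.1f%%", 100 * res$scf[1]),
              if (res$significant[1]) " (significant)" else " (ns)")
      write_result_json(
        res[c("singular_values", "scf", "upci", "significant",
              "ec_correlation", "B")],
        file.path(outdir, paste0("mca_PM25_", other, ".json")))
      maps <- data.frame(id = c(res$left_ids, res$right_ids),
                         field = rep(c("PM25", other),
                                     c(length(res$left_ids),
                                       length(res$right_ids))),
                         homogeneous = c(res$homo_left[1, ],
                                         res$homo_right[1, ]),
                         heterogeneous = c(res$hetero_right[1, ],
                                           res$hetero_left[1, ]))
      utils::write.csv(maps,
                       file.path(outdir,
                                 paste0("mca_maps_PM25_", other, ".csv")),
                       row.names = FALSE)
    }
  }

  # --- attribution ------------------------------------------------------
  attribution <- NULL
  if (length(mca_out) == 2) {
    att_cfg <- config$attribution
    tau <- att_cfg$tau %||% 0.5
    nc <- att_cfg$n_components %||% 2
    pm_so <- mca_out$PM25_SO2
    pm_no <- mca_out$PM25_NO2
    # widen the threshold stepwise if a map is too peaked to yield enough
    # columns for the requested number of components
    hotspot_min <- function(map, tau, min_n) {
      repeat {
        m <- select_hotspot(map, tau)
        if (length(m$ids) >= min_n || tau <= 0.05) return(m)
        tau <- max(tau - 0.1, 0.05)
      }
    }
    y_mask <- hotspot_min(pm_so$homo_left[1, ], tau, 1)
    so_mask <- hotspot_min(pm_so$homo_right[1, ], tau, nc)
    no_mask <- hotspot_min(pm_no$homo_right[1, ], tau, nc)
    y <- regional_mean_series(anoms$PM25, y_mask)
    pca_so <- field_pca(anoms$SO2, so_mask, nc)
    pca_no <- field_pca(anoms$NO2, no_mask, nc)
    regs <- cbind(pca_so$scores, pca_no$scores)
    colnames(regs) <- c(paste0("SO2_PC", seq_len(nc)),
                        paste0("NO2_PC", seq_len(nc)))
    expl <- stats::setNames(c(pca_so$explained, pca_no$explained),
                            colnames(regs))
    attribution <- fit_attribution(y, regs, explained_variance = expl)
    log_msg("attribution: R^2 = ", sprintf("%.2f", attribution$r_squared),
            ", top LMG = ",
            attribution$table$regressor[which.max(attribution$table$lmg)])
    write_result_json(c(attribution["r_squared"], attribution["n"],
                        list(table = attribution$table)),
                      file.path(outdir, "attribution.json"))
    utils::write.csv(attribution$table,
                     file.path(outdir, "attribution_table.csv"),
                     row.names = FALSE)
  }

  # --- manifest ---------------------------------------------------------
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("aqmca")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_records = nrow(records),
    n_clusters = nrow(clusters$centroids),
    qc_removed = lapply(qc_out$report, `[[`, "removed_fraction"),
    clusters_used = lapply(panels, function(p) length(p$cluster_ids)))
  write_result_json(manifest, file.path(outdir, "manifest.json"))
  log_msg("artifacts written to ", outdir)
  invisible(list(stations = stations, clusters = clusters,
                 qc_report = qc_out$report, records = qc_out$records,
                 panels = panels, trend_table = trend_table,
                 anomalies = anoms, mca = mca_out,
                 attribution = attribution, truth = truth,
                 manifest = manifest, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
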