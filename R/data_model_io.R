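#' @keywords internal
"_PACKAGE"

POLLUTANTS <- c("PM25", "SO2", "NO2")

#' Read hourly station records from long-format CSV
#'
#' Parses a long-format delimited file of hourly per-station pollutant
#' observations. Expected columns (header names): `station_id`, `lat`,
#' `lon`, `pollutant`, `timestamp` (ISO-8601, hourly, timezone-naive
#' local time), `value` (concentration in ug/m3, empty field = missing).
#'
#' Missing values are preserved as `NA`, never coerced to zero. Rows with
#' negative values, out-of-range coordinates, non-hourly timestamps or
#' unknown pollutant codes are rejected with an error naming the offending
#' data row.
#'
#' @param path path to a CSV file.
#' @param pollutant optional character vector; keep only these pollutants.
#'   Unknown pollutant codes excluded by the filter are silently dropped.
#' @return a `data.frame` with columns `station_id` (character), `lat`,
#'   `lon` (numeric degrees), `pollutant` (character), `timestamp`
#'   (POSIXct, UTC-encoded naive local time) and `value` (numeric, ug/m3).
#' @export
read_hourly <- function(path, pollutant = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  required <- c("station_id", "lat", "lon", "pollutant", "timestamp", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) return(empty_hourly())
  df$station_id <- as.character(df$station_id)
  df$pollutant <- as.character(df$pollutant)
  if (!is.null(pollutant)) df <- df[df$pollutant %in% pollutant, , drop = FALSE]
  if (nrow(df) == 0) return(empty_hourly())
  bad <- which(!(df$pollutant %in% POLLUTANTS))
  if (length(bad))
    stop("unknown pollutant '", df$pollutant[bad[1]], "' at data row ", bad[1])
  val <- trimws(df$value)
  val[val == ""] <- NA_character_
  num <- suppressWarnings(as.numeric(val))
  bad <- which(!is.na(val) & is.na(num))
  if (length(bad))
    stop("malformed value '", val[bad[1]], "' at data row ", bad[1])
  bad <- which(!is.na(num) & num < 0)
  if (length(bad))
    stop("negative concentration ", num[bad[1]], " at data row ", bad[1])
  df$value <- num
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable timestamp '", df$timestamp[bad[1]], "' at data row ", bad[1])
  lt <- as.POSIXlt(ts)
  bad <- which(lt$min != 0 | lt$sec != 0)
  if (length(bad))
    stop("timestamp not on the hour at data row ", bad[1])
  df$timestamp <- ts
  bad <- which(df$lat < -90 | df$lat > 90 | df$lon < -180 | df$lon > 180 |
                 is.na(df$lat) | is.na(df$lon))
  if (length(bad))
    stop("coordinates out of range at data row ", bad[1])
  key <- paste(df$station_id, df$pollutant, format(df$timestamp, "%Y%m%d%H"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (station, pollutant, timestamp) key at data row ", dup[1])
  rownames(df) <- NULL
  df[required]
}

empty_hourly <- function() {
  data.frame(station_id = character(), lat = numeric(), lon = numeric(),
             pollutant = character(),
             timestamp = as.POSIXct(character(), tz = "UTC"),
             value = numeric(), stringsAsFactors = FALSE)
}

#' Write hourly records to long-format CSV
#'
#' Inverse of [read_hourly()]; missing values are written as empty fields.
#'
#' @param records data.frame as returned by [read_hourly()] or
#'   [generate_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hourly <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  out$value <- ifelse(is.na(out$value), "", num_to_chr(out$value))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# full-precision numeric formatting so CSV round-trips are bit-exact
num_to_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Construct a semi-monthly panel object
#'
#' A panel holds cluster-level semi-monthly integrated concentrations:
#' the all-value mean, the fourth-quartile-averaged mean (mean over values
#' above the within-window 75th percentile) and a completeness fraction,
#' each as a periods x clusters matrix.
#'
#' @param cluster_ids character vector of cluster identifiers (columns).
#' @param periods data.frame with integer columns `year` and
#'   `period_index` (1..24; two windows per calendar month).
#' @param values_all,values_q4 numeric matrices (periods x clusters), ug/m3.
#' @param completeness numeric matrix in \[0, 1\], valid-hour fraction.
#' @return an object of class `semimonthly_panel`.
#' @export
semimonthly_panel <- function(cluster_ids, periods, values_all, values_q4,
                              completeness) {
  cluster_ids <- as.character(cluster_ids)
  stopifnot(is.data.frame(periods),
            all(c("year", "period_index") %in% names(periods)))
  if (!all(periods$period_index %in% 1:24))
    stop("period_index must be in 1..24")
  dims <- c(nrow(periods), length(cluster_ids))
  for (m in list(values_all, values_q4, completeness))
    if (!identical(dim(m), as.integer(dims)))
      stop("panel matrices must be ", dims[1], " x ", dims[2])
  cc <- completeness[!is.na(completeness)]
  if (length(cc) && (min(cc) < 0 || max(cc) > 1))
    stop("completeness must lie in [0, 1]")
  dn <- list(NULL, cluster_ids)
  dimnames(values_all) <- dimnames(values_q4) <- dimnames(completeness) <- dn
  structure(list(cluster_ids = cluster_ids,
                 periods = periods[c("year", "period_index")],
                 values_all = values_all, values_q4 = values_q4,
                 completeness = completeness),
            class = "semimonthly_panel")
}

#' @export
print.semimonthly_panel <- function(x, ...) {
  cat("Semi-monthly panel:", nrow(x$periods), "periods x",
      length(x$cluster_ids), "clusters\n")
  cat("  years:", paste(range(x$periods$year), collapse = "-"),
      " missing cells:", sum(is.na(x$values_all)), "\n")
  invisible(x)
}

#' Write a semi-monthly panel to CSV
#'
#' Wide CSV, one column per cluster, stacked by variable
#' (`all`, `q4`, `completeness`). Values are written with full precision so
#' that [read_panel()] reproduces the panel bit-exactly; missing cells are
#' empty fields.
#'
#' @param panel a [semimonthly_panel()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "semimonthly_panel"))
  blocks <- list(all = panel$values_all, q4 = panel$values_q4,
                 completeness = panel$completeness)
  rows <- lapply(names(blocks), function(v) {
    m <- blocks[[v]]
    chr <- matrix(num_to_chr(as.numeric(m)), nrow = nrow(m))
    data.frame(variable = v, year = panel$periods$year,
               period_index = panel$periods$period_index,
               chr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:3)] <- panel$cluster_ids
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a semi-monthly panel written by [write_panel()]
#'
#' @param path CSV path.
#' @return a [semimonthly_panel()] object.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- setdiff(names(df), c("variable", "year", "period_index"))
  get_block <- function(v) {
    b <- df[df$variable == v, , drop = FALSE]
    as.matrix(b[ids])
  }
  first <- df[df$variable == "all", , drop = FALSE]
  semimonthly_panel(ids,
                    data.frame(year = first$year,
                               period_index = first$period_index),
                    get_block("all"), get_block("q4"),
                    get_block("completeness"))
}

#' Construct an anomaly field
#'
#' A deseasonalized time x station (or cluster) matrix for one pollutant,
#' together with the 24-row semi-month-of-year climatology that was removed.
#'
#' @param pollutant pollutant code.
#' @param periods data.frame(year, period_index).
#' @param ids station/cluster identifiers (columns).
#' @param anomalies periods x ids matrix of anomalies, ug/m3.
#' @param climatology 24 x ids matrix of semi-month-of-year means, ug/m3.
#' @return an object of class `anomaly_field`.
#' @export
anomaly_field <- function(pollutant, periods, ids, anomalies, climatology) {
  ids <- as.character(ids)
  stopifnot(nrow(anomalies) == nrow(periods), ncol(anomalies) == length(ids),
            nrow(climatology) == 24, ncol(climatology) == length(ids))
  dimnames(anomalies) <- list(NULL, ids)
  dimnames(climatology) <- list(NULL, ids)
  structure(list(pollutant = pollutant,
                 periods = periods[c("year", "period_index")],
                 ids = ids, anomalies = anomalies, climatology = climatology),
            class = "anomaly_field")
}

#' @export
print.anomaly_field <- function(x, ...) {
  cat("Anomaly field (", x$pollutant, "): ", nrow(x$anomalies), " periods x ",
      length(x$ids), " series\n", sep = "")
  invisible(x)
}

#' Write an anomaly field to CSV (wide, one column per series)
#' @param field an [anomaly_field()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anomaly_field <- function(field, path) {
  m <- field$anomalies
  chr <- matrix(num_to_chr(as.numeric(m)), nrow = nrow(m))
  out <- data.frame(year = field$periods$year,
                    period_index = field$periods$period_index,
                    chr, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- field$ids
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize an analysis result object to JSON
#'
#' Matrices become row-major nested arrays with their dimnames preserved.
#'
#' @param x a result list (e.g. from [compute_mca()] or [fit_attribution()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
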