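fmt_utc <- function(t) {
  as.POSIXct(t, origin = "1970-01-01", tz = "UTC")
}

#' Write / read a Qstarz-style GPS CSV
#'
#' The logger dialect: columns INDEX, UTC DATE (yyyy/mm/dd), UTC TIME
#' (HH:MM:SS), LATITUDE, LONGITUDE, SPEED (km/h). Speed is the logged value
#' when present, else derived from consecutive fixes.
#'
#' @param track A \code{gps_track}.
#' @param path Output/input CSV path.
#' @return \code{write_qstarz_csv}: the path, invisibly.
#' @export
write_qstarz_csv <- function(track, path) {
  sp <- track$speed
  if (all(is.na(sp))) sp <- derived_speed_kmh(track)
  sp[is.na(sp)] <- 0
  df <- data.frame(
    INDEX = seq_len(nrow(track)),
    `UTC DATE` = format(fmt_utc(track$time), "%Y/%m/%d"),
    `UTC TIME` = format(fmt_utc(track$time), "%H:%M:%S"),
    LATITUDE = sprintf("%.6f", track$lat),
    LONGITUDE = sprintf("%.6f", track$lon),
    SPEED = sprintf("%.3f", sp),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qstarz_csv
#' @param device,id Identifiers attached to the returned track.
#' @return \code{read_qstarz_csv}: a \code{gps_track}.
#' @export
read_qstarz_csv <- function(path, device = "qstarz", id = "") {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("UTC DATE", "UTC TIME", "LATITUDE", "LONGITUDE")
  if (!all(need %in% names(df))) stop("not a Qstarz-style CSV: missing columns")
  tm <- as.numeric(as.POSIXct(
    paste(df[["UTC DATE"]], df[["UTC TIME"]]),
    format = "%Y/%m/%d %H:%M:%S", tz = "UTC"
  ))
  speed <- if ("SPEED" %in% names(df)) as.numeric(df[["SPEED"]]) else NULL
  gps_track(tm, as.numeric(df$LATITUDE), as.numeric(df$LONGITUDE),
    speed = speed, device = device, id = id
  )
}

#' Read a generic GPS CSV with a column mapping
#'
#' @param path CSV path.
#' @param mapping Named list mapping \code{time}, \code{lat}, \code{lon} and
#'   optionally \code{speed} to column names in the file. \code{time} may be
#'   epoch seconds or an ISO datetime string.
#' @param device,id Identifiers attached to the returned track.
#' @return A \code{gps_track}.
#' @export
read_gps_csv <- function(path,
                         mapping = list(time = "time", lat = "lat", lon = "lon"),
                         device = "gps", id = "") {
  df <- utils::read.csv(path, check.names = FALSE)
  for (f in c("time", "lat", "lon")) {
    if (!mapping[[f]] %in% names(df)) {
      stop(sprintf("mapped column '%s' for %s not found", mapping[[f]], f))
    }
  }
  tm <- df[[mapping$time]]
  if (!is.numeric(tm)) {
    tm <- as.numeric(as.POSIXct(tm, tz = "UTC"))
  }
  speed <- if (!is.null(mapping$speed) && mapping$speed %in% names(df)) {
    as.numeric(df[[mapping$speed]])
  } else {
    NULL
  }
  gps_track(tm, as.numeric(df[[mapping$lat]]), as.numeric(df[[mapping$lon]]),
    speed = speed, device = device, id = id
  )
}

#' Write / read a raw accelerometer CSV
#'
#' Plain CSV with columns \code{time} (epoch seconds), \code{ax}, \code{ay},
#' \code{az} (g); the sampling rate and placement travel in a \code{#}-prefixed
#' header line so a stream round-trips losslessly.
#'
#' @param stream An \code{accel_stream}.
#' @param path CSV path.
#' @return \code{write_accel_csv}: the path invisibly;
#'   \code{read_accel_csv}: an \code{accel_stream}.
#' @export
write_accel_csv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# rate=%g placement=%s device=%s start=%.3f",
    stream$rate, stream$placement, stream$device, stream$start
  ), con)
  df <- data.frame(
    time = sprintf("%.4f", stream_times(stream)),
    ax = sprintf("%.5f", stream$data[, 1]),
    ay = sprintf("%.5f", stream$data[, 2]),
    az = sprintf("%.5f", stream$data[, 3])
  )
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- list(rate = 30, placement = "wrist", device = "accel", start = NA)
  if (startsWith(hdr, "#")) {
    kv <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
    for (pair in strsplit(kv, "=")) meta[[pair[1]]] <- pair[2]
  }
  df <- utils::read.csv(path, comment.char = "#")
  start <- if (is.na(meta$start)) df$time[1] else as.numeric(meta$start)
  accel_stream(
    data = cbind(df$ax, df$ay, df$az),
    rate = as.numeric(meta$rate),
    start = start,
    placement = meta$placement,
    device = meta$device
  )
}

#' Write / read a diary CSV
#' @param diary A \code{diary_table}.
#' @param path CSV path.
#' @export
write_diary_csv <- function(diary, path) {
  utils::write.csv(as.data.frame(diary), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diary_csv
#' @export
read_diary_csv <- function(path) {
  out <- utils::read.csv(path)
  out$date <- as.Date(out$date)
  class(out) <- c("diary_table", "data.frame")
  out
}

#' Write / read ground truth as JSON
#' @param truth A \code{day_truth}.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  payload <- truth
  class(payload) <- NULL
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$intervals <- as.data.frame(raw$intervals)
  raw$trips <- as.data.frame(raw$trips)
  if (!is.null(raw$detectable)) raw$detectable <- as.data.frame(raw$detectable)
  class(raw) <- "day_truth"
  raw
}

#' Write / read a scenario configuration as YAML
#' @param config A \code{scenario_config}.
#' @param path YAML path.
#' @export
write_scenario_yaml <- function(config, path) {
  payload <- unclass(config)
  payload$start_date <- as.character(payload$start_date)
  payload$poi_list <- as.list(payload$poi_list)
  # named vectors must become maps to survive the YAML round trip
  payload$gps_interval <- as.list(payload$gps_interval)
  payload$accel_rate <- as.list(payload$accel_rate)
  yaml::write_yaml(payload, path, precision = 17) # lossless doubles
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$start_date <- as.Date(raw$start_date)
  raw$poi_list <- as.data.frame(raw$poi_list)
  for (f in c("gps_interval", "accel_rate")) raw[[f]] <- unlist(raw[[f]])
  do.call(scenario_config, raw[names(raw) %in% names(formals(scenario_config))])
}
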