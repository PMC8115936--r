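# CSV conversion of the streams. Dialect: comma separator, "." decimal,
# ISO-8601 UTC timestamps, header row. Sample timestamps are derived as
# utc_start + index / sample_rate (the recorder stores periodic clock
# anchors, not per-sample clocks).

#' Convert an ESF recording to tabular chunks
#'
#' Splits a recording into chunks of at most `chunkSeconds` (200 s by
#' default, the duration of one converted field file) and returns one data
#' frame per chunk with a numeric Unix timestamp column and the six channel
#' columns. Row-binding the chunks reproduces the recording.
#'
#' @param rec an [ESFRecording-class].
#' @param chunkSeconds chunk span in seconds (> 0).
#' @return List of data frames with columns `timestamp`, `ch1`..`ch6`.
#' @seealso [writeESFCSV()] for writing the chunks to disk.
#' @export
esfToCSV <- function(rec, chunkSeconds = 200) {
  stopifnot(is(rec, "ESFRecording"), chunkSeconds > 0)
  n <- nrow(rec@samples)
  if (n == 0L) return(list())
  per <- as.integer(ceiling(chunkSeconds * rec@sampleRate))
  starts <- seq(1L, n, by = per)
  lapply(starts, function(s) {
    idx <- s:min(s + per - 1L, n)
    df <- data.frame(
      timestamp = rec@meta@utcStart + (idx - 1) / rec@sampleRate)
    ch <- as.data.frame(rec@samples[idx, , drop = FALSE])
    names(ch) <- paste0("ch", 1:6)
    rownames(ch) <- NULL
    cbind(df, ch)
  })
}

#' Write ESF CSV chunk files
#'
#' One file per chunk, named `esf_<index>.csv`, timestamps formatted as
#' ISO-8601 UTC with sub-second digits.
#'
#' @param rec an [ESFRecording-class].
#' @param dir output directory (created if missing).
#' @param chunkSeconds chunk span, seconds.
#' @return Character vector of file paths, invisibly.
#' @export
writeESFCSV <- function(rec, dir, chunkSeconds = 200) {
  chunks <- esfToCSV(rec, chunkSeconds)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(chunks))
  digits <- max(1, ceiling(log10(rec@sampleRate)))
  for (i in seq_along(chunks)) {
    df <- chunks[[i]]
    df$timestamp <- iso8601(df$timestamp, digits = digits)
    paths[i] <- file.path(dir, sprintf("esf_%04d.csv", i))
    utils::write.csv(df, paths[i], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Read a local weather table
#'
#' Replacement input for an online weather download: a CSV with columns
#' `timestamp` (ISO-8601 UTC or Unix seconds), `humidity` (percent),
#' `uv_index` and `temperature` (degrees C). Rows are sorted by time.
#'
#' @param source CSV file path.
#' @return A [WeatherSeries-class].
#' @export
readWeatherTable <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("timestamp", "humidity", "uv_index", "temperature")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ts <- if (is.numeric(df$timestamp)) {
    as.numeric(df$timestamp)
  } else {
    vapply(df$timestamp, function(s)
      tryCatch(parse_utc(s), error = function(e) NA_real_),
      0, USE.NAMES = FALSE)
  }
  bad <- which(is.na(ts))
  if (length(bad))
    stop(sprintf("unparsable timestamp at line %d: '%s'",
                 bad[1] + 1L, df$timestamp[bad[1]]), call. = FALSE)
  ord <- order(ts)
  weatherSeries(ts[ord], df$humidity[ord], df$uv_index[ord],
                df$temperature[ord])
}

#' Write / read event and truth annotation tables
#'
#' Events and ground-truth annotations share one CSV schema: `label`,
#' `channel`, `t_start`, `t_end`, `n_waggles`, `fundamental_hz`, plus any
#' extra columns present (detector output adds `distance_m`, `mean_power`,
#' `regularity`).
#'
#' @param events data frame of events or truth annotations.
#' @param path CSV file path.
#' @return `writeEventCSV` returns `path` invisibly; `readEventCSV` the
#'   data frame.
#' @export
writeEventCSV <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEventCSV
#' @export
readEventCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
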