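# Aggregation and environment analysis: hourly/daily event counts, daily
# band-power means, rank correlations with weather, seasonal power
# comparison, and a deterministic machine-readable run summary.

#' Per-class event counts over time bins
#'
#' @param events detector or truth event data frame (`label`, `t_start`).
#' @param utcStart Unix seconds anchoring `t_start = 0`.
#' @param binS bin width, seconds (1 h and 2 h are the conventional
#'   choices; 2 h bins merge adjacent 1 h bins additively).
#' @param span optional `c(t0, t1)` Unix-second span to cover (defaults
#'   to the events' span); bins are aligned to the UTC grid.
#' @return Data frame: `bin_start` (Unix s) plus one count column per
#'   class present (`WRS`, `SRS`, `FRS`).
#' @export
hourlyEventCounts <- function(events, utcStart = 0, binS = 3600,
                              span = NULL) {
  labels <- c("WRS", "SRS", "FRS")
  if (is.null(span)) {
    if (!nrow(events)) {
      out <- data.frame(bin_start = numeric(0))
      for (lb in labels) out[[lb]] <- integer(0)
      return(out)
    }
    span <- utcStart + range(events$t_start)
  }
  grid0 <- floor(span[1] / binS) * binS
  edges <- seq(grid0, ceiling((span[2] + 1e-9) / binS) * binS, by = binS)
  if (length(edges) < 2) edges <- c(grid0, grid0 + binS)
  starts <- edges[-length(edges)]
  out <- data.frame(bin_start = starts)
  for (lb in labels) {
    tt <- utcStart + events$t_start[events$label == lb]
    idx <- findInterval(tt, edges, rightmost.closed = FALSE)
    idx <- idx[idx >= 1 & idx <= length(starts)]
    out[[lb]] <- tabulate(idx, nbins = length(starts))
  }
  out
}

#' Daily means of band power
#'
#' For each UTC day, hourly means of each band-power trace are averaged
#' (mean of per-hour values, so partially covered hours carry equal
#' weight).
#'
#' @param traces named list of [BandPowerTrace-class] objects on a common
#'   frame grid.
#' @param utcStart Unix seconds anchoring trace time 0.
#' @return Data frame: `day` (UTC date), `band`, `mean_power`.
#' @export
dailyBandPower <- function(traces, utcStart = 0) {
  rows <- list()
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    if (!length(tr@times)) next
    abs_t <- utcStart + tr@times
    hour_bin <- floor(abs_t / 3600)
    hourly <- tapply(tr@power, hour_bin, mean)
    day_of_hour <- floor(as.numeric(names(hourly)) * 3600 / 86400)
    daily <- tapply(as.numeric(hourly), day_of_hour, mean)
    rows[[nm]] <- data.frame(
      day = format(as.POSIXct(as.numeric(names(daily)) * 86400,
                              origin = "1970-01-01", tz = "UTC"),
                   "%Y-%m-%d"),
      band = nm, mean_power = as.numeric(daily),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(day = character(0),
                                      band = character(0),
                                      mean_power = numeric(0))
  rownames(out) <- NULL
  out
}

#' Rank correlation between two time series
#'
#' Aligns the series by nearest timestamps (pairs farther apart than
#' `toleranceS` are dropped; no interpolation of ranks) and computes
#' Spearman's rank correlation.
#'
#' @param x,y data frames with columns `time` (Unix s) and `value`.
#' @param toleranceS maximum alignment gap, seconds (default 60).
#' @return List with `rho`, `n` (aligned pairs) and `p`.
#' @export
correlateEnvironment <- function(x, y, toleranceS = 60) {
  stopifnot(all(c("time", "value") %in% names(x)),
            all(c("time", "value") %in% names(y)))
  yt <- y$time
  idx <- findInterval(x$time, yt, all.inside = TRUE)
  idx_next <- pmin(idx + 1L, length(yt))
  nearer <- abs(yt[idx_next] - x$time) < abs(yt[idx] - x$time)
  idx[nearer] <- idx_next[nearer]
  gap <- abs(yt[idx] - x$time)
  keep <- which(gap <= toleranceS)
  if (length(keep) < 10)
    stop("insufficient data: fewer than 10 aligned pairs", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x$value[keep], y$value[idx[keep]],
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), n = length(keep), p = ct$p.value)
}

#' Seasonal band-power comparison
#'
#' Percent difference of means, `100 * (mean(a) - mean(b)) / mean(b)`
#' (`b` is the reference, conventionally the winter sample), with a
#' two-sample unequal-variance (Welch) t test.
#'
#' @param a,b numeric samples of band power (e.g. summer and winter).
#' @return List with `percent_diff`, `t`, `df`, `p`.
#' @export
seasonalPowerComparison <- function(a, b) {
  stopifnot(length(a) > 1, length(b) > 1)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(percent_diff = 100 * (mean(a) - mean(b)) / mean(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Summarize one monitoring run
#'
#' Deterministic, machine-readable digest of a run: per-class event
#' counts by hour and day, telemetry daily minima/means/maxima, hourly
#' entrance activity, optional weather correlations, and the full
#' detector-config snapshot for provenance.
#'
#' @param events detector event data frame.
#' @param utcStart Unix seconds anchoring event time 0.
#' @param activity optional passage data frame plus its source trace, as
#'   `list(events = , trace = )`.
#' @param telemetry optional [TelemetrySeries-class].
#' @param weather optional [WeatherSeries-class]; when given together
#'   with telemetry, in-hive and outdoor series are rank-correlated.
#' @param cfg the [detectorConfig()] used for detection.
#' @return List of class `"RunSummary"`.
#' @export
summarizeRun <- function(events, utcStart = 0, activity = NULL,
                         telemetry = NULL, weather = NULL,
                         cfg = detectorConfig()) {
  hourly <- hourlyEventCounts(events, utcStart, binS = 3600)
  daily <- hourlyEventCounts(events, utcStart, binS = 86400)
  out <- list(
    software = list(package = "hiveESF",
                    version = as.character(utils::packageVersion("hiveESF"))),
    config = config_as_list(cfg),
    n_events = nrow(events),
    event_counts = as.list(table(factor(events$label,
                                        levels = c("WRS", "SRS", "FRS")))),
    hourly_counts = hourly,
    daily_counts = daily,
    total_distance_m = sum(events$distance_m, na.rm = TRUE))
  if (!is.null(activity)) {
    out$activity_hourly <- hourlyActivity(activity$events, activity$trace)
    out$n_passages <- nrow(activity$events)
  }
  if (!is.null(telemetry)) {
    df <- as.data.frame(telemetry)
    day <- floor(df$timestamp / 86400)
    stat3 <- function(v) {
      data.frame(day = format(as.POSIXct(unique(day) * 86400,
                                         origin = "1970-01-01", tz = "UTC"),
                              "%Y-%m-%d"),
                 min = as.numeric(tapply(v, day, min)),
                 mean = as.numeric(tapply(v, day, mean)),
                 max = as.numeric(tapply(v, day, max)))
    }
    out$telemetry <- list(temp_in = stat3(df$temp_in),
                          temp_out = stat3(df$temp_out),
                          hum_in = stat3(df$hum_in),
                          hum_out = stat3(df$hum_out))
  }
  if (!is.null(weather) && !is.null(telemetry)) {
    wdf <- as.data.frame(weather)
    tdf <- as.data.frame(telemetry)
    pairs <- list(
      c("hum_out_vs_weather_humidity", "hum_out", "humidity"),
      c("temp_out_vs_weather_temperature", "temp_out", "temperature"))
    cors <- lapply(pairs, function(p) {
      res <- tryCatch(correlateEnvironment(
        data.frame(time = tdf$timestamp, value = tdf[[p[2]]]),
        data.frame(time = wdf$timestamp, value = wdf[[p[3]]])),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(pair = p[1], rho = res$rho, n = res$n, p = res$p)
    })
    cors <- do.call(rbind, cors)
    if (!is.null(cors)) out$correlations <- cors
  }
  class(out) <- c("RunSummary", "list")
  out
}

#' Write a run summary as JSON
#'
#' Byte-identical output for identical inputs (keys in fixed order, full
#' numeric precision).
#'
#' @param summary a [summarizeRun()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRunSummary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  invisible(path)
}
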