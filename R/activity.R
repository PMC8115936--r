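# Entrance-traffic analytics from the 100 S/s capacitance streams.

#' Count bee passages in an entrance-activity trace
#'
#' The two capacitance channels are averaged, smoothed with a moving
#' average, and baseline-corrected with a rolling median; local maxima of
#' the residual whose height reaches `prominence` times the residual's
#' MAD (robust noise scale) are reported as passages. Directional
#' (in/out) separation is deliberately out of scope.
#'
#' @param trace an [ActivityTrace-class].
#' @param smoothS moving-average window, seconds (default 0.15, about
#'   half a passage bump).
#' @param prominence peak height threshold in noise-MAD units (default 5).
#' @param baselineS rolling-median baseline window, seconds.
#' @return Data frame of passages: `time` (s from trace start),
#'   `amplitude` (baseline-corrected capacitance units).
#' @export
countPassages <- function(trace, smoothS = 0.15, prominence = 5,
                          baselineS = 5) {
  stopifnot(is(trace, "ActivityTrace"))
  fs <- trace@sampleRate
  x <- rowMeans(trace@samples)
  n <- length(x)
  if (n == 0L)
    return(data.frame(time = numeric(0), amplitude = numeric(0)))
  w <- max(1L, as.integer(round(smoothS * fs)))
  kern <- rep(1 / w, w)
  xs <- as.numeric(stats::filter(x, kern, sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  base <- if (n >= 3) stats::runmed(xs, odd_window(baselineS * fs, n))
          else rep(median(xs), n)
  r <- xs - base
  sigma <- mad(r)
  thr <- prominence * sigma
  if (thr <= 0) thr <- 0.05 * max(r, 0)
  if (thr <= 0)
    return(data.frame(time = numeric(0), amplitude = numeric(0)))
  cand <- which(r > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[r[cand] >= r[cand - 1] & r[cand] > r[cand + 1]]
  if (!length(cand))
    return(data.frame(time = numeric(0), amplitude = numeric(0)))
  # enforce a refractory distance of about one bump width
  min_sep <- max(1L, as.integer(round(2 * smoothS * fs)))
  keep <- logical(length(cand))
  taken <- integer(0)
  for (i in order(r[cand], decreasing = TRUE)) {
    if (!length(taken) || all(abs(cand[i] - taken) >= min_sep)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  cand <- sort(cand[keep])
  data.frame(time = (cand - 1) / fs, amplitude = r[cand])
}

#' Bin passage events into activity counts
#'
#' Histograms passage events on the recording's UTC grid. Bins outside
#' the recorded span are marked uncovered (`covered = FALSE`) so that "no
#' data" is distinguishable from "zero traffic".
#'
#' @param events passage data frame from [countPassages()] (times in
#'   seconds from trace start).
#' @param trace the source [ActivityTrace-class] (supplies the UTC
#'   anchor and span).
#' @param binS bin width, seconds (default 3600).
#' @return Data frame: `bin_start` (Unix s, aligned to the bin grid),
#'   `count`, `covered`.
#' @export
hourlyActivity <- function(events, trace, binS = 3600) {
  stopifnot(is(trace, "ActivityTrace"))
  t0 <- trace@meta@utcStart
  t1 <- t0 + durationSec(trace)
  grid0 <- floor(t0 / binS) * binS
  edges <- seq(grid0, ceiling(t1 / binS) * binS, by = binS)
  starts <- edges[-length(edges)]
  abs_times <- t0 + events$time
  idx <- findInterval(abs_times, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(starts))
  data.frame(bin_start = starts, count = counts,
             covered = starts < t1 & (starts + binS) > t0)
}
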