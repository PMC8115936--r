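# Rule-based detector: band-power segmentation, class assignment by
# band-and-duration rules, waggle counting, distance decoding, bout
# grouping, cross-channel fusion and evaluation against ground truth.

empty_intervals <- function() {
  data.frame(band = character(0), t_start = numeric(0),
             t_end = numeric(0), peak_power = numeric(0),
             mean_power = numeric(0), stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(label = character(0), channel = integer(0),
             t_start = numeric(0), t_end = numeric(0),
             n_waggles = integer(0), distance_m = numeric(0),
             mean_power = numeric(0), regularity = numeric(0),
             low_confidence = logical(0), stringsAsFactors = FALSE)
}

#' Segment a band-power trace into candidate intervals
#'
#' Intervals start where the trace rises above `k` times its rolling-median
#' baseline and end when it falls below `hysteresis` times that threshold.
#' A small absolute floor (`floorFrac` of the trace peak) guards the
#' baseline in quiet recordings. Interval edges are refined to the
#' crossing of half the interior power level, interpolated between frames:
#' for a flat-power event seen through a symmetric STFT window the
#' half-level crossing occurs exactly when the frame center passes the true
#' event edge, so refined edges are unbiased estimates of the event span.
#' Intervals separated by less than `mergeGap` are merged.
#'
#' @param trace a [BandPowerTrace-class].
#' @param k threshold multiple of the rolling-median baseline.
#' @param hysteresis falling-edge fraction of the rising threshold.
#' @param mergeGap merge gap, seconds.
#' @param baselineWinS rolling-median window, seconds (must be much longer
#'   than the longest expected event in this band).
#' @param floorFrac absolute threshold floor as a fraction of the trace
#'   peak.
#' @return Data frame of non-overlapping intervals ordered by onset:
#'   `band`, `t_start`, `t_end`, `peak_power`, `mean_power`.
#' @export
segmentBand <- function(trace, k = 4, hysteresis = 0.5, mergeGap = 0.1,
                        baselineWinS = 30, floorFrac = 1e-4) {
  stopifnot(is(trace, "BandPowerTrace"))
  p <- trace@power
  tt <- trace@times
  nf <- length(p)
  if (nf == 0L || max(p) <= 0) return(empty_intervals())
  hop <- if (nf > 1) median(diff(tt)) else trace@hopS
  if (!is.finite(hop) || hop <= 0) hop <- 1
  # Two-pass baseline: a first pass with a global robust level masks frames
  # that are clearly active, so long or frequent events cannot drag the
  # rolling median up to their own level.
  global_base <- stats::quantile(p, 0.25, names = FALSE)
  premask <- p > pmax(k * global_base, floorFrac * max(p))
  p_masked <- p
  p_masked[premask] <- global_base
  baseline <- if (nf >= 3) {
    stats::runmed(p_masked, odd_window(baselineWinS / hop, nf))
  } else rep(median(p_masked), nf)
  thr <- pmax(k * baseline, floorFrac * max(p))
  lo <- hysteresis * thr

  runs <- list()
  active <- FALSE
  start <- 0L
  for (i in seq_len(nf)) {
    if (!active && p[i] > thr[i]) {
      active <- TRUE
      start <- i
    } else if (active && p[i] < lo[i]) {
      runs[[length(runs) + 1L]] <- c(start, i - 1L)
      active <- FALSE
    }
  }
  if (active) runs[[length(runs) + 1L]] <- c(start, nf)
  if (!length(runs)) return(empty_intervals())

  max_walk <- if (is.finite(trace@windowS) && !is.na(trace@windowS)) {
    as.integer(ceiling(trace@windowS / hop)) + 2L
  } else 2L
  refine <- function(i1, i2) {
    level <- median(p[i1:i2]) / 2
    # left edge: locate the level crossing, walking outward when the run
    # edge is above the level and inward when it is below
    j <- i1
    steps <- 0L
    if (p[j] > level) {
      while (j > 1L && p[j - 1L] > level && steps < max_walk) {
        j <- j - 1L
        steps <- steps + 1L
      }
    } else {
      while (j < i2 && p[j] <= level) j <- j + 1L
    }
    t_on <- if (j > 1L && p[j - 1L] <= level && p[j] > level) {
      tt[j - 1L] + (level - p[j - 1L]) / (p[j] - p[j - 1L]) *
        (tt[j] - tt[j - 1L])
    } else tt[j] - hop / 2
    j <- i2
    steps <- 0L
    if (p[j] > level) {
      while (j < nf && p[j + 1L] > level && steps < max_walk) {
        j <- j + 1L
        steps <- steps + 1L
      }
    } else {
      while (j > i1 && p[j] <= level) j <- j - 1L
    }
    t_off <- if (j < nf && p[j + 1L] <= level && p[j] > level) {
      tt[j] + (p[j] - level) / (p[j] - p[j + 1L]) * (tt[j + 1L] - tt[j])
    } else tt[j] + hop / 2
    c(max(t_on, tt[1] - hop / 2), min(t_off, tt[nf] + hop / 2))
  }

  out <- lapply(runs, function(r) {
    edges <- refine(r[1], r[2])
    data.frame(band = trace@band@name, t_start = edges[1],
               t_end = edges[2], peak_power = max(p[r[1]:r[2]]),
               mean_power = mean(p[r[1]:r[2]]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  # enforce ordering and merge near-adjacent intervals
  out <- out[order(out$t_start), , drop = FALSE]
  merged <- out[1, , drop = FALSE]
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      last <- nrow(merged)
      if (out$t_start[i] - merged$t_end[last] < mergeGap) {
        w1 <- merged$t_end[last] - merged$t_start[last]
        w2 <- out$t_end[i] - out$t_start[i]
        merged$mean_power[last] <-
          (merged$mean_power[last] * w1 + out$mean_power[i] * w2) /
          max(w1 + w2, 1e-12)
        merged$t_end[last] <- max(merged$t_end[last], out$t_end[i])
        merged$peak_power[last] <- max(merged$peak_power[last],
                                       out$peak_power[i])
      } else {
        merged <- rbind(merged, out[i, ])
      }
    }
  }
  rownames(merged) <- NULL
  merged
}

# Segment every detector band of one channel; returns a named list of
# interval data frames.
segment_channel <- function(x, fs, cfg) {
  lowspec <- stftSpectrogram(x, fs, cfg@lowWindow[["window"]],
                             cfg@lowWindow[["hop"]])
  highspec <- stftSpectrogram(x, fs, cfg@highWindow[["window"]],
                              cfg@highWindow[["hop"]])
  use_low <- vapply(cfg@bands, function(b) b@fHi <= 30, TRUE)
  out <- list()
  for (nm in c("WRS_L", "WRS_H", "SRS", "FRS")) {
    band <- cfg@bands[[nm]]
    band@fHi <- min(band@fHi, fs / 2)
    spec <- if (use_low[[nm]]) lowspec else highspec
    trace <- bandPower(spec, band)
    bw <- if (nm %in% names(cfg@baselineWin)) cfg@baselineWin[[nm]] else 30
    out[[nm]] <- segmentBand(trace, k = cfg@kFactor,
                             hysteresis = cfg@hysteresis,
                             mergeGap = cfg@mergeGap, baselineWinS = bw,
                             floorFrac = cfg@floorFrac)
  }
  out
}

# Remove candidates overlapping an accepted event span.
consume <- function(cands, t0, t1) {
  lapply(cands, function(df) {
    if (!nrow(df)) return(df)
    keep <- interval_overlap(df$t_start, df$t_end, t0, t1) <= 0
    df[keep, , drop = FALSE]
  })
}

#' Classify candidate intervals of one channel into signal events
#'
#' Rules are applied in priority order, each accepted event consuming
#' overlapping candidates in the remaining bands:
#' \enumerate{
#'   \item FRS: an interval in the fanning band lasting longer than 15 s
#'     whose waveform regularity reaches the configured minimum (fanning
#'     is characterized by highly regular 90-120 Hz waves);
#'   \item SRS: an interval in the short-pulse band lasting under 1 s;
#'   \item WRS: an interval in the abdomen band (5-25 Hz) of plausible run
#'     duration whose span is concurrently active in the wing band
#'     (190-230 Hz) for at least the configured fraction.
#' }
#' Durations are measured on the STFT frame grid, so the class duration
#' bounds are compared with a half-hop guard band; spans of accepted
#' events lying within the guard are snapped to the class bound, making
#' the emitted events satisfy the class definitions exactly.
#'
#' @param cands named list of candidate data frames (`WRS_L`, `WRS_H`,
#'   `SRS`, `FRS`) from [segmentBand()] on one channel.
#' @param x the channel waveform (needed for the FRS regularity check).
#' @param fs sample rate, Hz.
#' @param cfg a [detectorConfig()].
#' @param channel channel number recorded in the output.
#' @return Event data frame: `label`, `channel`, `t_start`, `t_end`,
#'   `n_waggles` (NA here; filled by [countWaggles()] downstream),
#'   `distance_m`, `mean_power`, `regularity`, `low_confidence`.
#' @export
classifyEvents <- function(cands, x, fs, cfg, channel = 1L) {
  highHop <- cfg@highWindow[["hop"]]
  lowHop <- cfg@lowWindow[["hop"]]
  events <- list()
  n <- length(x)

  add_event <- function(label, t0, t1, mean_power, regularity = NA_real_) {
    events[[length(events) + 1L]] <<- data.frame(
      label = label, channel = as.integer(channel), t_start = t0,
      t_end = t1, n_waggles = NA_integer_, distance_m = NA_real_,
      mean_power = mean_power, regularity = regularity,
      low_confidence = FALSE, stringsAsFactors = FALSE)
  }

  # 1) fanning: long, highly regular waves
  frs <- cands$FRS
  guard <- highHop / 2
  if (nrow(frs)) {
    for (i in seq_len(nrow(frs))) {
      dur <- frs$t_end[i] - frs$t_start[i]
      if (dur <= cfg@frsDur[1] - guard || dur >= cfg@frsDur[2]) next
      i0 <- max(1L, as.integer(floor(frs$t_start[i] * fs)) + 1L)
      i1 <- min(n, as.integer(ceiling(frs$t_end[i] * fs)))
      band <- cfg@bands$FRS
      reg <- tryCatch(regularityIndex(x[i0:i1], fs, band),
                      error = function(e) NA_real_)
      if (is.na(reg) || reg < cfg@frsRegularityMin) next
      t0 <- frs$t_start[i]
      t1 <- frs$t_end[i]
      if (t1 - t0 < cfg@frsDur[1]) {  # snap to the class minimum
        mid <- (t0 + t1) / 2
        t0 <- mid - cfg@frsDur[1] / 2
        t1 <- mid + cfg@frsDur[1] / 2
      }
      add_event("FRS", t0, t1, frs$mean_power[i], regularity = reg)
      cands <- consume(cands, t0, t1)
    }
  }

  # 2) short pulses
  srs <- cands$SRS
  if (nrow(srs)) {
    for (i in seq_len(nrow(srs))) {
      dur <- srs$t_end[i] - srs$t_start[i]
      if (dur >= cfg@srsDur[2] + guard || dur < cfg@srsDur[1]) next
      t0 <- srs$t_start[i]
      t1 <- srs$t_end[i]
      if (t1 - t0 > cfg@srsDur[2]) {  # snap to the class maximum
        mid <- (t0 + t1) / 2
        t0 <- mid - cfg@srsDur[2] / 2
        t1 <- mid + cfg@srsDur[2] / 2
      }
      add_event("SRS", t0, t1, srs$mean_power[i])
      cands <- consume(cands, t0, t1)
    }
  }

  # 3) waggle runs: low-band interval with concurrent wing-band activity
  wl <- cands$WRS_L
  guardLow <- lowHop / 2
  if (nrow(wl)) {
    wh <- cands$WRS_H
    for (i in seq_len(nrow(wl))) {
      dur <- wl$t_end[i] - wl$t_start[i]
      if (dur <= cfg@wrsDur[1] - guardLow ||
          dur >= cfg@wrsDur[2] + guardLow) next
      ov <- if (nrow(wh)) {
        sum(interval_overlap(wh$t_start, wh$t_end, wl$t_start[i],
                             wl$t_end[i]))
      } else 0
      if (ov / dur < cfg@wrsConcurrencyMin) next
      # dominance: the abdomen band must hold a minimum share of power
      # against the other bands, or the candidate is leakage from a
      # strong event elsewhere in the spectrum (e.g. a pulse onset)
      i0 <- max(1L, as.integer(floor(wl$t_start[i] * fs)) + 1L)
      i1 <- min(n, as.integer(ceiling(wl$t_end[i] * fs)))
      seg <- x[i0:i1]
      p_l <- rms(bandpassFilter(seg, fs, cfg@bands$WRS_L))^2
      nyq_band <- function(b) {
        b@fHi <- min(b@fHi, fs / 2)
        b
      }
      p_comp <- max(
        rms(bandpassFilter(seg, fs, nyq_band(cfg@bands$SRS)))^2,
        rms(bandpassFilter(seg, fs, nyq_band(cfg@bands$FRS)))^2)
      if (p_l < cfg@wrsDominanceMin * p_comp) next
      add_event("WRS", wl$t_start[i], wl$t_end[i], wl$mean_power[i])
    }
  }

  if (!length(events)) return(empty_events())
  out <- do.call(rbind, events)
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count waggle cycles within a detected waggle run
#'
#' Band-passes the event span in the abdomen band (zero-phase, so cycle
#' positions are preserved) and counts zero crossings: one waggle cycle
#' contributes one positive-going and one negative-going crossing, so the
#' count is the rounded mean of the two crossing counts, which stays
#' correct when a crossing sits right on a span boundary. When the
#' band-passed RMS falls below `waggleRmsFrac` of the raw span RMS the
#' count is flagged low-confidence (attribute `lowConfidence`).
#'
#' @param rec an [ESFRecording-class].
#' @param event one-row data frame with `label == "WRS"`, `channel`,
#'   `t_start`, `t_end`.
#' @param cfg a [detectorConfig()].
#' @return Integer count with logical attribute `lowConfidence`.
#' @export
countWaggles <- function(rec, event, cfg = detectorConfig()) {
  if (event$label != "WRS")
    stop("usage error: waggle counting applies to WRS events only",
         call. = FALSE)
  fs <- rec@sampleRate
  n <- nrow(rec@samples)
  pad <- 0.2
  i0 <- max(1L, as.integer(floor((event$t_start - pad) * fs)) + 1L)
  i1 <- min(n, as.integer(ceiling((event$t_end + pad) * fs)))
  seg <- rec@samples[i0:i1, event$channel]
  y <- bandpassFilter(seg, fs, cfg@bands$WRS_L)
  t <- (i0 - 1 + seq_along(y) - 1) / fs
  up <- which(y[-length(y)] <= 0 & y[-1] > 0)
  down <- which(y[-length(y)] >= 0 & y[-1] < 0)
  in_span <- function(idx) sum(t[idx] >= event$t_start &
                               t[idx] < event$t_end)
  count <- floor((in_span(up) + in_span(down)) / 2 + 0.5)
  low_conf <- rms(y) < cfg@waggleRmsFrac * max(rms(seg), .Machine$double.eps)
  structure(as.integer(count), lowConfidence = low_conf)
}

#' Decode foraging distance from a waggle count
#'
#' Each counted waggle cycle corresponds to about 75 m of distance to the
#' advertised food source.
#'
#' @param nWaggles non-negative waggle count (vectorized).
#' @param cfg a [detectorConfig()] (uses `metersPerWaggle`).
#' @return Distance in meters.
#' @export
decodeDistance <- function(nWaggles, cfg = detectorConfig()) {
  if (any(nWaggles < 0))
    stop("usage error: waggle count must be non-negative", call. = FALSE)
  as.numeric(nWaggles) * cfg@metersPerWaggle
}

#' Group waggle runs into dance bouts
#'
#' Consecutive waggle-run events on the same channel separated by less
#' than `boutMaxGap` form one bout; dancers repeat runs in quick
#' succession, and the bout-level median count gives a more stable
#' distance estimate than any single run.
#'
#' @param events event data frame (only `WRS` rows are used), time-sorted.
#' @param cfg a [detectorConfig()].
#' @return Data frame: `channel`, `t_start`, `t_end`, `n_runs`,
#'   `total_waggles`, `median_waggles`, `distance_m`.
#' @export
groupBouts <- function(events, cfg = detectorConfig()) {
  wrs <- events[events$label == "WRS", , drop = FALSE]
  out <- data.frame(channel = integer(0), t_start = numeric(0),
                    t_end = numeric(0), n_runs = integer(0),
                    total_waggles = numeric(0), median_waggles = numeric(0),
                    distance_m = numeric(0))
  if (!nrow(wrs)) return(out)
  wrs <- wrs[order(wrs$channel, wrs$t_start), , drop = FALSE]
  gap_prev <- c(Inf, wrs$t_start[-1] - wrs$t_end[-nrow(wrs)])
  new_bout <- gap_prev >= cfg@boutMaxGap |
    c(TRUE, wrs$channel[-1] != wrs$channel[-nrow(wrs)])
  bout_id <- cumsum(new_bout)
  for (b in unique(bout_id)) {
    m <- wrs[bout_id == b, , drop = FALSE]
    med <- median(m$n_waggles, na.rm = TRUE)
    out <- rbind(out, data.frame(
      channel = m$channel[1], t_start = min(m$t_start),
      t_end = max(m$t_end), n_runs = nrow(m),
      total_waggles = sum(m$n_waggles, na.rm = TRUE),
      median_waggles = med,
      distance_m = ifelse(is.na(med), NA_real_,
                          med * cfg@metersPerWaggle)))
  }
  rownames(out) <- NULL
  out
}

#' Merge duplicate detections of one signal across channels
#'
#' The six sensors face one dance floor, so one dance can register on
#' several channels. Same-label events on different channels whose spans
#' overlap by at least `overlapFrac` of the shorter event are merged
#' (transitively); the merged event keeps the span union and the features
#' of the strongest member (largest `mean_power`).
#'
#' @param events event data frame.
#' @param overlapFrac overlap threshold (fraction of the shorter event).
#' @return Merged event data frame sorted by onset.
#' @export
fuseChannels <- function(events, overlapFrac = 0.5) {
  if (!nrow(events)) return(events)
  n <- nrow(events)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (events$label[i] != events$label[j]) next
      if (events$channel[i] == events$channel[j]) next
      ov <- interval_overlap(events$t_start[i], events$t_end[i],
                             events$t_start[j], events$t_end[j])
      shorter <- min(events$t_end[i] - events$t_start[i],
                     events$t_end[j] - events$t_start[j])
      if (shorter > 0 && ov / shorter >= overlapFrac)
        parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  merged <- lapply(unique(root), function(r) {
    m <- events[root == r, , drop = FALSE]
    best <- m[which.max(m$mean_power), , drop = FALSE]
    best$t_start <- min(m$t_start)
    best$t_end <- max(m$t_end)
    best
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full detector on a recording
#'
#' Per channel: STFT at the two configured resolutions, band-power
#' segmentation per detector band, rule-based classification; then
#' cross-channel fusion, waggle counting and distance decoding for the
#' accepted waggle runs.
#'
#' @param rec an [ESFRecording-class].
#' @param cfg a [detectorConfig()].
#' @param fuse merge duplicate cross-channel detections with
#'   [fuseChannels()]. Default `FALSE`; enable for field rigs where the
#'   six sensors face one dance floor and a single dance can register on
#'   several channels at once.
#' @return Event data frame (see [classifyEvents()]) with `n_waggles` and
#'   `distance_m` filled for waggle runs.
#' @export
detectSignals <- function(rec, cfg = detectorConfig(), fuse = FALSE) {
  stopifnot(is(rec, "ESFRecording"))
  fs <- rec@sampleRate
  per_channel <- lapply(seq_len(ncol(rec@samples)), function(ch) {
    x <- rec@samples[, ch]
    cands <- segment_channel(x, fs, cfg)
    classifyEvents(cands, x, fs, cfg, channel = ch)
  })
  events <- do.call(rbind, per_channel)
  if (!nrow(events)) return(empty_events())
  events <- events[order(events$t_start), , drop = FALSE]
  rownames(events) <- NULL
  if (fuse) events <- fuseChannels(events, cfg@fuseOverlap)
  wrs_idx <- which(events$label == "WRS")
  for (i in wrs_idx) {
    cnt <- countWaggles(rec, events[i, ], cfg)
    events$n_waggles[i] <- as.integer(cnt)
    events$low_confidence[i] <- isTRUE(attr(cnt, "lowConfidence"))
    events$distance_m[i] <- decodeDistance(as.integer(cnt), cfg)
  }
  events
}

#' Locate a duration-rule boundary by sweeping tone-burst durations
#'
#' Renders constant-envelope tone bursts ([makeToneBurst()]) of the given
#' durations in otherwise silent recordings (six bursts per rendered
#' recording, one per channel), runs the detector, and records whether
#' each burst was assigned `label`. Sweeping fanning-band durations
#' upward locates the minimum fanning duration; sweeping pulse durations
#' locates the maximum short-pulse duration.
#'
#' @param freq burst frequency, Hz (e.g. 100 for the fanning band, 400
#'   for the short-pulse band).
#' @param durations burst durations to probe, seconds.
#' @param label class label whose acceptance is probed.
#' @param cfg a [detectorConfig()].
#' @param amplitude burst amplitude, ADC counts.
#' @param sampleRate samples per second.
#' @return Data frame: `duration`, `accepted`.
#' @export
sweepDurationBoundary <- function(freq, durations,
                                  label = c("FRS", "SRS", "WRS"),
                                  cfg = detectorConfig(),
                                  amplitude = 2000, sampleRate = 5000) {
  label <- match.arg(label)
  accepted <- logical(length(durations))
  onset <- 10
  idx <- seq_along(durations)
  for (batch in split(idx, (idx - 1) %/% 6L)) {
    total <- onset + max(durations[batch]) + 10
    n <- as.integer(round(total * sampleRate))
    m <- matrix(0, n, 6)
    for (j in seq_along(batch)) {
      b <- makeToneBurst(freq, durations[batch[j]], amplitude, sampleRate)
      i0 <- as.integer(onset * sampleRate) + 1L
      m[i0:(i0 + length(b$wave) - 1L), j] <- round(b$wave)
    }
    ev <- detectSignals(esfRecording(m, sampleRate), cfg)
    for (j in seq_along(batch)) {
      d <- durations[batch[j]]
      hit <- ev$label == label & ev$channel == j &
        ev$t_start < onset + d & ev$t_end > onset
      accepted[batch[j]] <- any(hit)
    }
  }
  data.frame(duration = durations, accepted = accepted)
}

#' Score detections against ground truth
#'
#' One-to-one greedy matching by descending overlap: a detection matches a
#' truth annotation when they share the same label and the overlap covers
#' at least `minOverlap` of the truth span. Precision with no detections
#' is reported as 0 with `precision_undefined = TRUE`.
#'
#' @param detected,truth time-sorted event / annotation data frames with
#'   `label`, `t_start`, `t_end`.
#' @param minOverlap match threshold as a fraction of the truth span.
#' @param matchChannel additionally require equal `channel` (default TRUE
#'   when both frames carry a channel column; ignored otherwise, e.g.
#'   after cross-channel fusion).
#' @return List with `perClass` (data frame: label, n_truth, n_detected,
#'   tp, fp, fn, precision, recall, f1, precision_undefined) and `pooled`
#'   (same fields over all classes).
#' @export
evaluateEvents <- function(detected, truth, minOverlap = 0.3,
                           matchChannel = TRUE) {
  matchChannel <- matchChannel && !is.null(detected$channel) &&
    !is.null(truth$channel)
  labels <- sort(unique(c(detected$label, truth$label)))
  per <- lapply(labels, function(lb) {
    d <- detected[detected$label == lb, , drop = FALSE]
    g <- truth[truth$label == lb, , drop = FALSE]
    pairs <- NULL
    if (nrow(d) && nrow(g)) {
      ov <- outer(seq_len(nrow(d)), seq_len(nrow(g)), function(i, j) {
        o <- interval_overlap(d$t_start[i], d$t_end[i], g$t_start[j],
                              g$t_end[j]) /
          pmax(g$t_end[j] - g$t_start[j], 1e-12)
        if (matchChannel) o <- o * (d$channel[i] == g$channel[j])
        o
      })
      ok <- which(ov >= minOverlap, arr.ind = TRUE)
      if (nrow(ok)) {
        ord <- order(ov[ok], decreasing = TRUE)
        used_d <- logical(nrow(d))
        used_g <- logical(nrow(g))
        keep <- logical(length(ord))
        for (r in seq_along(ord)) {
          i <- ok[ord[r], 1]
          j <- ok[ord[r], 2]
          if (!used_d[i] && !used_g[j]) {
            used_d[i] <- TRUE
            used_g[j] <- TRUE
            keep[r] <- TRUE
          }
        }
        pairs <- ok[ord[keep], , drop = FALSE]
      }
    }
    tp <- if (is.null(pairs)) 0L else nrow(pairs)
    data.frame(label = lb, n_truth = nrow(g), n_detected = nrow(d),
               tp = tp, fp = nrow(d) - tp, fn = nrow(g) - tp,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  score <- function(df) {
    undef <- df$n_detected == 0
    precision <- ifelse(undef, 0, df$tp / pmax(df$n_detected, 1))
    recall <- ifelse(df$n_truth == 0, NA, df$tp / pmax(df$n_truth, 1))
    f1 <- ifelse(precision + recall > 0,
                 2 * precision * recall / (precision + recall), 0)
    cbind(df, precision = precision, recall = recall, f1 = f1,
          precision_undefined = undef)
  }
  pooled <- data.frame(label = "all", n_truth = sum(per$n_truth),
                       n_detected = sum(per$n_detected), tp = sum(per$tp),
                       fp = sum(per$fp), fn = sum(per$fn),
                       stringsAsFactors = FALSE)
  list(perClass = score(per), pooled = score(pooled))
}
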