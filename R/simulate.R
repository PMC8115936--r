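# Ground-truth simulator: parametric waveform models of the three
# stereotyped colony signals, colored hive noise, entrance-capacitance
# traces and telemetry. Amplitudes are ADC counts of the 24-bit converter.

# Raised-cosine amplitude taper over the first/last `m` samples,
# suppressing the broadband click a hard onset would create.
edge_taper <- function(n, m) {
  m <- min(as.integer(round(m)), n %/% 2L)
  env <- rep(1, n)
  if (m > 1) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(m) - 1) / (m - 1))
    env[seq_len(m)] <- ramp
    env[n - seq_len(m) + 1L] <- ramp
  }
  env
}

truth_row <- function(label, channel, t_start, t_end, n_waggles = NA,
                      fundamental_hz = NA) {
  data.frame(label = label, channel = channel, t_start = t_start,
             t_end = t_end, n_waggles = n_waggles,
             fundamental_hz = fundamental_hz, stringsAsFactors = FALSE)
}

#' Waggle-run specification
#'
#' Parameters of one simulated waggle run: a low-frequency abdomen
#' component whose instantaneous frequency follows a ramp (first 10 % of
#' the run), plateau (80 %) and decay (last 10 %) profile, summed with
#' wing-vibration bursts gated on a fraction of the waggle cycles.
#'
#' @param waggleFreq abdomen waggling frequency, Hz, within 5-25
#'   (default 13).
#' @param wingFreq wing-vibration frequency, Hz, within 190-230
#'   (default 210).
#' @param nWaggles number of waggle cycles (>= 1); each cycle decodes
#'   about 75 m of foraging distance.
#' @param wingSyncFraction fraction of waggle cycles carrying a wing burst
#'   (default 0.7; the wing component is only partially synchronized with
#'   the abdomen).
#' @param amplitude peak amplitude of each component, ADC counts.
#' @param fmDepth fractional frequency excursion of the ramp-plateau-decay
#'   profile (default 0.2): the run starts and ends at
#'   `(1 - fmDepth) * waggleFreq`.
#' @return A validated list of class `"WaggleRunSpec"`.
#' @export
waggleRunSpec <- function(waggleFreq = 13, wingFreq = 210, nWaggles = 13,
                          wingSyncFraction = 0.7, amplitude = 1000,
                          fmDepth = 0.2) {
  if (waggleFreq < 5 || waggleFreq > 25)
    stop("parameter error: waggleFreq must lie in [5, 25] Hz",
         call. = FALSE)
  if (wingFreq < 190 || wingFreq > 230)
    stop("parameter error: wingFreq must lie in [190, 230] Hz",
         call. = FALSE)
  if (nWaggles < 1)
    stop("parameter error: nWaggles must be >= 1", call. = FALSE)
  if (wingSyncFraction < 0 || wingSyncFraction > 1)
    stop("parameter error: wingSyncFraction must lie in [0, 1]",
         call. = FALSE)
  if (fmDepth < 0 || fmDepth >= 1)
    stop("parameter error: fmDepth must lie in [0, 1)", call. = FALSE)
  structure(list(waggleFreq = waggleFreq, wingFreq = wingFreq,
                 nWaggles = as.integer(round(nWaggles)),
                 wingSyncFraction = wingSyncFraction,
                 amplitude = amplitude, fmDepth = fmDepth),
            class = "WaggleRunSpec")
}

#' Synthesize one waggle run
#'
#' The abdomen component is a phase-continuous sinusoid whose instantaneous
#' frequency ramps up over the first 10 % of the run, holds a plateau for
#' 80 %, and decays over the last 10 % (excursion `fmDepth`). The run
#' duration is chosen so the integrated phase covers exactly `nWaggles`
#' cycles. Wing bursts are Hann-gated copies of a phase-continuous
#' `wingFreq` oscillator, placed on an evenly spread `wingSyncFraction`
#' share of the waggle cycles.
#'
#' @param spec a [waggleRunSpec()].
#' @param sampleRate samples per second.
#' @return List with `wave` (numeric), `truth` (one-row annotation data
#'   frame) and `components` (list with `abdomen` and `wing` waveforms,
#'   useful for band-local scaling).
#' @export
makeWaggleRun <- function(spec, sampleRate = 5000) {
  stopifnot(inherits(spec, "WaggleRunSpec"))
  meanMult <- 1 - 0.1 * spec$fmDepth  # mean of the ramp-plateau-decay profile
  dur <- spec$nWaggles / (spec$waggleFreq * meanMult)
  n <- max(2L, as.integer(round(dur * sampleRate)))
  u <- (seq_len(n) - 0.5) / n
  m <- rep(1, n)
  ramp <- u < 0.1
  m[ramp] <- 1 - spec$fmDepth + spec$fmDepth * u[ramp] / 0.1
  decay <- u > 0.9
  m[decay] <- 1 - spec$fmDepth * (u[decay] - 0.9) / 0.1
  finst <- spec$waggleFreq * m
  phase <- 2 * pi * cumsum(finst) / sampleRate
  abdomen <- spec$amplitude * sin(phase)
  # deterministic, evenly spread selection of gated cycles
  cyc <- pmin(floor(phase / (2 * pi)), spec$nWaggles - 1)
  k <- 0:(spec$nWaggles - 1)
  sel <- floor((k + 1) * spec$wingSyncFraction) >
    floor(k * spec$wingSyncFraction)
  gate <- ifelse(sel[cyc + 1], 0.5 - 0.5 * cos(phase %% (2 * pi)), 0)
  t <- (seq_len(n) - 1) / sampleRate
  wing <- spec$amplitude * gate * sin(2 * pi * spec$wingFreq * t)
  list(wave = abdomen + wing,
       truth = truth_row("WRS", NA, 0, n / sampleRate,
                         n_waggles = spec$nWaggles,
                         fundamental_hz = spec$waggleFreq),
       components = list(abdomen = abdomen, wing = wing))
}

#' Short-pulse specification / synthesis
#'
#' A Hann-windowed pulse of a high fundamental (> 350 Hz) plus harmonics
#' with 1/k amplitude decay, lasting under 1 s.
#'
#' @param fundamental fundamental frequency, Hz (> 350).
#' @param duration pulse duration, seconds (0 < duration < 1).
#' @param nHarmonics number of harmonics above the fundamental.
#' @param amplitude fundamental amplitude, ADC counts.
#' @return `srsSpec` returns a validated list of class `"SRSSpec"`;
#'   `makeSRS` a list with `wave` and `truth` as in [makeWaggleRun()].
#' @export
srsSpec <- function(fundamental = 400, duration = 0.5, nHarmonics = 2,
                    amplitude = 1000) {
  if (fundamental <= 350)
    stop("parameter error: SRS fundamental must exceed 350 Hz",
         call. = FALSE)
  if (duration <= 0 || duration >= 1)
    stop("parameter error: SRS duration must lie in (0, 1) s",
         call. = FALSE)
  structure(list(fundamental = fundamental, duration = duration,
                 nHarmonics = as.integer(nHarmonics),
                 amplitude = amplitude), class = "SRSSpec")
}

#' @rdname srsSpec
#' @param spec an `srsSpec()`.
#' @param sampleRate samples per second.
#' @export
makeSRS <- function(spec, sampleRate = 5000) {
  stopifnot(inherits(spec, "SRSSpec"))
  n <- max(2L, as.integer(round(spec$duration * sampleRate)))
  t <- (seq_len(n) - 1) / sampleRate
  w <- hann(n)
  wave <- numeric(n)
  for (h in seq_len(spec$nHarmonics + 1L)) {
    fh <- h * spec$fundamental
    if (fh >= sampleRate / 2) break
    wave <- wave + (spec$amplitude / h) * sin(2 * pi * fh * t)
  }
  wave <- w * wave
  list(wave = wave,
       truth = truth_row("SRS", NA, 0, n / sampleRate,
                         fundamental_hz = spec$fundamental),
       components = list(pulse = wave))
}

#' Fanning specification / synthesis
#'
#' A near-sinusoid in the 90-120 Hz fanning band lasting longer than 15 s,
#' with optional fractional cycle-period jitter: each cycle's period is
#' multiplied by `1 + jitter * e`, `e ~ N(0, 1)` truncated at 2.5 sd.
#' Regularity (see [regularityIndex()]) decreases as jitter grows.
#'
#' @param freq fanning frequency, Hz, within 90-120.
#' @param duration seconds (> 15).
#' @param jitter fractional cycle-period jitter (>= 0).
#' @param amplitude amplitude, ADC counts.
#' @return `fanningSpec` returns a validated list of class `"FanningSpec"`;
#'   `makeFanning` a list with `wave` and `truth`.
#' @export
fanningSpec <- function(freq = 100, duration = 20, jitter = 0,
                        amplitude = 1000) {
  if (freq < 90 || freq > 120)
    stop("parameter error: fanning frequency must lie in [90, 120] Hz",
         call. = FALSE)
  if (duration <= 15)
    stop("parameter error: fanning duration must exceed 15 s",
         call. = FALSE)
  if (jitter < 0)
    stop("parameter error: jitter must be >= 0", call. = FALSE)
  structure(list(freq = freq, duration = duration, jitter = jitter,
                 amplitude = amplitude), class = "FanningSpec")
}

#' @rdname fanningSpec
#' @param spec a `fanningSpec()`.
#' @param sampleRate samples per second.
#' @param seed optional integer seed for the period jitter; the caller's
#'   RNG stream is restored afterwards.
#' @export
makeFanning <- function(spec, sampleRate = 5000, seed = NULL) {
  stopifnot(inherits(spec, "FanningSpec"))
  with_seed(seed, {
    n <- as.integer(round(spec$duration * sampleRate))
    ncyc <- ceiling(spec$duration * spec$freq * 1.2) + 2L
    e <- pmax(-2.5, pmin(2.5, rnorm(ncyc)))
    periods <- (1 + spec$jitter * e) / spec$freq
    periods[periods < 0.2 / spec$freq] <- 0.2 / spec$freq
    bounds <- c(0, cumsum(periods))
    t <- (seq_len(n) - 1) / sampleRate
    k <- findInterval(t, bounds)
    frac <- (t - bounds[k]) / periods[k]
    wave <- spec$amplitude * sin(2 * pi * (k - 1 + frac))
    wave <- wave * edge_taper(n, 0.05 * sampleRate)  # wings spin up/down
    list(wave = wave,
         truth = truth_row("FRS", NA, 0, n / sampleRate,
                           fundamental_hz = spec$freq),
         components = list(fan = wave))
  })
}

#' Constant-envelope tone burst
#'
#' A sinusoid of constant amplitude and duration with short raised-cosine
#' edge tapers: the reference waveform for probing duration-based
#' classification rules, where the burst's support is its duration by
#' construction.
#'
#' @param freq tone frequency, Hz.
#' @param duration burst duration, seconds.
#' @param amplitude amplitude, ADC counts.
#' @param sampleRate samples per second.
#' @param taperS edge-taper length, seconds (default 0.01, short enough
#'   that the half-level support of the burst stays within a frame hop of
#'   its nominal duration).
#' @return List with `wave` and the burst's span in `truth`-style fields.
#' @export
makeToneBurst <- function(freq, duration, amplitude = 1000,
                          sampleRate = 5000, taperS = 0.01) {
  stopifnot(freq > 0, duration > 0, freq < sampleRate / 2)
  n <- max(2L, as.integer(round(duration * sampleRate)))
  t <- (seq_len(n) - 1) / sampleRate
  wave <- amplitude * sin(2 * pi * freq * t) *
    edge_taper(n, taperS * sampleRate)
  list(wave = wave, t_start = 0, t_end = n / sampleRate, freq = freq)
}

#' Hive noise specification
#'
#' Additive noise model for simulated ESF channels: white Gaussian noise,
#' 1/f-shaped pink noise (power slope -1), a mains-hum sinusoid (50 Hz by
#' default, the European grid), and band-limited (< 30 Hz) "crowd" clutter
#' standing in for the bodies of many bees moving in front of a sensor.
#'
#' @param whiteRms,pinkRms,mainsRms,crowdRms component RMS amplitudes in
#'   ADC counts (>= 0; 0 disables a component).
#' @param mainsHz mains frequency, Hz.
#' @return A validated list of class `"NoiseSpec"`.
#' @export
noiseSpec <- function(whiteRms = 200, pinkRms = 400, mainsHz = 50,
                      mainsRms = 300, crowdRms = 400) {
  vals <- c(whiteRms, pinkRms, mainsRms, crowdRms)
  if (any(vals < 0))
    stop("parameter error: RMS values must be >= 0", call. = FALSE)
  structure(list(whiteRms = whiteRms, pinkRms = pinkRms, mainsHz = mainsHz,
                 mainsRms = mainsRms, crowdRms = crowdRms),
            class = "NoiseSpec")
}

#' Synthesize hive noise
#'
#' @param duration seconds (> 0).
#' @param spec a [noiseSpec()].
#' @param sampleRate samples per second.
#' @param seed optional integer seed (caller's RNG restored afterwards).
#' @return Numeric waveform of `round(duration * sampleRate)` samples.
#' @export
makeNoise <- function(duration, spec = noiseSpec(), sampleRate = 5000,
                      seed = NULL) {
  stopifnot(inherits(spec, "NoiseSpec"), duration > 0)
  n <- as.integer(round(duration * sampleRate))
  with_seed(seed, {
    out <- numeric(n)
    if (spec$whiteRms > 0)
      out <- out + spec$whiteRms * rnorm(n)
    if (spec$pinkRms > 0) {
      n2 <- stats::nextn(n, c(2, 3, 5))  # keep the FFT length smooth
      w <- rnorm(n2)
      X <- fft(w)
      k <- 0:(n2 - 1)
      f <- pmin(k, n2 - k) * sampleRate / n2
      shape <- 1 / sqrt(pmax(f, sampleRate / n2))  # power ~ 1/f
      shape[1] <- 0
      pink <- Re(fft(X * shape, inverse = TRUE))[seq_len(n)] / n2
      out <- out + spec$pinkRms * pink / rms(pink)
    }
    if (spec$mainsRms > 0) {
      t <- (seq_len(n) - 1) / sampleRate
      ph <- runif(1, 0, 2 * pi)
      out <- out + spec$mainsRms * sqrt(2) *
        sin(2 * pi * spec$mainsHz * t + ph)
    }
    if (spec$crowdRms > 0) {
      rw <- cumsum(rnorm(n))
      lp <- bandpassFilter(rw, sampleRate,
                           bandDef("crowd", 0.5, min(30, sampleRate / 2 - 1)),
                           transitionHz = 0.5)
      out <- out + spec$crowdRms * lp / rms(lp)
    }
    out
  })
}

#' Scenario: a full synthetic multi-channel recording specification
#'
#' @param duration recording duration, seconds.
#' @param events list of [scenarioEvent()] entries; events on the same
#'   channel must not overlap in time.
#' @param noise a [noiseSpec()] applied independently per channel.
#' @param seed integer seed making the rendering fully deterministic.
#' @param sampleRate samples per second (default 5000).
#' @param meta a [HiveMetadata-class]; the default start time lies inside
#'   the 06:00-23:59 UTC recording window of the field device.
#' @return A validated list of class `"Scenario"`.
#' @export
scenario <- function(duration, events = list(), noise = noiseSpec(),
                     seed = 1, sampleRate = 5000, meta = hiveMetadata()) {
  stopifnot(duration > 0)
  structure(list(duration = duration, events = events, noise = noise,
                 seed = as.integer(seed), sampleRate = sampleRate,
                 meta = meta), class = "Scenario")
}

#' @rdname scenario
#' @param kind `"WRS"`, `"SRS"` or `"FRS"`.
#' @param channel ESF channel, 1-6.
#' @param tStart event onset, seconds from recording start.
#' @param spec the per-class spec: [waggleRunSpec()], [srsSpec()] or
#'   [fanningSpec()].
#' @param snrDb optional band-local signal-to-noise ratio in dB; when set,
#'   each waveform component is rescaled so that its RMS over the event
#'   span is `10^(snrDb/20)` times the RMS of the channel noise restricted
#'   to the component's frequency band over the same span.
#' @export
scenarioEvent <- function(kind = c("WRS", "SRS", "FRS"), channel, tStart,
                          spec, snrDb = NA) {
  kind <- match.arg(kind)
  expected <- c(WRS = "WaggleRunSpec", SRS = "SRSSpec", FRS = "FanningSpec")
  if (!inherits(spec, expected[[kind]]))
    stop(sprintf("parameter error: %s event needs a %s", kind,
                 expected[[kind]]), call. = FALSE)
  if (channel < 1 || channel > 6)
    stop("parameter error: channel must be 1-6", call. = FALSE)
  list(kind = kind, channel = as.integer(channel), tStart = tStart,
       spec = spec, snrDb = snrDb)
}

# Frequency band occupied by one waveform component, for band-local SNR.
component_band <- function(kind, comp, spec) {
  switch(paste(kind, comp, sep = "."),
         WRS.abdomen = bandDef("WRS_L", 5, 25),
         WRS.wing = bandDef("WRS_H", 190, 230),
         SRS.pulse = bandDef("SRS", 350, 2400),
         FRS.fan = bandDef("FRS", 90, 120),
         stop("unknown component"))
}

#' Render a scenario into a recording plus ground truth
#'
#' Per channel, independent noise is generated first; each event waveform
#' is then synthesized (optionally rescaled to its band-local SNR) and
#' added at its onset. The final sum is rounded to integer ADC counts.
#' Rendering is fully deterministic given the scenario (including its
#' seed).
#'
#' @param sc a [scenario()].
#' @return List with `recording` (an [ESFRecording-class]) and `truth`
#'   (annotation data frame sorted by onset: `label`, `channel`,
#'   `t_start`, `t_end`, `n_waggles`, `fundamental_hz`).
#' @export
renderScenario <- function(sc) {
  stopifnot(inherits(sc, "Scenario"))
  fs <- sc$sampleRate
  n <- as.integer(round(sc$duration * fs))
  with_seed(sc$seed, {
    chans <- matrix(0, n, 6)
    for (ch in 1:6) chans[, ch] <- makeNoise(sc$duration, sc$noise, fs)
    truth <- list()
    spans <- lapply(1:6, function(i) matrix(0, 0, 2))
    for (ev in sc$events) {
      made <- switch(ev$kind,
                     WRS = makeWaggleRun(ev$spec, fs),
                     SRS = makeSRS(ev$spec, fs),
                     FRS = makeFanning(ev$spec, fs))
      len <- length(made$wave)
      i0 <- as.integer(round(ev$tStart * fs)) + 1L
      i1 <- i0 + len - 1L
      if (i0 < 1L || i1 > n)
        stop("scenario error: event does not fit inside the recording",
             call. = FALSE)
      t0 <- (i0 - 1) / fs
      t1 <- i1 / fs
      prev <- spans[[ev$channel]]
      if (nrow(prev) &&
          any(interval_overlap(prev[, 1], prev[, 2], t0, t1) > 0))
        stop("scenario error: overlapping events on channel ", ev$channel,
             call. = FALSE)
      spans[[ev$channel]] <- rbind(prev, c(t0, t1))
      wave <- made$wave
      if (!is.na(ev$snrDb)) {
        wave <- numeric(len)
        for (comp in names(made$components)) {
          cw <- made$components[[comp]]
          if (rms(cw) == 0) next
          band <- component_band(ev$kind, comp, ev$spec)
          band@fHi <- min(band@fHi, fs / 2 - 1)
          noise_band <- bandpassFilter(chans[i0:i1, ev$channel], fs, band)
          target <- 10^(ev$snrDb / 20) * rms(noise_band)
          wave <- wave + cw * target / rms(cw)
        }
      }
      chans[i0:i1, ev$channel] <- chans[i0:i1, ev$channel] + wave
      tr <- made$truth
      tr$channel <- ev$channel
      tr$t_start <- tr$t_start + t0
      tr$t_end <- tr$t_end + t0
      truth[[length(truth) + 1L]] <- tr
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(label = character(0), channel = integer(0),
                             t_start = numeric(0), t_end = numeric(0),
                             n_waggles = integer(0),
                             fundamental_hz = numeric(0))
    truth <- truth[order(truth$t_start), , drop = FALSE]
    rownames(truth) <- NULL
    chans <- round(chans)
    chans[chans > ADC_MAX] <- ADC_MAX
    chans[chans < -ADC_MAX] <- -ADC_MAX
    list(recording = esfRecording(chans, sampleRate = fs, meta = sc$meta),
         truth = truth)
  })
}

#' Entrance-activity simulation
#'
#' Each bee passage adds a raised-cosine capacitance bump of width
#' `bumpWidth` to both entrance channels, the second channel lagging by
#' `channelLag` (a bee crosses the two sensor rings in sequence).
#'
#' @param passageTimes passage times, seconds from trace start.
#' @param duration trace duration, seconds.
#' @param bumpWidth full bump width, seconds (default 0.3).
#' @param amplitudePerBee bump peak amplitude, capacitance units.
#' @param noiseRms white sensor noise RMS.
#' @param sampleRate samples per second (default 100).
#' @param channelLag inter-channel lag, seconds.
#' @param seed optional integer seed for the noise.
#' @param meta a [HiveMetadata-class].
#' @return List with `trace` (an [ActivityTrace-class]) and `nPassages`.
#' @export
makeActivity <- function(passageTimes, duration, bumpWidth = 0.3,
                         amplitudePerBee = 1, noiseRms = 0,
                         sampleRate = 100, channelLag = 0.05, seed = NULL,
                         meta = hiveMetadata()) {
  stopifnot(duration > 0)
  if (length(passageTimes) &&
      (min(passageTimes) < 0 || max(passageTimes) > duration))
    stop("parameter error: passage times must lie within the trace",
         call. = FALSE)
  n <- as.integer(round(duration * sampleRate))
  t <- (seq_len(n) - 1) / sampleRate
  bump_at <- function(center) {
    y <- numeric(n)
    sel <- abs(t - center) < bumpWidth / 2
    y[sel] <- 0.5 * (1 + cos(2 * pi * (t[sel] - center) / bumpWidth))
    y
  }
  ch1 <- numeric(n)
  ch2 <- numeric(n)
  for (p in passageTimes) {
    ch1 <- ch1 + amplitudePerBee * bump_at(p)
    ch2 <- ch2 + amplitudePerBee * bump_at(p + channelLag)
  }
  if (noiseRms > 0) {
    with_seed(seed, {
      ch1 <- ch1 + noiseRms * rnorm(n)
      ch2 <- ch2 + noiseRms * rnorm(n)
    })
  }
  list(trace = activityTrace(cbind(ch1, ch2), sampleRate = sampleRate,
                             meta = meta),
       nPassages = length(passageTimes))
}

#' Telemetry simulation
#'
#' Generates the 120 s-cadence stream: brood-nest temperature clamped near
#' its setpoint (honeybees thermoregulate the brood around 35 degrees C),
#' sinusoidal diurnal cycles for outdoor temperature and humidity
#' (temperature peaking mid-afternoon, humidity in antiphase), slowly
#' drifting load cells and an MCU temperature tracking ambient.
#'
#' @param days number of days (>= 1).
#' @param broodSetpoint brood-nest temperature setpoint, degrees C.
#' @param tempOutMean,tempOutAmp outdoor diurnal mean and half-amplitude,
#'   degrees C.
#' @param humOutMean,humOutAmp outdoor humidity diurnal mean and
#'   half-amplitude, percent.
#' @param hiveMassKg total hive mass split over the three load cells, kg.
#' @param noiseSd sensor noise SD applied to each channel.
#' @param cadence sampling interval, seconds (default 120).
#' @param seed optional integer seed.
#' @param meta a [HiveMetadata-class]; its `utcStart` anchors the series.
#' @return A [TelemetrySeries-class] with `86400 / cadence` records per
#'   day.
#' @export
makeTelemetry <- function(days = 1, broodSetpoint = 35, tempOutMean = 18,
                          tempOutAmp = 6, humOutMean = 65, humOutAmp = 20,
                          hiveMassKg = 55, noiseSd = 0.3, cadence = 120,
                          seed = NULL, meta = hiveMetadata()) {
  stopifnot(days >= 1)
  per_day <- as.integer(86400 / cadence)
  n <- per_day * as.integer(days)
  ts <- meta@utcStart + cadence * (seq_len(n) - 1)
  hour <- (ts %% 86400) / 3600
  with_seed(seed, {
    diurnal <- cos(2 * pi * (hour - 14) / 24)  # warmest at 14:00 UTC
    temp_out <- tempOutMean + tempOutAmp * diurnal + noiseSd * rnorm(n)
    hum_out <- pmin(100, pmax(0, humOutMean - humOutAmp * diurnal +
                                2 * noiseSd * rnorm(n)))
    temp_in <- broodSetpoint + 0.2 * noiseSd * rnorm(n)
    hum_in <- pmin(100, pmax(0, 60 + noiseSd * rnorm(n)))
    drift <- cumsum(rnorm(n, sd = noiseSd / 500))
    loads <- cbind(hiveMassKg / 3 + drift + noiseSd / 10 * rnorm(n),
                   hiveMassKg / 3 + drift + noiseSd / 10 * rnorm(n),
                   hiveMassKg / 3 + drift + noiseSd / 10 * rnorm(n))
    mcu <- temp_out + 5 + noiseSd * rnorm(n)
    telemetrySeries(ts, temp_in, temp_out, hum_in, hum_out, loads, mcu,
                    meta = meta)
  })
}

#' Benchmark scenario with a fixed class mix
#'
#' Standard synthetic study condition used throughout the package's own
#' evaluation: `nPerClass` events of each class spread over the six
#' channels with per-class parameters drawn from their natural ranges,
#' every event rescaled to the same band-local SNR, atop the default hive
#' noise.
#'
#' @param nPerClass events per class (default 50).
#' @param snrDb band-local SNR in dB (default 10).
#' @param seed integer seed.
#' @param gapRange uniform range of within-channel gaps between events,
#'   seconds.
#' @param noise a [noiseSpec()].
#' @return The rendered list from [renderScenario()] plus the `scenario`
#'   element.
#' @export
benchmarkScenario <- function(nPerClass = 50, snrDb = 10, seed = 1,
                              gapRange = c(2.5, 4), noise = noiseSpec()) {
  with_seed(seed, {
    kinds <- rep(c("WRS", "SRS", "FRS"), each = nPerClass)
    kinds <- sample(kinds)
    chan <- rep_len(1:6, length(kinds))
    specs <- lapply(kinds, function(k) {
      switch(k,
        WRS = waggleRunSpec(waggleFreq = runif(1, 11, 15),
                            wingFreq = runif(1, 200, 220),
                            nWaggles = sample(8:20, 1)),
        SRS = srsSpec(fundamental = runif(1, 380, 450),
                      duration = runif(1, 0.2, 0.8),
                      nHarmonics = sample(1:3, 1)),
        FRS = fanningSpec(freq = runif(1, 95, 115),
                          duration = runif(1, 16, 22), jitter = 0.03))
    })
    durs <- vapply(seq_along(kinds), function(i) {
      switch(kinds[i],
             WRS = specs[[i]]$nWaggles /
               (specs[[i]]$waggleFreq * (1 - 0.1 * specs[[i]]$fmDepth)),
             SRS = specs[[i]]$duration,
             FRS = specs[[i]]$duration)
    }, 0)
    t_next <- rep(3, 6)  # lead-in per channel
    events <- vector("list", length(kinds))
    for (i in seq_along(kinds)) {
      ch <- chan[i]
      events[[i]] <- scenarioEvent(kinds[i], ch, t_next[ch], specs[[i]],
                                   snrDb = snrDb)
      t_next[ch] <- t_next[ch] + durs[i] + runif(1, gapRange[1], gapRange[2])
    }
    sc <- scenario(duration = max(t_next) + 3, events = events,
                   noise = noise, seed = seed + 1L)
    out <- renderScenario(sc)
    out$scenario <- sc
    out
  })
}
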