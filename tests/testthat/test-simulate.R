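# Waveform models, noise, scenario rendering, activity and telemetry.

band_rms <- function(x, fs, lo, hi) {
  sqrt(mean(bandpassFilter(x, fs, bandDef("b", lo, hi))^2))
}

test_that("waggle runs carry the configured cycle count and duration", {
  fs <- 5000
  run <- makeWaggleRun(waggleRunSpec(nWaggles = 13, waggleFreq = 13,
                                     fmDepth = 0), fs)
  expect_equal(run$truth$t_end, 1.0, tolerance = 1e-3)
  y <- bandpassFilter(run$wave, fs, bandDef("WRS_L", 5, 25))
  up <- sum(y[-length(y)] <= 0 & y[-1] > 0)
  expect_equal(up, 13)

  # frequency-modulated run: duration stretches, cycle count fixed
  run2 <- makeWaggleRun(waggleRunSpec(nWaggles = 13, waggleFreq = 13,
                                      fmDepth = 0.2), fs)
  expect_equal(run2$truth$t_end, 13 / (13 * 0.98), tolerance = 1e-3)
})

test_that("wing component obeys the synchronization fraction", {
  fs <- 5000
  silent <- makeWaggleRun(waggleRunSpec(wingSyncFraction = 0), fs)
  expect_lt(band_rms(silent$wave, fs, 190, 230),
            1e-2 * band_rms(silent$wave, fs, 5, 25))

  full <- makeWaggleRun(waggleRunSpec(wingSyncFraction = 0.7), fs)
  expect_gt(band_rms(full$wave, fs, 190, 230),
            0.1 * band_rms(full$wave, fs, 5, 25))
})

test_that("waggle-run spectrogram shows concurrent low and high ridges", {
  fs <- 5000
  run <- makeWaggleRun(waggleRunSpec(nWaggles = 20), fs)
  sp <- stftSpectrogram(run$wave, fs, 0.2, 0.05)
  lo <- bandPower(sp, bandDef("WRS_L", 5, 25))
  hi <- bandPower(sp, bandDef("WRS_H", 190, 230))
  out <- bandPower(sp, bandDef("mid", 60, 180))
  mid_frames <- lo@times > 0.3 & lo@times < max(lo@times) - 0.3
  expect_true(all(lo@power[mid_frames] > 10 * out@power[mid_frames]))
  expect_true(mean(hi@power[mid_frames] > 10 * out@power[mid_frames]) > 0.5)
})

test_that("short pulses place their harmonics and respect bounds", {
  fs <- 5000
  p <- makeSRS(srsSpec(400, 0.5, nHarmonics = 2), fs)
  X <- Mod(fft(p$wave))[1:(length(p$wave) %/% 2)]
  hz <- (seq_along(X) - 1) * fs / length(p$wave)
  top <- order(X, decreasing = TRUE)[1:12]
  for (f in c(400, 800, 1200))
    expect_true(any(abs(hz[top] - f) < 5))
  expect_error(srsSpec(400, 1.2), "parameter error")
  expect_error(srsSpec(300, 0.5), "parameter error")

  silent <- makeSRS(srsSpec(400, 0.5, amplitude = 0), fs)
  expect_true(all(silent$wave == 0))
  expect_equal(silent$truth$label, "SRS")
})

test_that("fanning regularity decreases with period jitter", {
  fs <- 5000
  regs <- vapply(c(0, 0.1, 0.3), function(j) {
    f <- makeFanning(fanningSpec(100, 20, j), fs, seed = 2)
    regularityIndex(f$wave, fs, bandDef("FRS", 90, 120))
  }, 0)
  expect_gte(regs[1], 0.9)
  expect_true(all(diff(regs) < 0))
  expect_error(fanningSpec(100, 10), "parameter error")
  expect_error(fanningSpec(150, 20), "parameter error")
})

test_that("noise model components behave as specified", {
  fs <- 5000
  zero <- makeNoise(2, noiseSpec(0, 0, 50, 0, 0), fs, seed = 1)
  expect_true(all(zero == 0))

  a <- makeNoise(2, noiseSpec(), fs, seed = 9)
  b <- makeNoise(2, noiseSpec(), fs, seed = 9)
  expect_identical(a, b)

  # pink-only: periodogram log-log slope about -1 between 10 and 500 Hz
  pink <- makeNoise(20, noiseSpec(whiteRms = 0, pinkRms = 100,
                                  mainsRms = 0, crowdRms = 0), fs,
                    seed = 5)
  n <- length(pink)
  P <- Mod(fft(pink)[2:(n %/% 2)])^2
  hz <- (1:(n %/% 2 - 1)) * fs / n
  sel <- hz >= 10 & hz <= 500
  # average within log-spaced bins before regressing
  bins <- cut(log10(hz[sel]), 25)
  lp <- tapply(log10(P[sel]), bins, mean)
  lf <- tapply(log10(hz[sel]), bins, mean)
  slope <- coef(lm(lp ~ lf))[2]
  expect_equal(unname(slope), -1, tolerance = 0.2)
})

test_that("scenario rendering is deterministic and books events correctly", {
  ns <- quiet_noise()
  empty <- renderScenario(scenario(3, list(), noise = ns, seed = 1))
  expect_equal(nrow(empty$truth), 0L)
  expect_equal(nSamples(empty$recording), 15000L)

  evs <- list(
    scenarioEvent("WRS", 1, 1, waggleRunSpec(nWaggles = 10)),
    scenarioEvent("SRS", 2, 5, srsSpec(400, 0.5)),
    scenarioEvent("FRS", 3, 2, fanningSpec(100, 16)))
  sc <- scenario(25, evs, noise = ns, seed = 3)
  out1 <- renderScenario(sc)
  out2 <- renderScenario(sc)
  expect_identical(streamData(out1$recording), streamData(out2$recording))
  expect_equal(nrow(out1$truth), 3L)
  expect_equal(out1$truth$label, c("WRS", "FRS", "SRS"))  # sorted by onset
  expect_equal(out1$truth$t_start, c(1, 2, 5), tolerance = 1e-6)

  clash <- list(
    scenarioEvent("FRS", 1, 1, fanningSpec(100, 16)),
    scenarioEvent("SRS", 1, 5, srsSpec(400, 0.5)))
  expect_error(renderScenario(scenario(25, clash, noise = ns, seed = 1)),
               "scenario error: overlapping")
})

test_that("event waveforms are silent outside their spans", {
  ns <- noiseSpec(0, 0, 50, 0, 0)  # no noise at all
  evs <- list(scenarioEvent("SRS", 1, 5, srsSpec(400, 0.5)))
  out <- renderScenario(scenario(10, evs, noise = ns, seed = 1))
  x <- streamData(out$recording)[, 1]
  fs <- sampleRate(out$recording)
  before <- x[1:(5 * fs - 1)]
  after <- x[(5.6 * fs):length(x)]
  expect_true(all(before == 0))
  expect_true(all(after == 0))
})

test_that("activity traces superpose passage bumps on both channels", {
  res <- makeActivity(seq(5, 50, by = 5), duration = 60, noiseRms = 0)
  expect_equal(res$nPassages, 10L)
  expect_equal(sampleRate(res$trace), 100)
  x <- rowMeans(streamData(res$trace))
  above <- rle(x > 0.4)  # one excursion above half-height per passage
  expect_equal(sum(above$values), 10L)

  flat <- makeActivity(numeric(0), duration = 10, noiseRms = 0)
  expect_true(all(streamData(flat$trace) == 0))

  # two coincident passages double the bump amplitude
  lone <- makeActivity(5, duration = 10, noiseRms = 0)
  pair <- makeActivity(c(5, 5), duration = 10, noiseRms = 0)
  expect_equal(max(streamData(pair$trace)[, 1]),
               2 * max(streamData(lone$trace)[, 1]), tolerance = 1e-9)
})

test_that("telemetry has 120 s cadence and diurnal outdoor structure", {
  tel <- makeTelemetry(days = 1, noiseSd = 0, seed = 1)
  df <- as.data.frame(tel)
  expect_equal(nrow(df), 720L)
  expect_true(all(diff(df$timestamp) == 120))
  expect_true(all(df$temp_in == 35))

  tel2 <- makeTelemetry(days = 2, seed = 2)
  x <- as.data.frame(tel2)$temp_out
  ac <- acf(x, lag.max = 720, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[360:720]) + 359, 720, tolerance = 5)
})
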