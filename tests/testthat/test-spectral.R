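# STFT, band power, band-pass filtering, regularity index.

test_that("spectrogram satisfies Parseval per frame and in total", {
  fs <- 5000
  set.seed(3)
  x <- rnorm(fs * 2)
  sp <- stftSpectrogram(x, fs, windowS = 0.2, hopS = 0.05)
  win <- as.integer(0.2 * fs)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win)
  starts <- seq(1, length(x) - win + 1, by = as.integer(0.05 * fs))
  energy <- sum(vapply(starts, function(s)
    sum((w * x[s:(s + win - 1)])^2), 0))
  df <- fs / win
  expect_equal(sum(sp@power) * df * sum(w^2), energy, tolerance = 0.01)

  zero <- stftSpectrogram(numeric(fs), fs, 0.2, 0.05)
  expect_true(all(zero@power == 0))
  short <- stftSpectrogram(numeric(10), fs, 0.2, 0.05)
  expect_equal(nrow(short@power), 0L)
})

test_that("a pure tone concentrates power near its frequency", {
  fs <- 5000
  t <- (0:(2 * fs - 1)) / fs
  sp <- stftSpectrogram(sin(2 * pi * 100 * t), fs, windowS = 0.5,
                        hopS = 0.25)
  bin100 <- which.min(abs(sp@freqs - 100))
  near <- (bin100 - 2):(bin100 + 2)
  expect_gte(sum(sp@power[, near]) / sum(sp@power), 0.95)
})

test_that("band power selects half-open bands and is additive", {
  fs <- 5000
  t <- (0:(2 * fs - 1)) / fs
  sp <- stftSpectrogram(sin(2 * pi * 100 * t), fs, 0.2, 0.05)
  inband <- bandPower(sp, bandDef("FRS", 90, 120))
  outband <- bandPower(sp, bandDef("WRS_L", 5, 25))
  expect_gt(mean(inband@power), 1e4 * mean(outband@power))
  expect_error(bandPower(sp, bandDef("tiny", 100.1, 100.2)),
               "configuration error.*tiny")

  set.seed(8)
  spw <- stftSpectrogram(rnorm(fs), fs, 0.2, 0.05)
  a <- bandPower(spw, bandDef("a", 100, 200))
  b <- bandPower(spw, bandDef("b", 200, 300))
  ab <- bandPower(spw, bandDef("ab", 100, 300))
  n_a <- sum(spw@freqs >= 100 & spw@freqs < 200)
  n_b <- sum(spw@freqs >= 200 & spw@freqs < 300)
  expect_equal((a@power * n_a + b@power * n_b) / (n_a + n_b), ab@power,
               tolerance = 1e-12)
})

test_that("band-pass filter is selective, zero-phase and idempotent", {
  fs <- 5000
  t <- (0:(4 * fs - 1)) / fs
  mix <- sin(2 * pi * 13 * t) + sin(2 * pi * 210 * t)
  y <- bandpassFilter(mix, fs, bandDef("WRS_L", 5, 25))
  amp <- function(sig, f) 2 * abs(mean(sig * exp(-2i * pi * f * t)))
  expect_gt(amp(y, 13), 0.99)
  expect_lt(20 * log10(amp(y, 210) / 1), -40)

  expect_identical(bandpassFilter(numeric(100), fs, bandDef("x", 5, 25)),
                   numeric(100))

  tone <- sin(2 * pi * 13 * t)
  y1 <- bandpassFilter(tone, fs, bandDef("WRS_L", 5, 25))
  cc <- ccf(y1, tone, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  y2 <- bandpassFilter(y1, fs, bandDef("WRS_L", 5, 25))
  expect_lt(sqrt(mean((y2 - y1)^2)) / sqrt(mean(y1^2)), 0.01)

  expect_error(bandpassFilter(tone, fs, bandDef("hi", 2000, 3000)),
               "Nyquist")
})

test_that("regularity index separates coherent waves from noise", {
  fs <- 5000
  fan <- makeFanning(fanningSpec(100, 20, 0), fs, seed = 1)
  expect_gte(regularityIndex(fan$wave, fs, bandDef("FRS", 90, 120)), 0.9)

  set.seed(4)
  wn <- rnorm(20 * fs)
  expect_lt(regularityIndex(wn, fs, bandDef("FRS", 90, 120)), 0.3)

  expect_error(regularityIndex(rnorm(100), fs, bandDef("FRS", 90, 120)),
               "undefined result")
})
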