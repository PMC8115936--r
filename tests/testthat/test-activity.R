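# Entrance-traffic analytics.

test_that("clean, well-separated passages are recovered exactly", {
  res <- makeActivity(seq(5, 50, by = 5), duration = 60, noiseRms = 0)
  ev <- countPassages(res$trace)
  expect_equal(nrow(ev), 10L)
  expect_equal(ev$time, seq(5, 50, by = 5), tolerance = 0.1)

  flat <- makeActivity(numeric(0), duration = 30, noiseRms = 0)
  expect_equal(nrow(countPassages(flat$trace)), 0L)
})

test_that("passages at 10 dB SNR are counted within two", {
  set.seed(12)
  times <- sort(runif(20, 2, 118))
  times <- times[c(TRUE, diff(times) > 1.5)]
  while (length(times) < 20) {
    cand <- runif(1, 2, 118)
    if (all(abs(cand - times) > 1.5)) times <- sort(c(times, cand))
  }
  res <- makeActivity(times, duration = 120, amplitudePerBee = 1,
                      noiseRms = 10^(-10 / 20), seed = 13)
  ev <- countPassages(res$trace)
  expect_lte(abs(nrow(ev) - 20), 2)
})

test_that("passage count grows with true passage number on clean traces", {
  counts <- vapply(c(3, 6, 12), function(k) {
    res <- makeActivity(seq(5, by = 4, length.out = k), duration = 60,
                        noiseRms = 0)
    nrow(countPassages(res$trace))
  }, 0L)
  expect_true(all(diff(counts) > 0))
})

test_that("hourly binning conserves counts and marks coverage", {
  meta <- hiveMetadata(utcStart = "2020-04-17T06:00:00")
  res <- makeActivity(c(100, 200, 4000), duration = 3 * 3600,
                      noiseRms = 0, meta = meta)
  ev <- countPassages(res$trace)
  bins <- hourlyActivity(ev, res$trace)
  expect_equal(sum(bins$count), nrow(ev))
  expect_equal(bins$count[1:2], c(2L, 1L))
  expect_true(all(bins$covered[1:3]))

  none <- hourlyActivity(ev[0, ], res$trace)
  expect_true(all(none$count == 0))
})
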