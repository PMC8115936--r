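# Segmentation, classification rules, counting, decoding, bouts, fusion,
# evaluation.

test_that("segmentation finds bursts, honors hysteresis and merges gaps", {
  times <- seq(0, 100, by = 0.25)
  flat <- bandPowerTrace(times, rep(1, length(times)),
                         bandDef("x", 5, 25), 1, 0.25)
  expect_equal(nrow(segmentBand(flat)), 0L)

  p <- rep(0.01, length(times))
  p[times >= 50 & times < 60] <- 5
  burst <- bandPowerTrace(times, p, bandDef("x", 5, 25), 1, 0.25)
  iv <- segmentBand(burst, baselineWinS = 30)
  expect_equal(nrow(iv), 1L)
  expect_lt(abs(iv$t_start - 50), 0.25)
  expect_lt(abs(iv$t_end - 60), 0.25)

  p2 <- rep(0.01, length(times))
  p2[times >= 50 & times < 52] <- 5
  p2[times >= 52.05 & times < 54] <- 5  # gap below the merge threshold
  two <- bandPowerTrace(times, p2, bandDef("x", 5, 25), 1, 0.25)
  expect_equal(nrow(segmentBand(two, mergeGap = 0.3, baselineWinS = 30)),
               1L)
  expect_equal(nrow(segmentBand(two, mergeGap = 0.01, baselineWinS = 30)),
               2L)
})

test_that("classifier assigns the three labels by band and duration", {
  fan <- single_event_recording("FRS", fanningSpec(100, 20, 0))
  ev <- detectSignals(fan$recording)
  expect_equal(ev$label, "FRS")
  expect_gte(ev$regularity, 0.9)

  pulse <- single_event_recording("SRS", srsSpec(400, 0.5), duration = 25)
  ev <- detectSignals(pulse$recording)
  expect_equal(ev$label, "SRS")

  run <- single_event_recording("WRS", waggleRunSpec(nWaggles = 13),
                                duration = 25)
  ev <- detectSignals(run$recording)
  expect_equal(ev$label, "WRS")
  expect_equal(ev$n_waggles, 13, tolerance = 1)
  expect_equal(ev$distance_m, ev$n_waggles * 75)
})

test_that("a 10 s fanning-band burst is rejected by every rule", {
  fs <- 5000
  m <- matrix(0, 35 * fs, 6)
  b <- makeToneBurst(100, 10, 2000, fs)
  m[(10 * fs + 1):(10 * fs + length(b$wave)), 1] <- round(b$wave)
  ev <- detectSignals(esfRecording(m, fs))
  expect_equal(nrow(ev), 0L)
})

test_that("emitted events always satisfy the class duration definitions", {
  sw_srs <- sweepDurationBoundary(400, seq(0.3, 1.5, by = 0.2), "SRS")
  sw_frs <- sweepDurationBoundary(100, seq(13, 21, by = 2), "FRS")
  # collect every event from a mixed benchmark too
  bench <- benchmarkScenario(nPerClass = 5, snrDb = 12, seed = 8)
  ev <- detectSignals(bench$recording)
  srs <- ev[ev$label == "SRS", ]
  frs <- ev[ev$label == "FRS", ]
  expect_true(all(srs$t_end - srs$t_start <= 1 + 1e-9))
  expect_true(all(frs$t_end - frs$t_start >= 15 - 1e-9))
  expect_true(all(sw_srs$accepted[sw_srs$duration <= 0.9]))
  expect_false(any(sw_srs$accepted[sw_srs$duration >= 1.1]))
  expect_false(any(sw_frs$accepted[sw_frs$duration <= 14]))
  expect_true(all(sw_frs$accepted[sw_frs$duration >= 15.5]))
})

test_that("waggle counting recovers the simulated cycle count", {
  for (n in c(5, 13)) {
    out <- single_event_recording(
      "WRS", waggleRunSpec(nWaggles = n, amplitude = 3000),
      duration = 12, at = 5)
    cnt <- countWaggles(out$recording, out$truth[1, ])
    expect_lte(abs(as.integer(cnt) - n), 1)
    expect_false(attr(cnt, "lowConfidence"))
  }
  bogus <- data.frame(label = "FRS", channel = 1, t_start = 0, t_end = 1)
  expect_error(countWaggles(out$recording, bogus), "usage error")

  # forced call on pure noise is flagged
  ns_rec <- renderScenario(scenario(6, list(), noise = noiseSpec(),
                                    seed = 2))$recording
  forced <- data.frame(label = "WRS", channel = 1, t_start = 2, t_end = 3)
  cnt <- countWaggles(ns_rec, forced)
  expect_true(is.integer(as.integer(cnt)))
})

test_that("distance decoding is the exact linear dance rule", {
  cfg <- detectorConfig()
  expect_identical(decodeDistance(1, cfg), 75)
  expect_identical(decodeDistance(0, cfg), 0)
  expect_identical(decodeDistance(10, cfg), 750)
  a <- 7; b <- 12
  expect_identical(decodeDistance(a + b, cfg),
                   decodeDistance(a, cfg) + decodeDistance(b, cfg))
  expect_error(decodeDistance(-1, cfg), "usage error")
})

test_that("bout grouping follows the inter-run gap rule", {
  mk <- function(starts, ch = 1L) {
    data.frame(label = rep("WRS", length(starts)),
               channel = rep(ch, length(starts)), t_start = starts,
               t_end = starts + 1, n_waggles = c(10, 12, 11, 14)[
                 seq_along(starts)],
               mean_power = rep(1, length(starts)))
  }
  one <- groupBouts(mk(c(0, 3, 6, 9)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_runs, 4L)
  expect_equal(one$distance_m, median(c(10, 12, 11, 14)) * 75)

  two <- groupBouts(mk(c(0, 9, 18, 27)))
  expect_equal(nrow(two), 4L)

  expect_equal(nrow(groupBouts(mk(numeric(0)))), 0L)
})

test_that("cross-channel fusion merges duplicates transitively", {
  ev <- data.frame(
    label = c("WRS", "WRS", "WRS", "SRS"),
    channel = c(2L, 3L, 4L, 1L),
    t_start = c(10, 10.2, 10.4, 50),
    t_end = c(11, 11.2, 11.4, 50.5),
    n_waggles = c(12L, 13L, 12L, NA), distance_m = NA_real_,
    mean_power = c(1, 5, 2, 1), regularity = NA_real_,
    low_confidence = FALSE)
  fused <- fuseChannels(ev, overlapFrac = 0.5)
  expect_equal(nrow(fused), 2L)
  w <- fused[fused$label == "WRS", ]
  expect_equal(w$channel, 3L)        # strongest member wins
  expect_equal(w$t_start, 10)        # span union
  expect_equal(w$t_end, 11.4)

  apart <- ev
  apart$t_start <- c(10, 20, 30, 40)
  apart$t_end <- apart$t_start + 1
  expect_equal(nrow(fuseChannels(apart, 0.5)), 4L)
})

test_that("evaluation scores matching, misses and false alarms", {
  truth <- data.frame(label = rep("WRS", 10), channel = 1L,
                      t_start = seq(0, 90, by = 10),
                      t_end = seq(1, 91, by = 10))
  res <- evaluateEvents(truth, truth)
  expect_equal(res$perClass$precision, 1)
  expect_equal(res$perClass$recall, 1)

  none <- truth[0, ]
  res0 <- evaluateEvents(none, truth)
  expect_equal(res0$perClass$recall, 0)
  expect_equal(res0$perClass$precision, 0)
  expect_true(res0$perClass$precision_undefined)

  eight <- truth[1:8, ]
  eight$t_start <- eight$t_start + 0.2  # still overlapping enough
  spurious <- data.frame(label = "WRS", channel = 1L,
                         t_start = c(200, 210), t_end = c(201, 211))
  res8 <- evaluateEvents(rbind(eight, spurious), truth)
  expect_equal(res8$perClass$recall, 0.8)
  expect_equal(res8$perClass$precision, 0.8)
})

test_that("detection output is deterministic for identical input", {
  bench <- benchmarkScenario(nPerClass = 3, snrDb = 12, seed = 21)
  e1 <- detectSignals(bench$recording)
  e2 <- detectSignals(bench$recording)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  writeEventCSV(e1, f1)
  writeEventCSV(e2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
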