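# Aggregation, environment correlation, seasonal comparison, summaries.

test_that("hourly event counts conserve totals and merge into 2 h bins", {
  ev <- data.frame(
    label = c(rep("WRS", 10), "SRS", "FRS"),
    t_start = c(runif(10, 3600, 7200), 100, 9000))
  ev <- ev[order(ev$t_start), ]
  h1 <- hourlyEventCounts(ev, utcStart = 0, binS = 3600,
                          span = c(0, 10800))
  expect_equal(sum(h1$WRS), 10L)
  expect_equal(sum(h1$SRS) + sum(h1$FRS), 2L)
  h2 <- hourlyEventCounts(ev, utcStart = 0, binS = 7200,
                          span = c(0, 10800))
  expect_equal(h2$WRS[1], h1$WRS[1] + h1$WRS[2])
  expect_equal(sum(h2$WRS), sum(h1$WRS))

  empty <- hourlyEventCounts(ev[0, ], utcStart = 0)
  expect_equal(nrow(empty), 0L)
})

test_that("daily band power averages hourly means per UTC day", {
  tr_const <- bandPowerTrace(seq(0, 86399, by = 60), rep(2.5, 1440),
                             bandDef("WRS_L", 5, 25))
  out <- dailyBandPower(list(WRS_L = tr_const), utcStart = 0)
  expect_equal(out$mean_power, 2.5)

  two_days <- bandPowerTrace(seq(0, 2 * 86400 - 1, by = 60),
                             rep(c(0, 1), each = 1440),
                             bandDef("FRS", 90, 120))
  out2 <- dailyBandPower(list(FRS = two_days), utcStart = 0)
  expect_equal(out2$mean_power, c(0, 1))
  # equal-length days: mean of daily means equals the global mean
  expect_equal(mean(out2$mean_power), mean(two_days@power))
})

test_that("environment correlation reproduces closed-form cases", {
  tt <- seq(0, 999) * 120
  x <- data.frame(time = tt, value = sin(tt / 5000) + tt / 1e5)
  same <- correlateEnvironment(x, x)
  expect_equal(same$rho, 1)
  neg <- correlateEnvironment(x, data.frame(time = tt, value = -x$value))
  expect_equal(neg$rho, -1)
  # Spearman is invariant under monotone maps
  mono <- correlateEnvironment(x, data.frame(time = tt,
                                             value = exp(x$value)))
  expect_equal(mono$rho, 1)

  # too few alignable pairs -> insufficient data
  y_short <- data.frame(time = tt[1:5], value = x$value[1:5])
  expect_error(correlateEnvironment(x[1:30, ], y_short),
               "insufficient data")
})

test_that("seasonal comparison reports percent difference and Welch t", {
  a <- rep(c(1, 2), 50)
  same <- seasonalPowerComparison(a, a)
  expect_equal(same$percent_diff, 0)

  # fixed reference convention: b in the denominator
  b <- a * 1.013
  res <- seasonalPowerComparison(a, b)
  expect_equal(res$percent_diff, 100 * (1 / 1.013 - 1), tolerance = 1e-9)

  set.seed(5)
  big_a <- rnorm(2e4, mean = 1.013, sd = 0.05)
  big_b <- rnorm(2e4, mean = 1.000, sd = 0.05)
  shift <- seasonalPowerComparison(big_a, big_b)
  expect_lt(shift$p, 0.001)
  expect_equal(shift$percent_diff, 1.3, tolerance = 0.2)
})

test_that("run summaries are deterministic and conserve counts", {
  bench <- benchmarkScenario(nPerClass = 2, snrDb = 12, seed = 31)
  ev <- detectSignals(bench$recording)
  tel <- makeTelemetry(days = 1, seed = 3)
  summ <- summarizeRun(ev, utcStart = 1587362400, telemetry = tel)
  expect_equal(summ$n_events, nrow(ev))
  expect_equal(sum(unlist(summ$event_counts)), nrow(ev))
  expect_equal(sum(summ$hourly_counts$WRS), sum(ev$label == "WRS"))

  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  writeRunSummary(summ, f1)
  writeRunSummary(summarizeRun(ev, utcStart = 1587362400,
                               telemetry = tel), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  empty <- summarizeRun(detectSignals(
    renderScenario(scenario(2, list(), noise = quiet_noise(),
                            seed = 1))$recording))
  expect_equal(empty$n_events, 0L)
})

test_that("config and scenario YAML files round trip", {
  cfg <- detectorConfig(kFactor = 5, metersPerWaggle = 80)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeDetectorConfig(cfg, path)
  back <- readDetectorConfig(path)
  expect_equal(back@kFactor, 5)
  expect_equal(back@metersPerWaggle, 80)
  expect_equal(back@frsDur, c(15, Inf))
  expect_equal(back@bands$WRS_H@fLo, 190)

  sc <- scenario(30, list(
    scenarioEvent("WRS", 1, 2, waggleRunSpec(nWaggles = 9), snrDb = 10),
    scenarioEvent("FRS", 2, 5, fanningSpec(105, 17, 0.02))),
    noise = noiseSpec(whiteRms = 10), seed = 4)
  spath <- withr::local_tempfile(fileext = ".yaml")
  writeScenario(sc, spath)
  sc2 <- readScenario(spath)
  expect_equal(sc2$duration, 30)
  expect_equal(sc2$events[[1]]$spec$nWaggles, 9L)
  expect_equal(sc2$events[[1]]$snrDb, 10)
  expect_equal(sc2$events[[2]]$spec$freq, 105)
  expect_equal(sc2$noise$whiteRms, 10)
  r1 <- renderScenario(sc)
  r2 <- renderScenario(sc2)
  expect_identical(streamData(r1$recording), streamData(r2$recording))
})
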