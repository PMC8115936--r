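# Binary container, CSV conversion, WAV export, weather table.

test_that("ESF binary writes header plus 3 bytes per sample per channel", {
  rec <- esfRecording(matrix(0, 5000, 6))
  path <- withr::local_tempfile()
  expect_identical(writeESFBinary(rec, path), 64L + 3L * 6L * 5000L)
  expect_identical(file.size(path), 64 + 90000)

  empty <- esfRecording(matrix(0, 0, 6))
  path2 <- withr::local_tempfile()
  expect_identical(writeESFBinary(empty, path2), 64L)
})

test_that("ESF binary round trip is bit-exact for random recordings", {
  for (s in 1:20) {
    rec <- random_recording(n = sample(0:400, 1), seed = s)
    path <- tempfile()
    writeESFBinary(rec, path)
    back <- readESFBinary(path)
    expect_identical(streamData(back), streamData(rec))
    expect_equal(sampleRate(back), sampleRate(rec))
    expect_identical(hiveMeta(back)@hiveId, hiveMeta(rec)@hiveId)
    expect_identical(hiveMeta(back)@utcStart, hiveMeta(rec)@utcStart)
    unlink(path)
  }
})

test_that("reader rejects wrong magic and truncated payloads", {
  rec <- random_recording(n = 10)
  path <- withr::local_tempfile()
  writeESFBinary(rec, path)
  bytes <- readBin(path, "raw", file.size(path))

  bad <- bytes
  bad[1:4] <- charToRaw("NOPE")
  badfile <- withr::local_tempfile()
  writeBin(bad, badfile)
  expect_error(readESFBinary(badfile), "format error")

  cut <- bytes[seq_len(length(bytes) - 5L)]  # mid-frame cut
  cutfile <- withr::local_tempfile()
  writeBin(cut, cutfile)
  expect_error(readESFBinary(cutfile), "corruption error.*byte offset")
})

test_that("samples outside the 24-bit range are refused", {
  m <- matrix(0, 10, 6)
  m[1, 1] <- 2^23  # one past the signed maximum
  expect_error(esfRecording(m), "24-bit")
})

test_that("activity and telemetry streams round trip through their dialects", {
  act <- makeActivity(c(1, 2.5, 7), duration = 10, noiseRms = 0.01,
                      seed = 3)$trace
  path <- withr::local_tempfile()
  writeActivityBinary(act, path)
  back <- readActivityBinary(path)
  expect_equal(sampleRate(back), 100)
  # float32 payload: exact to single precision
  expect_equal(streamData(back), streamData(act), tolerance = 1e-6)

  tel <- makeTelemetry(days = 1, seed = 4)
  path2 <- withr::local_tempfile()
  writeTelemetryBinary(tel, path2)
  tback <- readTelemetryBinary(path2)
  expect_identical(tback@timestamps, tel@timestamps)
  expect_equal(tback@tempIn, tel@tempIn, tolerance = 1e-6)
  expect_equal(tback@loadCells, tel@loadCells, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("CSV chunking splits by ceiling division and concatenates back", {
  # 500 s at 50 S/s keeps the fixture small; chunk semantics are the same
  rec <- esfRecording(matrix(round(rnorm(500 * 50 * 6, sd = 100)),
                             ncol = 6), sampleRate = 50)
  chunks <- esfToCSV(rec, chunkSeconds = 200)
  expect_length(chunks, 3L)
  expect_equal(vapply(chunks, nrow, 0L), c(10000L, 10000L, 5000L))
  whole <- do.call(rbind, chunks)
  expect_equal(as.matrix(whole[, -1]), streamData(rec),
               ignore_attr = TRUE)
  # absolute Unix timestamps carry ~1e-7 s double precision
  expect_equal(diff(whole$timestamp[1:2]), 1 / 50, tolerance = 1e-4)

  one_sec <- esfRecording(matrix(0, 5000, 6))
  expect_equal(nrow(esfToCSV(one_sec)[[1]]), 5000L)
  expect_length(esfToCSV(esfRecording(matrix(0, 0, 6))), 0L)
})

test_that("WAV export is peak-normalized mono PCM preserving the tone", {
  fs <- 5000
  t <- (0:(10 * fs - 1)) / fs
  m <- matrix(0, length(t), 6)
  m[, 3] <- round(1000 * sin(2 * pi * 100 * t))
  rec <- esfRecording(m, fs)
  path <- withr::local_tempfile(fileext = ".wav")
  expect_identical(esfToWAV(rec, 3, path), length(t))
  wav <- readWAV(path)
  expect_equal(wav$sampleRate, fs)
  expect_length(wav$samples, 10L * fs)
  expect_equal(max(abs(wav$samples)), 0.95, tolerance = 1e-3)
  spec <- Mod(fft(wav$samples))[1:(5 * fs)]
  peak_hz <- (which.max(spec) - 1) / 10  # 10 s -> 0.1 Hz bins
  expect_equal(peak_hz, 100, tolerance = 0.1)

  zero <- esfRecording(matrix(0, 100, 6))
  zpath <- withr::local_tempfile(fileext = ".wav")
  esfToWAV(zero, 1, zpath)
  expect_true(all(readWAV(zpath)$samples == 0))
  expect_error(esfToWAV(rec, 7, path), "index error")
})

test_that("weather tables are validated and sorted", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    timestamp = c("2020-08-14T12:00:00", "2020-08-14T10:00:00",
                  "2020-08-14T11:00:00"),
    humidity = c(40, 60, 50), uv_index = c(5, 2, 3),
    temperature = c(25, 20, 22))
  write.csv(df, path, row.names = FALSE)
  ws <- readWeatherTable(path)
  expect_length(ws@timestamps, 3L)
  expect_true(all(diff(ws@timestamps) > 0))
  expect_equal(ws@humidity, c(60, 50, 40))  # time-sorted

  df$humidity[1] <- 150
  write.csv(df, path, row.names = FALSE)
  expect_error(readWeatherTable(path), "humidity")

  write.csv(df[, -2], path, row.names = FALSE)
  expect_error(readWeatherTable(path), "schema error.*humidity")

  df$humidity[1] <- 40
  df$timestamp[2] <- "not-a-time"
  write.csv(df, path, row.names = FALSE)
  expect_error(readWeatherTable(path), "line 3")
})
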