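# Shared fixtures: all synthetic, generated at test time.

# Faint hive noise: keeps recordings integer-valid and non-degenerate
# without drowning clean events.
quiet_noise <- function() {
  noiseSpec(whiteRms = 2, pinkRms = 2, mainsRms = 1, crowdRms = 2)
}

# A recording holding one clean event of the given kind on channel 1.
single_event_recording <- function(kind, spec, duration = 40, at = 10,
                                   seed = 7) {
  sc <- scenario(duration, list(scenarioEvent(kind, 1, at, spec)),
                 noise = quiet_noise(), seed = seed)
  renderScenario(sc)
}

# Small valid ESF recording with random integer samples.
random_recording <- function(n = 500, sampleRate = 5000, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(sample.int(2^24, n * 6, replace = TRUE) - 2^23 - 1L,
                ncol = 6)
    m[abs(m) > 2^23 - 1] <- 0
    esfRecording(m, sampleRate = sampleRate,
                 meta = hiveMetadata("hiveA", "hw01",
                                     utcStart = "2020-04-20T06:00:00"))
  })
}
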