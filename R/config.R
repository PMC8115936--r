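# Detector configuration: every rule constant of the classifier in one
# object, serializable to/from YAML so a deployment can tune bands and
# durations without touching code.

#' Detector configuration
#'
#' Holds the frequency bands, STFT resolutions, segmentation thresholds and
#' class duration rules used by [detectSignals()]. All durations are in
#' seconds, frequencies in Hz.
#'
#' @slot bands named list of [BandDef-class]: `WRS_L` (abdomen waggling,
#'   5-25 Hz), `WRS_H` (wing vibration, 190-230 Hz), `SRS` (short pulses,
#'   350-2400 Hz), `FRS` (fanning, 90-120 Hz) and the environmental
#'   comparison band `ENV_380_400`.
#' @slot lowWindow,highWindow STFT `c(window, hop)` in seconds for the
#'   low-frequency (<= 30 Hz) and high-frequency analyses.
#' @slot kFactor segmentation threshold as a multiple of the rolling-median
#'   baseline of the band-power trace.
#' @slot hysteresis falling-edge threshold as a fraction of the rising one.
#' @slot floorFrac absolute threshold floor as a fraction of the trace peak,
#'   guarding against near-zero baselines in quiet recordings.
#' @slot baselineWin named per-band rolling-median window, seconds.
#' @slot mergeGap intervals closer than this merge into one, seconds.
#' @slot srsDur,frsDur,wrsDur `c(min, max)` duration rules per class.
#' @slot frsRegularityMin minimum spectral regularity index for fanning.
#' @slot wrsConcurrencyMin minimum fraction of a WRS_L interval that must be
#'   concurrently active in WRS_H.
#' @slot boutMaxGap maximum within-bout gap between waggle runs, seconds.
#' @slot metersPerWaggle distance decoded per counted waggle cycle, meters.
#' @slot fuseOverlap cross-channel merge threshold (fraction of the shorter
#'   event).
#' @slot matchOverlap evaluation match threshold (fraction of the truth
#'   span).
#' @slot waggleRmsFrac waggle counts are flagged low-confidence when the
#'   band-passed RMS falls below this fraction of the raw span RMS.
#' @slot wrsDominanceMin minimum power of the abdomen band relative to the
#'   strongest competing band (SRS, FRS) over a candidate span; rejects
#'   spectral-leakage ghosts of strong events in other bands.
#' @exportClass DetectorConfig
setClass("DetectorConfig",
  representation(bands = "list", lowWindow = "numeric",
                 highWindow = "numeric", kFactor = "numeric",
                 hysteresis = "numeric", floorFrac = "numeric",
                 baselineWin = "numeric", mergeGap = "numeric",
                 srsDur = "numeric", frsDur = "numeric", wrsDur = "numeric",
                 frsRegularityMin = "numeric", wrsConcurrencyMin = "numeric",
                 boutMaxGap = "numeric", metersPerWaggle = "numeric",
                 fuseOverlap = "numeric", matchOverlap = "numeric",
                 waggleRmsFrac = "numeric", wrsDominanceMin = "numeric"))

setValidity("DetectorConfig", function(object) {
  msg <- character()
  need <- c("WRS_L", "WRS_H", "SRS", "FRS")
  if (!all(need %in% names(object@bands)))
    msg <- c(msg, paste("bands must include", paste(need, collapse = ", ")))
  if (!all(vapply(object@bands, is, TRUE, class2 = "BandDef")))
    msg <- c(msg, "bands must be BandDef objects")
  if (object@kFactor <= 1)
    msg <- c(msg, "kFactor must exceed 1")
  if (object@hysteresis <= 0 || object@hysteresis > 1)
    msg <- c(msg, "hysteresis must lie in (0, 1]")
  for (nm in c("srsDur", "frsDur", "wrsDur")) {
    d <- slot(object, nm)
    if (length(d) != 2L || d[1] <= 0 || d[1] >= d[2])
      msg <- c(msg, paste(nm, "must be c(min, max) with 0 < min < max"))
  }
  if (object@metersPerWaggle <= 0)
    msg <- c(msg, "metersPerWaggle must be positive")
  if (object@boutMaxGap <= 0)
    msg <- c(msg, "boutMaxGap must be positive")
  if (length(msg)) msg else TRUE
})

#' Build a detector configuration
#'
#' Defaults implement the classification rules for the three stereotyped
#' colony signals: fanning lasts longer than 15 s in 90-120 Hz with highly
#' regular waves; short pulses last under 1 s with fundamentals above
#' 350 Hz; waggle runs pair a 5-25 Hz abdomen component with a partially
#' synchronized 190-230 Hz wing component, and each counted waggle cycle
#' decodes 75 m of foraging distance.
#'
#' @param bands named list of [BandDef-class]; see
#'   [DetectorConfig-class].
#' @param lowWindow,highWindow STFT `c(window, hop)` seconds.
#' @param kFactor,hysteresis,floorFrac,baselineWin,mergeGap segmentation
#'   parameters; `baselineWin` is a named vector of per-band rolling-median
#'   windows (the FRS baseline must be much longer than one fanning event).
#' @param srsDur,frsDur,wrsDur per-class `c(min, max)` duration rules, s.
#' @param frsRegularityMin,wrsConcurrencyMin classification minima.
#' @param boutMaxGap,metersPerWaggle dance-bout gap and distance decoding
#'   constant.
#' @param fuseOverlap,matchOverlap,waggleRmsFrac see
#'   [DetectorConfig-class].
#' @return A [DetectorConfig-class] object.
#' @export
detectorConfig <- function(
    bands = list(WRS_L = bandDef("WRS_L", 5, 25),
                 WRS_H = bandDef("WRS_H", 190, 230),
                 SRS = bandDef("SRS", 350, 2400),
                 FRS = bandDef("FRS", 90, 120),
                 ENV_380_400 = bandDef("ENV_380_400", 380, 400)),
    lowWindow = c(window = 1.0, hop = 0.25),
    highWindow = c(window = 0.2, hop = 0.05),
    kFactor = 4, hysteresis = 0.5, floorFrac = 1e-4,
    baselineWin = c(WRS_L = 30, WRS_H = 5, SRS = 5, FRS = 60),
    mergeGap = 0.1,
    srsDur = c(0.02, 1), frsDur = c(15, Inf), wrsDur = c(0.4, 10),
    frsRegularityMin = 0.6, wrsConcurrencyMin = 0.3,
    boutMaxGap = 5, metersPerWaggle = 75,
    fuseOverlap = 0.5, matchOverlap = 0.3, waggleRmsFrac = 0.05,
    wrsDominanceMin = 0.05) {
  new("DetectorConfig", bands = bands, lowWindow = lowWindow,
      highWindow = highWindow, kFactor = kFactor, hysteresis = hysteresis,
      floorFrac = floorFrac, baselineWin = baselineWin, mergeGap = mergeGap,
      srsDur = srsDur, frsDur = frsDur, wrsDur = wrsDur,
      frsRegularityMin = frsRegularityMin,
      wrsConcurrencyMin = wrsConcurrencyMin, boutMaxGap = boutMaxGap,
      metersPerWaggle = metersPerWaggle, fuseOverlap = fuseOverlap,
      matchOverlap = matchOverlap, waggleRmsFrac = waggleRmsFrac,
      wrsDominanceMin = wrsDominanceMin)
}

setMethod("show", "DetectorConfig", function(object) {
  cat("DetectorConfig\n")
  for (b in object@bands)
    cat(sprintf("  band %-12s [%g, %g) Hz\n", b@name, b@fLo, b@fHi))
  cat(sprintf("  k = %g, hysteresis = %g, merge gap = %g s\n",
              object@kFactor, object@hysteresis, object@mergeGap))
  cat(sprintf("  SRS %g-%g s | FRS > %g s (regularity >= %g) | WRS %g-%g s\n",
              object@srsDur[1], object@srsDur[2], object@frsDur[1],
              object@frsRegularityMin, object@wrsDur[1], object@wrsDur[2]))
  cat(sprintf("  %g m per waggle, bout gap < %g s\n",
              object@metersPerWaggle, object@boutMaxGap))
})

# Plain-list snapshot (used in run summaries and YAML round trips).
config_as_list <- function(cfg) {
  list(
    bands = lapply(cfg@bands, function(b)
      list(name = b@name, f_lo = b@fLo, f_hi = b@fHi)),
    low_window = as.list(stats::setNames(as.numeric(cfg@lowWindow),
                                         c("window", "hop"))),
    high_window = as.list(stats::setNames(as.numeric(cfg@highWindow),
                                          c("window", "hop"))),
    k_factor = cfg@kFactor, hysteresis = cfg@hysteresis,
    floor_frac = cfg@floorFrac,
    baseline_win = as.list(cfg@baselineWin),
    merge_gap = cfg@mergeGap,
    srs_dur = cfg@srsDur, frs_dur = cfg@frsDur, wrs_dur = cfg@wrsDur,
    frs_regularity_min = cfg@frsRegularityMin,
    wrs_concurrency_min = cfg@wrsConcurrencyMin,
    bout_max_gap = cfg@boutMaxGap, meters_per_waggle = cfg@metersPerWaggle,
    fuse_overlap = cfg@fuseOverlap, match_overlap = cfg@matchOverlap,
    waggle_rms_frac = cfg@waggleRmsFrac,
    wrs_dominance_min = cfg@wrsDominanceMin)
}

#' Read / write detector configuration as YAML
#'
#' Only keys present in the file override the defaults, so a config file can
#' be as small as one changed threshold.
#'
#' @param path YAML file path.
#' @return [readDetectorConfig()] returns a [DetectorConfig-class];
#'   [writeDetectorConfig()] returns `path` invisibly.
#' @export
readDetectorConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- detectorConfig()
  if (!is.null(raw$bands)) {
    bands <- lapply(raw$bands, function(b) bandDef(b$name, b$f_lo, b$f_hi))
    names(bands) <- vapply(bands, function(b) b@name, "")
    cfg@bands <- bands
  }
  num2 <- function(x, nm) stats::setNames(as.numeric(unlist(x)), nm)
  if (!is.null(raw$low_window))
    cfg@lowWindow <- num2(raw$low_window[c("window", "hop")],
                          c("window", "hop"))
  if (!is.null(raw$high_window))
    cfg@highWindow <- num2(raw$high_window[c("window", "hop")],
                           c("window", "hop"))
  scalars <- c(k_factor = "kFactor", hysteresis = "hysteresis",
               floor_frac = "floorFrac", merge_gap = "mergeGap",
               frs_regularity_min = "frsRegularityMin",
               wrs_concurrency_min = "wrsConcurrencyMin",
               bout_max_gap = "boutMaxGap",
               meters_per_waggle = "metersPerWaggle",
               fuse_overlap = "fuseOverlap", match_overlap = "matchOverlap",
               waggle_rms_frac = "waggleRmsFrac",
               wrs_dominance_min = "wrsDominanceMin")
  for (key in names(scalars))
    if (!is.null(raw[[key]]))
      slot(cfg, scalars[[key]]) <- as.numeric(raw[[key]])
  durs <- c(srs_dur = "srsDur", frs_dur = "frsDur", wrs_dur = "wrsDur")
  for (key in names(durs)) {
    if (!is.null(raw[[key]])) {
      v <- as.numeric(unlist(raw[[key]]))
      v[is.na(v)] <- Inf
      slot(cfg, durs[[key]]) <- v
    }
  }
  if (!is.null(raw$baseline_win))
    cfg@baselineWin <- unlist(raw$baseline_win)
  validObject(cfg)
  cfg
}

#' Read / write a simulation scenario as YAML
#'
#' Schema: top-level `duration`, `seed`, `sample_rate`, a `noise` mapping
#' (`white_rms`, `pink_rms`, `mains_hz`, `mains_rms`, `crowd_rms`) and an
#' `events` list whose entries carry `kind` (WRS/SRS/FRS), `channel`,
#' `t_start`, optional `snr_db`, and a `spec` mapping with the class
#' parameters (waggle runs: `waggle_freq`, `wing_freq`, `n_waggles`,
#' `wing_sync_fraction`, `amplitude`, `fm_depth`; pulses: `fundamental`,
#' `duration`, `n_harmonics`, `amplitude`; fanning: `freq`, `duration`,
#' `jitter`, `amplitude`).
#'
#' @param path YAML file path.
#' @return [readScenario()] returns a [scenario()] list.
#' @export
readScenario <- function(path) {
  raw <- yaml::read_yaml(path)
  nz <- raw$noise %||% list()
  noise <- noiseSpec(
    whiteRms = nz$white_rms %||% 200, pinkRms = nz$pink_rms %||% 400,
    mainsHz = nz$mains_hz %||% 50, mainsRms = nz$mains_rms %||% 300,
    crowdRms = nz$crowd_rms %||% 400)
  events <- lapply(raw$events, function(e) {
    s <- e$spec
    spec <- switch(e$kind,
      WRS = waggleRunSpec(
        waggleFreq = s$waggle_freq %||% 13,
        wingFreq = s$wing_freq %||% 210,
        nWaggles = s$n_waggles %||% 13,
        wingSyncFraction = s$wing_sync_fraction %||% 0.7,
        amplitude = s$amplitude %||% 1000,
        fmDepth = s$fm_depth %||% 0.2),
      SRS = srsSpec(fundamental = s$fundamental %||% 400,
                    duration = s$duration %||% 0.5,
                    nHarmonics = s$n_harmonics %||% 2,
                    amplitude = s$amplitude %||% 1000),
      FRS = fanningSpec(freq = s$freq %||% 100,
                        duration = s$duration %||% 20,
                        jitter = s$jitter %||% 0,
                        amplitude = s$amplitude %||% 1000),
      stop("unknown event kind: ", e$kind))
    scenarioEvent(e$kind, e$channel, e$t_start, spec,
                  snrDb = e$snr_db %||% NA)
  })
  scenario(duration = raw$duration, events = events, noise = noise,
           seed = raw$seed %||% 1,
           sampleRate = raw$sample_rate %||% 5000)
}

#' @rdname readScenario
#' @param sc a [scenario()] list.
#' @export
writeScenario <- function(sc, path) {
  spec_list <- function(ev) {
    s <- ev$spec
    switch(ev$kind,
      WRS = list(waggle_freq = s$waggleFreq, wing_freq = s$wingFreq,
                 n_waggles = s$nWaggles,
                 wing_sync_fraction = s$wingSyncFraction,
                 amplitude = s$amplitude, fm_depth = s$fmDepth),
      SRS = list(fundamental = s$fundamental, duration = s$duration,
                 n_harmonics = s$nHarmonics, amplitude = s$amplitude),
      FRS = list(freq = s$freq, duration = s$duration, jitter = s$jitter,
                 amplitude = s$amplitude))
  }
  lst <- list(
    duration = sc$duration, seed = sc$seed, sample_rate = sc$sampleRate,
    noise = list(white_rms = sc$noise$whiteRms,
                 pink_rms = sc$noise$pinkRms, mains_hz = sc$noise$mainsHz,
                 mains_rms = sc$noise$mainsRms,
                 crowd_rms = sc$noise$crowdRms),
    events = lapply(sc$events, function(ev) {
      out <- list(kind = ev$kind, channel = ev$channel,
                  t_start = ev$tStart, spec = spec_list(ev))
      if (!is.na(ev$snrDb)) out$snr_db <- ev$snrDb
      out
    }))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname readDetectorConfig
#' @param cfg a [DetectorConfig-class].
#' @export
writeDetectorConfig <- function(cfg, path) {
  lst <- config_as_list(cfg)
  lst$frs_dur[!is.finite(lst$frs_dur)] <- NA  # YAML has no Inf literal
  yaml::write_yaml(lst, path)
  invisible(path)
}
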