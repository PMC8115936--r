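# S4 containers for the three hive data streams and derived spectral objects.
#
# Amplitudes of ESF samples are ADC counts of the 24-bit converter
# (dimensionless); activity samples are arbitrary capacitance units.

ADC_MAX <- 2^23 - 1

#' Hive and hardware metadata attached to every stream
#'
#' @slot hiveId opaque non-empty hive identifier (at most 16 ASCII bytes in
#'   the binary container).
#' @slot hardwareId opaque non-empty recorder identifier.
#' @slot latitude,longitude decimal degrees; `NA` when no fix is available.
#' @slot utcStart absolute recording start, Unix seconds (UTC).
#' @exportClass HiveMetadata
setClass("HiveMetadata",
  representation(hiveId = "character", hardwareId = "character",
                 latitude = "numeric", longitude = "numeric",
                 utcStart = "numeric"),
  prototype(hiveId = "hive", hardwareId = "hw",
            latitude = NA_real_, longitude = NA_real_,
            utcStart = 0))

setValidity("HiveMetadata", function(object) {
  msg <- character()
  if (length(object@hiveId) != 1L || !nzchar(object@hiveId))
    msg <- c(msg, "hiveId must be a single non-empty string")
  if (length(object@hardwareId) != 1L || !nzchar(object@hardwareId))
    msg <- c(msg, "hardwareId must be a single non-empty string")
  if (nchar(object@hiveId, type = "bytes") > 16L)
    msg <- c(msg, "hiveId exceeds 16 bytes")
  if (nchar(object@hardwareId, type = "bytes") > 16L)
    msg <- c(msg, "hardwareId exceeds 16 bytes")
  if (length(object@utcStart) != 1L || !is.finite(object@utcStart) ||
      object@utcStart < 0)
    msg <- c(msg, "utcStart must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct hive metadata
#'
#' @param hiveId,hardwareId identifiers (non-empty, at most 16 ASCII bytes).
#' @param latitude,longitude optional position in decimal degrees.
#' @param utcStart recording start as Unix seconds, a `POSIXct`, or an
#'   ISO-8601 string; stored at seconds resolution.
#' @return A [HiveMetadata-class] object.
#' @export
hiveMetadata <- function(hiveId = "hive", hardwareId = "hw",
                         latitude = NA_real_, longitude = NA_real_,
                         utcStart = "2020-04-20T06:00:00") {
  new("HiveMetadata", hiveId = hiveId, hardwareId = hardwareId,
      latitude = as.numeric(latitude), longitude = as.numeric(longitude),
      utcStart = floor(parse_utc(utcStart)))
}

#' Six-channel electrostatic-field recording
#'
#' Samples are ADC counts: integer-valued and representable in the signed
#' 24-bit range of the recorder's converter.
#'
#' @slot samples numeric matrix, one column per ESF channel (6 columns).
#' @slot sampleRate samples per second per channel (default 5000).
#' @slot meta a [HiveMetadata-class].
#' @exportClass ESFRecording
setClass("ESFRecording",
  representation(samples = "matrix", sampleRate = "numeric",
                 meta = "HiveMetadata"))

setValidity("ESFRecording", function(object) {
  msg <- character()
  if (ncol(object@samples) != 6L)
    msg <- c(msg, "an ESF recording has exactly 6 channels")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be numeric")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (nrow(object@samples) > 0) {
    if (anyNA(object@samples) || any(!is.finite(object@samples)))
      msg <- c(msg, "samples must be finite")
    else {
      if (max(abs(object@samples)) > ADC_MAX)
        msg <- c(msg, "samples exceed the signed 24-bit range")
      if (!is_wholenumber(object@samples))
        msg <- c(msg, "samples must be integer-valued ADC counts")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ESF recording
#'
#' @param samples numeric matrix with 6 columns (one per channel) of
#'   integer-valued ADC counts in the signed 24-bit range.
#' @param sampleRate samples per second (default 5000).
#' @param meta a [HiveMetadata-class].
#' @return An [ESFRecording-class].
#' @export
esfRecording <- function(samples, sampleRate = 5000, meta = hiveMetadata()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL
  new("ESFRecording", samples = samples, sampleRate = as.numeric(sampleRate),
      meta = meta)
}

#' Two-channel entrance-capacitance activity trace
#'
#' @slot samples numeric matrix with 2 columns (entrance ring sensors),
#'   arbitrary capacitance units.
#' @slot sampleRate samples per second (default 100).
#' @slot meta a [HiveMetadata-class].
#' @exportClass ActivityTrace
setClass("ActivityTrace",
  representation(samples = "matrix", sampleRate = "numeric",
                 meta = "HiveMetadata"))

setValidity("ActivityTrace", function(object) {
  msg <- character()
  if (ncol(object@samples) != 2L)
    msg <- c(msg, "an activity trace has exactly 2 channels")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (nrow(object@samples) > 0 && anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an activity trace
#' @param samples numeric matrix with 2 columns.
#' @param sampleRate samples per second (default 100).
#' @param meta a [HiveMetadata-class].
#' @export
activityTrace <- function(samples, sampleRate = 100, meta = hiveMetadata()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL
  new("ActivityTrace", samples = samples, sampleRate = as.numeric(sampleRate),
      meta = meta)
}

#' Hive telemetry at 120-second cadence
#'
#' @slot timestamps Unix seconds (UTC), strictly increasing, nominal
#'   cadence 120 s.
#' @slot tempIn,tempOut hive / ambient temperature, degrees C.
#' @slot humIn,humOut relative humidity, percent, in `[0, 100]`.
#' @slot loadCells matrix with 3 columns, one per load cell, kg.
#' @slot mcuTemp microcontroller temperature, degrees C.
#' @slot meta a [HiveMetadata-class].
#' @exportClass TelemetrySeries
setClass("TelemetrySeries",
  representation(timestamps = "numeric", tempIn = "numeric",
                 tempOut = "numeric", humIn = "numeric", humOut = "numeric",
                 loadCells = "matrix", mcuTemp = "numeric",
                 meta = "HiveMetadata"))

setValidity("TelemetrySeries", function(object) {
  msg <- character()
  n <- length(object@timestamps)
  if (n > 1 && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  lens <- c(length(object@tempIn), length(object@tempOut),
            length(object@humIn), length(object@humOut),
            nrow(object@loadCells), length(object@mcuTemp))
  if (any(lens != n))
    msg <- c(msg, "all telemetry fields must have one value per timestamp")
  if (ncol(object@loadCells) != 3L)
    msg <- c(msg, "loadCells must have 3 columns")
  hum <- c(object@humIn, object@humOut)
  if (length(hum) && (any(hum < 0, na.rm = TRUE) || any(hum > 100, na.rm = TRUE)))
    msg <- c(msg, "humidity must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct a telemetry series
#' @param timestamps Unix seconds (UTC), strictly increasing.
#' @param tempIn,tempOut,humIn,humOut,mcuTemp per-record sensor values.
#' @param loadCells numeric matrix with 3 columns, kg.
#' @param meta a [HiveMetadata-class].
#' @export
telemetrySeries <- function(timestamps, tempIn, tempOut, humIn, humOut,
                            loadCells, mcuTemp, meta = hiveMetadata()) {
  loadCells <- as.matrix(loadCells)
  storage.mode(loadCells) <- "double"
  new("TelemetrySeries", timestamps = as.numeric(timestamps),
      tempIn = as.numeric(tempIn), tempOut = as.numeric(tempOut),
      humIn = as.numeric(humIn), humOut = as.numeric(humOut),
      loadCells = loadCells, mcuTemp = as.numeric(mcuTemp), meta = meta)
}

#' Local weather series (replacement for a weather-service download)
#'
#' @slot timestamps Unix seconds (UTC), strictly increasing.
#' @slot humidity outdoor relative humidity, percent.
#' @slot uvIndex dimensionless UV index.
#' @slot temperature outdoor temperature, degrees C.
#' @exportClass WeatherSeries
setClass("WeatherSeries",
  representation(timestamps = "numeric", humidity = "numeric",
                 uvIndex = "numeric", temperature = "numeric"))

setValidity("WeatherSeries", function(object) {
  msg <- character()
  n <- length(object@timestamps)
  if (n > 1 && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(object@humidity) != n || length(object@uvIndex) != n ||
      length(object@temperature) != n)
    msg <- c(msg, "all weather fields must have one value per timestamp")
  if (length(object@humidity) &&
      (any(object@humidity < 0) || any(object@humidity > 100)))
    msg <- c(msg, "humidity must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct a weather series
#' @param timestamps Unix seconds (UTC).
#' @param humidity percent relative humidity.
#' @param uvIndex dimensionless UV index.
#' @param temperature degrees C.
#' @export
weatherSeries <- function(timestamps, humidity, uvIndex, temperature) {
  new("WeatherSeries", timestamps = as.numeric(timestamps),
      humidity = as.numeric(humidity), uvIndex = as.numeric(uvIndex),
      temperature = as.numeric(temperature))
}

#' Named frequency band
#'
#' Bands are half-open `[fLo, fHi)` so adjacent bands partition cleanly.
#'
#' @slot name band label, e.g. `"WRS_L"`.
#' @slot fLo,fHi band edges in Hz, `0 <= fLo < fHi`.
#' @exportClass BandDef
setClass("BandDef",
  representation(name = "character", fLo = "numeric", fHi = "numeric"))

setValidity("BandDef", function(object) {
  if (length(object@fLo) != 1L || length(object@fHi) != 1L ||
      object@fLo < 0 || object@fLo >= object@fHi)
    "band edges must satisfy 0 <= fLo < fHi"
  else TRUE
})

#' Construct a band definition
#' @param name band label.
#' @param fLo,fHi band edges, Hz (half-open `[fLo, fHi)`).
#' @export
bandDef <- function(name, fLo, fHi) {
  new("BandDef", name = as.character(name), fLo = as.numeric(fLo),
      fHi = as.numeric(fHi))
}

#' Short-time Fourier spectrogram
#'
#' Power is a one-sided spectral density (amplitude^2 per Hz) per frame.
#'
#' @slot times frame centers, seconds from signal start.
#' @slot freqs bin centers, Hz.
#' @slot power frames x bins matrix, non-negative.
#' @slot windowS,hopS analysis window length and hop, seconds.
#' @slot sampleRate source sample rate, Hz.
#' @exportClass Spectrogram
setClass("Spectrogram",
  representation(times = "numeric", freqs = "numeric", power = "matrix",
                 windowS = "numeric", hopS = "numeric",
                 sampleRate = "numeric"))

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@times) ||
      ncol(object@power) != length(object@freqs))
    msg <- c(msg, "power must be length(times) x length(freqs)")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@freqs) > 1 && any(diff(object@freqs) <= 0))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(object@power) && any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-band mean power trace derived from a spectrogram
#'
#' @slot times frame centers, seconds (same grid as the source spectrogram).
#' @slot power mean in-band spectral power per frame, non-negative.
#' @slot band the [BandDef-class] averaged over.
#' @slot windowS,hopS analysis window and hop of the source spectrogram.
#' @exportClass BandPowerTrace
setClass("BandPowerTrace",
  representation(times = "numeric", power = "numeric", band = "BandDef",
                 windowS = "numeric", hopS = "numeric"))

setValidity("BandPowerTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@power))
    msg <- c(msg, "times and power must have equal length")
  if (length(object@power) && any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a band-power trace
#' @param times frame centers, s.
#' @param power per-frame mean in-band power.
#' @param band a [BandDef-class].
#' @param windowS,hopS source spectrogram window and hop, s (`NA` when the
#'   trace was not derived from a spectrogram).
#' @export
bandPowerTrace <- function(times, power, band, windowS = NA_real_,
                           hopS = NA_real_) {
  new("BandPowerTrace", times = as.numeric(times), power = as.numeric(power),
      band = band, windowS = as.numeric(windowS), hopS = as.numeric(hopS))
}

## ---- accessors ----

#' @rdname accessors
#' @param object a hiveESF container.
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("durationSec", function(object) standardGeneric("durationSec"))
#' @rdname accessors
#' @export
setGeneric("hiveMeta", function(object) standardGeneric("hiveMeta"))
#' @rdname accessors
#' @export
setGeneric("streamData", function(object) standardGeneric("streamData"))

#' Accessors for hiveESF containers
#'
#' `sampleRate`, `nSamples`, `nChannels` and `durationSec` describe the
#' sampling grid; `hiveMeta` returns the attached [HiveMetadata-class];
#' `streamData` returns the raw sample matrix.
#'
#' @name accessors
NULL

#' @rdname accessors
setMethod("sampleRate", "ESFRecording", function(object) object@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "ActivityTrace", function(object) object@sampleRate)
#' @rdname accessors
setMethod("nSamples", "ESFRecording", function(object) nrow(object@samples))
#' @rdname accessors
setMethod("nSamples", "ActivityTrace", function(object) nrow(object@samples))
#' @rdname accessors
setMethod("nChannels", "ESFRecording", function(object) ncol(object@samples))
#' @rdname accessors
setMethod("nChannels", "ActivityTrace", function(object) ncol(object@samples))
#' @rdname accessors
setMethod("durationSec", "ESFRecording",
          function(object) nrow(object@samples) / object@sampleRate)
#' @rdname accessors
setMethod("durationSec", "ActivityTrace",
          function(object) nrow(object@samples) / object@sampleRate)
#' @rdname accessors
setMethod("hiveMeta", "ESFRecording", function(object) object@meta)
#' @rdname accessors
setMethod("hiveMeta", "ActivityTrace", function(object) object@meta)
#' @rdname accessors
setMethod("hiveMeta", "TelemetrySeries", function(object) object@meta)
#' @rdname accessors
setMethod("streamData", "ESFRecording", function(object) object@samples)
#' @rdname accessors
setMethod("streamData", "ActivityTrace", function(object) object@samples)

#' Telemetry as a data frame
#'
#' @param x a [TelemetrySeries-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @return data.frame with columns `timestamp`, `temp_in`, `temp_out`,
#'   `hum_in`, `hum_out`, `load1`..`load3`, `mcu_temp`.
#' @export
as.data.frame.TelemetrySeries <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(timestamp = x@timestamps, temp_in = x@tempIn,
             temp_out = x@tempOut, hum_in = x@humIn, hum_out = x@humOut,
             load1 = x@loadCells[, 1], load2 = x@loadCells[, 2],
             load3 = x@loadCells[, 3], mcu_temp = x@mcuTemp)
}

#' Weather as a data frame
#'
#' @param x a [WeatherSeries-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @export
as.data.frame.WeatherSeries <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(timestamp = x@timestamps, humidity = x@humidity,
             uv_index = x@uvIndex, temperature = x@temperature)
}

## ---- show ----

setMethod("show", "HiveMetadata", function(object) {
  cat("HiveMetadata | hive:", object@hiveId, "| hw:", object@hardwareId,
      "| start:", iso8601(object@utcStart), "UTC\n")
})

setMethod("show", "ESFRecording", function(object) {
  cat(sprintf("ESFRecording: %d channels x %d samples @ %g S/s (%.1f s)\n",
              ncol(object@samples), nrow(object@samples), object@sampleRate,
              durationSec(object)))
  show(object@meta)
})

setMethod("show", "ActivityTrace", function(object) {
  cat(sprintf("ActivityTrace: 2 channels x %d samples @ %g S/s (%.1f s)\n",
              nrow(object@samples), object@sampleRate, durationSec(object)))
})

setMethod("show", "TelemetrySeries", function(object) {
  n <- length(object@timestamps)
  cat(sprintf("TelemetrySeries: %d records", n))
  if (n > 1)
    cat(sprintf(", median cadence %.0f s", median(diff(object@timestamps))))
  cat("\n")
})

setMethod("show", "BandDef", function(object) {
  cat(sprintf("BandDef %s: [%g, %g) Hz\n", object@name, object@fLo,
              object@fHi))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf(
    "Spectrogram: %d frames x %d bins | window %.3g s, hop %.3g s\n",
    nrow(object@power), ncol(object@power), object@windowS, object@hopS))
})

setMethod("show", "BandPowerTrace", function(object) {
  cat(sprintf("BandPowerTrace [%s]: %d frames\n", object@band@name,
              length(object@times)))
})
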