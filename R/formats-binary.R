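# Binary recording container.
#
# One 64-byte header serves all three streams; the magic selects the
# payload layout:
#   "ESF1"  channel-interleaved 24-bit two's-complement little-endian
#   "ACT1"  2-channel interleaved IEEE-754 float32 little-endian
#   "TEL1"  fixed 8-field float32 records (temp_in, temp_out, hum_in,
#           hum_out, load1..load3, mcu_temp); timestamps are implied by
#           utc_start + index * interval
#
# Header layout (offsets in bytes, little-endian):
#   0  magic (4 ASCII)             5  format version (u8, = 1)
#   5  sample rate or telemetry interval in s (u32)
#   9  channel/field count (u8)   10  utc_start Unix seconds (u64)
#  18  hive_id (16, NUL padded)   34  hardware_id (16, NUL padded)
#  50  reserved zeros to 64

HEADER_SIZE <- 64L

pad_id <- function(x) {
  r <- charToRaw(x)
  c(r, raw(16L - length(r)))
}

u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

raw_u32 <- function(r) {
  sum(as.numeric(r) * c(1, 256, 65536, 16777216))
}

u64_raw <- function(x) {
  x <- as.numeric(x)
  out <- raw(8)
  for (i in 1:8) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_u64 <- function(r) {
  sum(as.numeric(r) * 256^(0:7))
}

make_header <- function(magic, rate, nch, meta) {
  h <- raw(HEADER_SIZE)
  h[1:4] <- charToRaw(magic)
  h[5] <- as.raw(1L)
  h[6:9] <- u32_raw(rate)
  h[10] <- as.raw(nch)
  h[11:18] <- u64_raw(meta@utcStart)
  h[19:34] <- pad_id(meta@hiveId)
  h[35:50] <- pad_id(meta@hardwareId)
  h
}

parse_header <- function(h, expect_magic) {
  magic <- rawToChar(h[1:4])
  if (magic != expect_magic)
    stop(sprintf("format error: expected magic '%s', found '%s'",
                 expect_magic, magic), call. = FALSE)
  version <- as.integer(h[5])
  if (version != 1L)
    stop(sprintf("format error: unsupported version %d", version),
         call. = FALSE)
  strip <- function(r) rawToChar(r[r != as.raw(0)])
  list(rate = raw_u32(h[6:9]), nch = as.integer(h[10]),
       utc_start = raw_u64(h[11:18]),
       hive_id = strip(h[19:34]), hardware_id = strip(h[35:50]))
}

# Pack signed integers into 24-bit little-endian triplets.
pack_i24 <- function(x) {
  if (any(abs(x) > ADC_MAX))
    stop("range error: sample outside the signed 24-bit range",
         call. = FALSE)
  v <- round(x)
  v[v < 0] <- v[v < 0] + 2^24
  out <- matrix(0, nrow = 3, ncol = length(v))
  out[1, ] <- v %% 256
  out[2, ] <- (v %/% 256) %% 256
  out[3, ] <- v %/% 65536
  as.raw(out)
}

unpack_i24 <- function(r) {
  m <- matrix(as.numeric(r), nrow = 3)
  v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
  v[v >= 2^23] <- v[v >= 2^23] - 2^24
  v
}

# Drain a binary connection in chunks (readBin needs a byte count up front).
read_all <- function(con, chunk = 8388608L) {
  parts <- list()
  repeat {
    p <- readBin(con, "raw", chunk)
    if (!length(p)) break
    parts[[length(parts) + 1L]] <- p
    if (length(p) < chunk) break
  }
  do.call(c, c(list(raw(0)), parts))
}

resolve_sink <- function(sink, open_mode) {
  if (is.character(sink)) {
    con <- file(sink, open_mode)
    list(con = con, close = TRUE)
  } else {
    list(con = sink, close = FALSE)
  }
}

#' Write an ESF recording to the binary container
#'
#' Samples are stored channel-interleaved as 24-bit two's-complement
#' little-endian integers after a 64-byte header.
#'
#' @param rec an [ESFRecording-class].
#' @param sink file path or writable binary connection.
#' @return Number of bytes written (header + 3 x 6 x n samples).
#' @seealso [readESFBinary()]
#' @export
writeESFBinary <- function(rec, sink) {
  stopifnot(is(rec, "ESFRecording"))
  validObject(rec)
  s <- resolve_sink(sink, "wb")
  if (s$close) on.exit(close(s$con))
  header <- make_header("ESF1", rec@sampleRate, ncol(rec@samples), rec@meta)
  writeBin(header, s$con)
  n <- nrow(rec@samples)
  if (n > 0) {
    interleaved <- as.vector(t(rec@samples))  # frame-major: ch1..ch6, ...
    writeBin(pack_i24(interleaved), s$con)
  }
  HEADER_SIZE + 3L * ncol(rec@samples) * n
}

#' Read an ESF recording from the binary container
#'
#' Bit-exact inverse of [writeESFBinary()].
#'
#' @param source file path or readable binary connection.
#' @return An [ESFRecording-class].
#' @export
readESFBinary <- function(source) {
  s <- resolve_sink(source, "rb")
  if (s$close) on.exit(close(s$con))
  h <- readBin(s$con, "raw", HEADER_SIZE)
  if (length(h) < HEADER_SIZE)
    stop("format error: stream shorter than one header", call. = FALSE)
  hd <- parse_header(h, "ESF1")
  payload <- read_all(s$con)
  frame_bytes <- 3L * hd$nch
  if (length(payload) %% frame_bytes != 0L) {
    good <- (length(payload) %/% frame_bytes) * frame_bytes
    stop(sprintf(
      "corruption error: payload truncated mid-frame at byte offset %d",
      HEADER_SIZE + good), call. = FALSE)
  }
  samples <- matrix(unpack_i24(payload), ncol = hd$nch, byrow = TRUE)
  if (length(payload) == 0L) samples <- matrix(0, 0, hd$nch)
  esfRecording(samples, sampleRate = hd$rate,
               meta = hiveMetadata(hd$hive_id, hd$hardware_id,
                                   utcStart = hd$utc_start))
}

#' Write / read an activity trace in the binary container
#'
#' Payload: 2-channel interleaved little-endian float32 after the common
#' 64-byte header (magic `"ACT1"`).
#'
#' @param trace an [ActivityTrace-class].
#' @param sink,source file path or binary connection.
#' @return `writeActivityBinary` returns bytes written; `readActivityBinary`
#'   returns an [ActivityTrace-class].
#' @export
writeActivityBinary <- function(trace, sink) {
  stopifnot(is(trace, "ActivityTrace"))
  validObject(trace)
  s <- resolve_sink(sink, "wb")
  if (s$close) on.exit(close(s$con))
  writeBin(make_header("ACT1", trace@sampleRate, 2L, trace@meta), s$con)
  inter <- as.vector(t(trace@samples))
  if (length(inter))
    writeBin(inter, s$con, size = 4L, endian = "little")
  HEADER_SIZE + 4L * length(inter)
}

#' @rdname writeActivityBinary
#' @export
readActivityBinary <- function(source) {
  s <- resolve_sink(source, "rb")
  if (s$close) on.exit(close(s$con))
  h <- readBin(s$con, "raw", HEADER_SIZE)
  if (length(h) < HEADER_SIZE)
    stop("format error: stream shorter than one header", call. = FALSE)
  hd <- parse_header(h, "ACT1")
  payload <- read_all(s$con)
  frame_bytes <- 4L * hd$nch
  if (length(payload) %% frame_bytes != 0L)
    stop(sprintf(
      "corruption error: payload truncated mid-frame at byte offset %d",
      HEADER_SIZE + (length(payload) %/% frame_bytes) * frame_bytes),
      call. = FALSE)
  vals <- readBin(payload, "double", n = length(payload) %/% 4L, size = 4L,
                  endian = "little")
  samples <- matrix(vals, ncol = hd$nch, byrow = TRUE)
  if (!length(vals)) samples <- matrix(0, 0, hd$nch)
  activityTrace(samples, sampleRate = hd$rate,
                meta = hiveMetadata(hd$hive_id, hd$hardware_id,
                                    utcStart = hd$utc_start))
}

#' Write / read a telemetry series in the binary container
#'
#' Payload: per record, 8 little-endian float32 fields (temp_in, temp_out,
#' hum_in, hum_out, load1..load3, mcu_temp) after the common header (magic
#' `"TEL1"`; the header rate field carries the cadence in seconds).
#' Timestamps are reconstructed as `utc_start + index * cadence`, so the
#' series must be on a uniform integer-second cadence to be serialized.
#'
#' @param tel a [TelemetrySeries-class] on a uniform cadence.
#' @param sink,source file path or binary connection.
#' @return `writeTelemetryBinary` returns bytes written;
#'   `readTelemetryBinary` returns a [TelemetrySeries-class].
#' @export
writeTelemetryBinary <- function(tel, sink) {
  stopifnot(is(tel, "TelemetrySeries"))
  validObject(tel)
  n <- length(tel@timestamps)
  cadence <- if (n > 1) diff(tel@timestamps) else 120
  if (n > 1 && (length(unique(cadence)) != 1L ||
                cadence[1] != round(cadence[1])))
    stop("telemetry must be on a uniform integer-second cadence",
         call. = FALSE)
  cadence <- if (n > 1) cadence[1] else 120
  meta <- tel@meta
  meta@utcStart <- if (n > 0) tel@timestamps[1] else meta@utcStart
  s <- resolve_sink(sink, "wb")
  if (s$close) on.exit(close(s$con))
  writeBin(make_header("TEL1", cadence, 8L, meta), s$con)
  if (n > 0) {
    fields <- cbind(tel@tempIn, tel@tempOut, tel@humIn, tel@humOut,
                    tel@loadCells, tel@mcuTemp)
    writeBin(as.vector(t(fields)), s$con, size = 4L, endian = "little")
  }
  HEADER_SIZE + 32L * n
}

#' @rdname writeTelemetryBinary
#' @export
readTelemetryBinary <- function(source) {
  s <- resolve_sink(source, "rb")
  if (s$close) on.exit(close(s$con))
  h <- readBin(s$con, "raw", HEADER_SIZE)
  if (length(h) < HEADER_SIZE)
    stop("format error: stream shorter than one header", call. = FALSE)
  hd <- parse_header(h, "TEL1")
  payload <- read_all(s$con)
  if (length(payload) %% 32L != 0L)
    stop(sprintf(
      "corruption error: payload truncated mid-record at byte offset %d",
      HEADER_SIZE + (length(payload) %/% 32L) * 32L), call. = FALSE)
  vals <- readBin(payload, "double", n = length(payload) %/% 4L, size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 8L, byrow = TRUE)
  n <- nrow(m)
  telemetrySeries(
    timestamps = hd$utc_start + hd$rate * (seq_len(n) - 1),
    tempIn = m[, 1], tempOut = m[, 2], humIn = m[, 3], humOut = m[, 4],
    loadCells = m[, 5:7, drop = FALSE], mcuTemp = m[, 8],
    meta = hiveMetadata(hd$hive_id, hd$hardware_id,
                        utcStart = hd$utc_start))
}
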