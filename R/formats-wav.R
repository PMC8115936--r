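# WAV export of single ESF channels for manual inspection in audio
# software. Minimal RIFF/WAVE writer and reader (mono, 16-bit PCM) kept
# inside the formats module; the dialect is fixed, not configurable.

u16_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))

#' Export one ESF channel as a WAV file
#'
#' Writes mono 16-bit PCM at the recording's sample rate. The channel is
#' peak-normalized so that the largest absolute sample maps to 0.95 of full
#' scale; an all-zero channel maps to digital silence.
#'
#' @param rec an [ESFRecording-class].
#' @param channel channel number, 1-6.
#' @param sink file path or writable binary connection.
#' @return Number of audio frames written, invisibly.
#' @export
esfToWAV <- function(rec, channel, sink) {
  stopifnot(is(rec, "ESFRecording"))
  if (length(channel) != 1L || channel < 1 || channel > ncol(rec@samples))
    stop("index error: channel must be between 1 and 6", call. = FALSE)
  x <- rec@samples[, channel]
  peak <- if (length(x)) max(abs(x)) else 0
  pcm <- if (peak > 0) as.integer(round(x / peak * 0.95 * 32767))
         else integer(length(x))
  s <- resolve_sink(sink, "wb")
  if (s$close) on.exit(close(s$con))
  data_bytes <- 2L * length(pcm)
  rate <- as.integer(round(rec@sampleRate))
  con <- s$con
  writeBin(charToRaw("RIFF"), con)
  writeBin(u32_raw(36L + data_bytes), con)
  writeBin(charToRaw("WAVE"), con)
  writeBin(charToRaw("fmt "), con)
  writeBin(u32_raw(16L), con)
  writeBin(u16_raw(1L), con)          # PCM
  writeBin(u16_raw(1L), con)          # mono
  writeBin(u32_raw(rate), con)
  writeBin(u32_raw(rate * 2L), con)   # byte rate
  writeBin(u16_raw(2L), con)          # block align
  writeBin(u16_raw(16L), con)         # bits per sample
  writeBin(charToRaw("data"), con)
  writeBin(u32_raw(data_bytes), con)
  if (length(pcm))
    writeBin(pcm, con, size = 2L, endian = "little")
  invisible(length(pcm))
}

#' Read a mono 16-bit PCM WAV file
#'
#' Companion reader for [esfToWAV()] output (used mainly to verify
#' round trips); returns the samples on the normalized [-1, 1] scale.
#'
#' @param source file path or readable binary connection.
#' @return List with `samples` (numeric, full scale = 1) and `sampleRate`.
#' @export
readWAV <- function(source) {
  s <- resolve_sink(source, "rb")
  if (s$close) on.exit(close(s$con))
  con <- s$con
  hdr <- readBin(con, "raw", 12L)
  if (length(hdr) < 12L || rawToChar(hdr[1:4]) != "RIFF" ||
      rawToChar(hdr[9:12]) != "WAVE")
    stop("format error: not a RIFF/WAVE stream", call. = FALSE)
  rate <- NA_real_
  samples <- NULL
  repeat {
    chunk_hdr <- readBin(con, "raw", 8L)
    if (length(chunk_hdr) < 8L) break
    cid <- rawToChar(chunk_hdr[1:4])
    clen <- raw_u32(chunk_hdr[5:8])
    body <- readBin(con, "raw", clen + clen %% 2L)
    if (cid == "fmt ") {
      fmt <- raw_u32(c(body[1:2], as.raw(0), as.raw(0)))
      nch <- raw_u32(c(body[3:4], as.raw(0), as.raw(0)))
      bits <- raw_u32(c(body[15:16], as.raw(0), as.raw(0)))
      if (fmt != 1 || nch != 1 || bits != 16)
        stop("format error: only mono 16-bit PCM is supported",
             call. = FALSE)
      rate <- raw_u32(body[5:8])
    } else if (cid == "data") {
      samples <- readBin(body[seq_len(clen)], "integer",
                         n = clen %/% 2L, size = 2L, signed = TRUE,
                         endian = "little") / 32767
    }
  }
  if (is.na(rate) || is.null(samples))
    stop("format error: missing fmt or data chunk", call. = FALSE)
  list(samples = samples, sampleRate = rate)
}
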