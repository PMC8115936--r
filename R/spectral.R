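# Time-frequency primitives: Hann STFT, per-band power traces, zero-phase
# band-pass filtering, and the spectral regularity index used to accept
# fanning events.

#' Short-time Fourier spectrogram
#'
#' Magnitude-squared STFT with a periodic Hann window. Power is a one-sided
#' spectral density: summing `power * df * sum(w^2)` over all bins of one
#' frame recovers that frame's windowed energy exactly (Parseval), where
#' `df = sampleRate / windowLength`.
#'
#' @param x numeric signal.
#' @param sampleRate samples per second.
#' @param windowS analysis window length, seconds (window must hold at
#'   least 8 samples).
#' @param hopS hop between frame starts, seconds (`hopS <= windowS`).
#' @return A [Spectrogram-class]; a signal shorter than one window yields
#'   an empty (0-frame) spectrogram.
#' @export
stftSpectrogram <- function(x, sampleRate, windowS = 1.0, hopS = 0.25) {
  win <- as.integer(round(windowS * sampleRate))
  hop <- max(1L, as.integer(round(hopS * sampleRate)))
  if (win < 8L)
    stop("window too short: need at least 8 samples", call. = FALSE)
  if (hop > win)
    stop("hop must not exceed the window length", call. = FALSE)
  n <- length(x)
  nbins <- win %/% 2L + 1L
  freqs <- (seq_len(nbins) - 1) * sampleRate / win
  if (n < win) {
    return(new("Spectrogram", times = numeric(0), freqs = freqs,
               power = matrix(0, 0, nbins), windowS = win / sampleRate,
               hopS = hop / sampleRate, sampleRate = sampleRate))
  }
  starts <- seq(1L, n - win + 1L, by = hop)
  w <- hann(win)
  idx <- outer(seq_len(win) - 1L, starts, "+")
  frames <- matrix(x[idx], nrow = win) * w
  X <- stats::mvfft(frames)[seq_len(nbins), , drop = FALSE]
  scale <- 1 / (sampleRate * sum(w^2))
  p <- Mod(X)^2 * scale
  mult <- rep(2, nbins)
  mult[1] <- 1
  if (win %% 2L == 0L) mult[nbins] <- 1
  p <- p * mult
  times <- (starts - 1 + (win - 1) / 2) / sampleRate
  new("Spectrogram", times = times, freqs = freqs, power = t(p),
      windowS = win / sampleRate, hopS = hop / sampleRate,
      sampleRate = sampleRate)
}

#' Mean in-band power trace
#'
#' Per-frame mean of spectrogram power over the half-open band
#' `[fLo, fHi)`.
#'
#' @param spec a [Spectrogram-class].
#' @param band a [BandDef-class].
#' @return A [BandPowerTrace-class] on the spectrogram's frame grid.
#' @export
bandPower <- function(spec, band) {
  stopifnot(is(spec, "Spectrogram"), is(band, "BandDef"))
  sel <- spec@freqs >= band@fLo & spec@freqs < band@fHi
  if (!any(sel))
    stop(sprintf("configuration error: band %s [%g, %g) contains no bins",
                 band@name, band@fLo, band@fHi), call. = FALSE)
  p <- if (nrow(spec@power)) rowMeans(spec@power[, sel, drop = FALSE])
       else numeric(0)
  bandPowerTrace(spec@times, p, band, windowS = spec@windowS,
                 hopS = spec@hopS)
}

#' Zero-phase band-pass filter
#'
#' Spectral-mask filtering: the FFT of the signal is multiplied by a real
#' mask that is 1 inside `[fLo, fHi)` and rolls off with raised-cosine
#' transitions of width `transitionHz` outside, then inverted. The filter
#' is exactly zero-phase (cycle positions are not shifted), exactly
#' idempotent for in-band tones, and numerically stable at arbitrarily low
#' band edges, where recursive designs fail.
#'
#' @param x numeric signal.
#' @param sampleRate samples per second.
#' @param band a [BandDef-class] below the Nyquist frequency.
#' @param transitionHz transition width in Hz; default
#'   `max(1, 0.2 * fLo, 0.05 * (fHi - fLo))`.
#' @return Filtered signal, same length as `x`.
#' @export
bandpassFilter <- function(x, sampleRate, band, transitionHz = NULL) {
  stopifnot(is(band, "BandDef"))
  if (band@fHi > sampleRate / 2)
    stop("configuration error: band extends beyond the Nyquist frequency",
         call. = FALSE)
  n0 <- length(x)
  if (n0 == 0L) return(numeric(0))
  if (is.null(transitionHz))
    transitionHz <- max(1, 0.2 * band@fLo, 0.05 * (band@fHi - band@fLo))
  # zero-pad to a 2-3-5-smooth length: R's mixed-radix FFT degrades badly
  # on lengths with large prime factors
  n <- stats::nextn(n0, c(2, 3, 5))
  x <- c(x, numeric(n - n0))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * sampleRate / n  # two-sided frequency axis
  mask <- numeric(n)
  lo0 <- max(band@fLo - transitionHz, 0)
  hi1 <- band@fHi + transitionHz
  inside <- f >= band@fLo & f < band@fHi
  mask[inside] <- 1
  rising <- f >= lo0 & f < band@fLo
  mask[rising] <- 0.5 - 0.5 * cos(pi * (f[rising] - lo0) /
                                  (band@fLo - lo0))
  falling <- f >= band@fHi & f < hi1
  mask[falling] <- 0.5 + 0.5 * cos(pi * (f[falling] - band@fHi) /
                                   transitionHz)
  if (band@fLo > 0) mask[1] <- 0  # never pass DC for a true band-pass
  Re(fft(fft(x) * mask, inverse = TRUE))[seq_len(n0)] / n
}

#' Spectral regularity index
#'
#' Concentration of in-band spectral power at the dominant peak, used to
#' quantify how "highly regular" a putative fanning segment is: the
#' Hann-windowed periodogram of the band-passed segment is computed, and
#' the power of the dominant spectral line -- the strongest in-band bin
#' plus its neighbourhood within `peakHalfWidthHz` (and never less than
#' the Hann main lobe of two bins) -- is divided by the total in-band
#' power. A jitter-free sinusoid scores near 1; slow drift or mild
#' cycle-period jitter keeps the line within the `peakHalfWidthHz`
#' tolerance; in-band white noise spreads power over the whole band and
#' scores near 0.
#'
#' @param x signal segment covering at least 20 cycles of the band's lower
#'   edge.
#' @param sampleRate samples per second.
#' @param band a [BandDef-class].
#' @param peakHalfWidthHz half-width of the dominant line, Hz (default 2).
#' @return Scalar in `[0, 1]`.
#' @export
regularityIndex <- function(x, sampleRate, band, peakHalfWidthHz = 2) {
  stopifnot(is(band, "BandDef"))
  n <- length(x)
  if (n / sampleRate * band@fLo < 20)
    stop("undefined result: segment shorter than 20 cycles of the band's ",
         "lower edge", call. = FALSE)
  y <- bandpassFilter(x, sampleRate, band)
  w <- hann(n)
  n2 <- stats::nextn(n, c(2, 3, 5))  # pad: keep the FFT fast for any span
  X <- Mod(fft(c(w * y, numeric(n2 - n)))[seq_len(n2 %/% 2 + 1)])^2
  freqs <- (seq_along(X) - 1) * sampleRate / n2
  sel <- which(freqs >= band@fLo & freqs < band@fHi)
  if (!length(sel) || sum(X[sel]) <= 0) return(0)
  pk <- sel[which.max(X[sel])]
  halfw <- max(2, round(peakHalfWidthHz * n2 / sampleRate))
  lobe <- intersect(sel, (pk - halfw):(pk + halfw))
  min(1, sum(X[lobe]) / sum(X[sel]))
}
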