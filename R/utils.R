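# Internal helpers shared across modules.

#' @importFrom stats fft median mad rnorm runif runmed sd
#' @import methods
NULL

# Evaluate `expr` under a temporary RNG state when `seed` is given; the
# caller's RNG stream is restored afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_wholenumber <- function(x, tol = 1e-6) {
  all(abs(x - round(x)) < tol)
}

# Odd window size for runmed, clamped to the series length.
odd_window <- function(k, n) {
  k <- max(1L, as.integer(round(k)))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > n) k <- if (n %% 2L == 1L) n else n - 1L
  max(1L, k)
}

# Hann window, periodic form (matches FFT bin spacing).
hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

# Format Unix seconds as ISO-8601 UTC with optional fractional digits.
iso8601 <- function(secs, digits = 0) {
  t <- as.POSIXct(secs, origin = "1970-01-01", tz = "UTC")
  if (digits > 0) {
    format(t, paste0("%Y-%m-%dT%H:%M:%OS", digits), tz = "UTC")
  } else {
    format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
}

parse_utc <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
  as.numeric(out)
}

# Overlap length of two closed intervals.
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}
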