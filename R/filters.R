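# Zero-phase filtering and analytic-signal utilities shared by the EMG and
# EEG preprocessing stages.

#' Zero-phase Butterworth bandpass
#'
#' Band limits are realized as a cascade of a 4th-order low-pass and a
#' 4th-order high-pass Butterworth section, each applied forward-backward
#' (`signal::filtfilt`), giving zero phase distortion and a stable
#' realization even for edges close to Nyquist.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param low,high band edges in Hz; `low = 0` drops the high-pass section.
#' @param order Butterworth order of each section.
#' @return filtered vector, same length as `x`.
#' @export
bandpass_zerophase <- function(x, rate, low, high, order = 4) {
  ny <- rate / 2
  if (high >= ny) {
    stop(sprintf("Nyquist error: upper band edge %g Hz requires rate > %g Hz",
                 high, 2 * high))
  }
  if (low < 0 || low >= high) stop("parameter error: need 0 <= low < high")
  y <- signal::filtfilt(signal::butter(order, high / ny, type = "low"), x)
  if (low > 0) {
    y <- signal::filtfilt(signal::butter(order, low / ny, type = "high"), y)
  }
  y
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns `x + i * H(x)`: the FFT of `x` with negative frequencies zeroed
#' and positive frequencies doubled.  `Mod()` of the result is the amplitude
#' envelope.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic_signal needs at least 2 samples")
  # zero-pad to a highly composite length: mixed-radix FFTs degrade to
  # O(n^2) on prime lengths
  N <- stats::nextn(n, c(2L, 3L, 5L))
  xp <- if (N > n) c(x, numeric(N - n)) else x
  h <- numeric(N)
  if (N %% 2L == 0L) {
    h[1] <- 1; h[N / 2 + 1] <- 1; h[2:(N / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((N + 1) / 2)] <- 2
  }
  a <- stats::fft(stats::fft(xp) * h, inverse = TRUE) / N
  a[seq_len(n)]
}

# centered moving average; edges use partial windows
moving_average <- function(x, n) {
  if (n <= 1L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_along(x) - floor(n / 2), 1L)
  hi <- pmin(seq_along(x) + ceiling(n / 2) - 1L, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# z-score a vector; errors on zero variance
zscore <- function(x, label = "signal") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("z-score error: zero variance in ", label)
  }
  (x - mean(x)) / s
}

# white Gaussian noise band-limited to [low, high] Hz, unit variance
bandlimited_noise <- function(n, rate, low, high) {
  x <- bandpass_zerophase(stats::rnorm(n), rate, low, min(high, rate / 2 * 0.98))
  x / stats::sd(x)
}
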