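# Internal signal-processing and misc helpers.

#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  # keep derived seeds well inside 32-bit integer range
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629L)
}

#' Zero-phase Butterworth band-pass filter
#'
#' `signal::filtfilt` applied forward and backward so the pass band keeps
#' zero phase shift; band edges in Hz.
#' @keywords internal
#' @noRd
bandpass <- function(x, fs, low, high, order = 3) {
  nyq <- fs / 2
  if (low <= 0 || high >= nyq) {
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz); got [",
         low, ", ", high, "]", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Amplitude envelope via the analytic signal
#'
#' FFT-based Hilbert transform; for an amplitude-modulated tone a(t)*cos(w t)
#' the result approximates a(t), so burst centers land on envelope maxima.
#' @keywords internal
#' @noRd
envelope_hilbert <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Moving average with centered window (odd length enforced)
#' @keywords internal
#' @noRd
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2)) -> y
  # fill edge NAs with nearest computed value
  idx <- which(!is.na(y))
  if (length(idx) == 0L) return(rep(mean(x), length(x)))
  y[seq_len(idx[1] - 1)] <- y[idx[1]]
  y[seq((idx[length(idx)] + 1), length.out = length(x) - idx[length(idx)])] <- y[idx[length(idx)]]
  y
}

#' Local maxima above a threshold with a refractory distance
#' @keywords internal
#' @noRd
find_peaks <- function(x, min_height = -Inf, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (length(cand) <= 1L || min_distance <= 1L) return(cand)
  # greedy keep-highest within refractory distance
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  taken <- logical(n)
  for (p in ord) {
    lo <- max(1L, p - min_distance); hi <- min(n, p + min_distance)
    if (!any(taken[lo:hi])) {
      keep[p] <- TRUE
      taken[lo:hi] <- TRUE
    }
  }
  sort(which(keep))
}

#' Quadratically interpolated argmax of a sampled curve
#'
#' Returns fractional index of the parabola through (i-1, i, i+1).
#' @keywords internal
#' @noRd
refine_peak <- function(x, i) {
  if (i <= 1L || i >= length(x)) return(as.numeric(i))
  a <- x[i - 1]; b <- x[i]; c <- x[i + 1]
  den <- a - 2 * b + c
  if (den == 0) return(as.numeric(i))
  i + 0.5 * (a - c) / den
}

#' Round to the nearest multiple of `grid` (ties to even, like base round)
#' @keywords internal
#' @noRd
round_to_grid <- function(x, grid = 2) grid * round(x / grid)

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
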