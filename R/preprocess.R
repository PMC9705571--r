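#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-4 Butterworth band-pass (default 25-400 Hz, the dominant
#' heart-sound band) forward and backward, so the effective magnitude response
#' is squared and the phase response is zero -- S1/S2 timing is preserved for
#' segmentation. Signal length is preserved.
#'
#' @param rec A [pcg_recording()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < rate/2`.
#' @param order Butterworth order (each pass).
#' @return The filtered `pcg_recording`.
#' @export
bandpass_filter <- function(rec, low_hz = 25, high_hz = 400, order = 4) {
  stopifnot(inherits(rec, "pcg_recording"))
  nyq <- rec$rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("cutoffs must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  rec$samples <- as.numeric(signal::filtfilt(bf, rec$samples))
  rec
}

#' RMS loudness normalization to a dBFS target
#'
#' Scales the signal so its root-mean-square amplitude equals
#' `10^(target_dbfs/20)` of full scale (reference 1.0 for float audio). The
#' default of -20 dBFS gives RMS 0.1.
#'
#' @param rec A [pcg_recording()].
#' @param target_dbfs Target RMS level in dBFS.
#' @return The normalized `pcg_recording`.
#' @export
rms_normalize <- function(rec, target_dbfs = -20) {
  stopifnot(inherits(rec, "pcg_recording"))
  rms <- sqrt(mean(rec$samples^2))
  if (rms == 0) stop("degenerate recording: all-zero signal cannot be normalized")
  rec$samples <- rec$samples * 10^(target_dbfs / 20) / rms
  rec
}

#' 85% spectral roll-off frequency
#'
#' The smallest frequency below which at least 85% of the total spectral
#' energy lies; a diagnostic used to characterize acquisition devices.
#'
#' @param rec A [pcg_recording()] (or a numeric vector with `rate` given).
#' @param rate Sampling rate, required when `rec` is a bare vector.
#' @param fraction Energy fraction (default 0.85).
#' @return Roll-off frequency in Hz.
#' @export
spectral_rolloff_85 <- function(rec, rate = NULL, fraction = 0.85) {
  if (inherits(rec, "pcg_recording")) {
    x <- rec$samples; rate <- rec$rate
  } else {
    x <- as.numeric(rec)
    if (is.null(rate)) stop("rate must be given for a bare vector")
  }
  if (length(x) == 0 || all(x == 0)) stop("all-zero or empty signal")
  n <- length(x)
  spec <- Mod(stats::fft(x))^2
  half <- spec[seq_len(floor(n / 2) + 1)]
  freqs <- (seq_along(half) - 1) * rate / n
  cum <- cumsum(half) / sum(half)
  freqs[which(cum >= fraction)[1]]
}
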