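# Envelope computation for heart-sound segmentation: four per-frame features
# in the style of the Schmidt/Springer segmentation family — homomorphic
# envelope, analytic-signal (Hilbert) magnitude, undecimated wavelet-detail
# energy, and 40-60 Hz band power — sampled at `feature_rate` and z-normalized
# per recording.

hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Smooth amplitude envelope: low-pass the log analytic magnitude, exponentiate.
homomorphic_envelope <- function(x, rate, lp_hz = 8) {
  am <- Mod(hilbert_analytic(x))
  bf <- signal::butter(1, lp_hz / (rate / 2), type = "low")
  exp(as.numeric(signal::filtfilt(bf, log(am + 1e-10))))
}

frame_means <- function(x, hop, nf) {
  colMeans(matrix(x[seq_len(nf * hop)], nrow = hop))
}

#' Per-frame envelope features for HSMM segmentation
#'
#' @param rec A filtered, normalized [pcg_recording()].
#' @param feature_rate Frame rate in Hz (default 50).
#' @return A `nf x 4` matrix (homomorphic, Hilbert, wavelet, 40-60 Hz power),
#'   each column z-normalized over the recording. The raw (per-sample)
#'   homomorphic envelope is attached as `attr(, "homomorphic")` and the frame
#'   hop in samples as `attr(, "hop")`.
#' @export
envelope_features <- function(rec, feature_rate = 50) {
  stopifnot(inherits(rec, "pcg_recording"))
  x <- rec$samples; rate <- rec$rate
  hop <- round(rate / feature_rate)
  nf <- length(x) %/% hop
  if (nf < 1) stop("recording shorter than one frame")
  if (all(x == 0)) stop("all-zero signal: envelope z-normalization undefined")
  hom <- homomorphic_envelope(x, rate)
  hil <- Mod(hilbert_analytic(x))
  wav <- abs(swt_detail_db4(x, level = 5)) # ~62-125 Hz detail band at 4 kHz
  bp <- signal::butter(2, c(40, 60) / (rate / 2), type = "pass")
  bnd <- as.numeric(signal::filtfilt(bp, x))^2
  E <- cbind(frame_means(hom, hop, nf), frame_means(hil, hop, nf),
             frame_means(wav, hop, nf), frame_means(bnd, hop, nf))
  colnames(E) <- c("homomorphic", "hilbert", "wavelet", "band40_60")
  for (j in seq_len(ncol(E))) {
    s <- stats::sd(E[, j])
    if (!is.finite(s) || s == 0) stop("degenerate envelope: zero variance")
    E[, j] <- (E[, j] - mean(E[, j])) / s
  }
  structure(E, homomorphic = hom, hop = hop, feature_rate = feature_rate)
}

#' Heart-rate and systolic-interval estimate from the envelope autocorrelation
#'
#' The beat period is the dominant autocorrelation lag of the homomorphic
#' envelope within 30-200 beats/min; the systolic interval (S1 onset to S2
#' onset) is the first prominent autocorrelation peak between 0.2 s and half
#' the beat period.
#'
#' @param env An [envelope_features()] matrix (its first column is used), or
#'   any numeric per-frame envelope.
#' @param feature_rate Frame rate in Hz.
#' @param min_peak Minimum normalized autocorrelation at the beat lag below
#'   which the estimate is rejected as unreliable.
#' @return List with `bpm` and `systole_duration_s`.
#' @export
estimate_heart_rate <- function(env, feature_rate = 50, min_peak = 0.3) {
  e <- if (is.matrix(env)) env[, 1] else as.numeric(env)
  nf <- length(e)
  if (nf < 3 * feature_rate) stop("need at least 3 s of envelope frames")
  ac <- stats::acf(e, lag.max = nf - 1, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lag_lo <- max(2L, floor(60 / 200 * feature_rate))
  lag_hi <- min(nf - 1L, ceiling(60 / 30 * feature_rate))
  lags <- lag_lo:lag_hi
  vals <- ac[lags + 1L]
  # restrict to local maxima so harmonics of short lags do not alias
  locmax <- vals >= c(vals[1], vals[-length(vals)]) &
    vals >= c(vals[-1], vals[length(vals)])
  if (!any(locmax & vals >= min_peak))
    stop("no reliable beat periodicity in the envelope autocorrelation")
  cand <- lags[locmax]
  beat_lag <- cand[which.max(ac[cand + 1L])]
  bpm <- 60 * feature_rate / beat_lag
  sys_lo <- max(2L, round(0.2 * feature_rate))
  sys_hi <- max(sys_lo + 1L, floor(beat_lag / 2))
  sl <- sys_lo:sys_hi
  sv <- ac[sl + 1L]
  sm <- sv >= c(sv[1], sv[-length(sv)]) & sv >= c(sv[-1], sv[length(sv)])
  sys_lag <- if (any(sm)) sl[sm][which.max(sv[sm])] else sl[which.max(sv)]
  list(bpm = bpm, systole_duration_s = sys_lag / feature_rate)
}
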