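#' Spectral analysis configuration
#'
#' Fixes the short-time transform and band layout used by all frequency-domain
#' features: a 64 ms Hann window with 16 ms stride, twelve power-spectral-
#' density bands spanning 25-400 Hz, four spectral-contrast octave-like bands,
#' 85% roll-off, 13 mel-frequency cepstral coefficients, and a 4-level
#' Daubechies-4 wavelet decomposition.
#'
#' @param fft_window_ms,fft_stride_ms Hann window length and stride in ms.
#' @param psd_band_edges Increasing vector of PSD band edges in Hz.
#' @param contrast_band_edges Increasing vector of spectral-contrast band
#'   edges in Hz (bands are labelled 2-5).
#' @param rolloff_fraction Spectral roll-off energy fraction.
#' @param n_mfcc Number of MFCCs kept.
#' @param n_mels Number of mel filters.
#' @param mel_fmax Upper mel-bank edge in Hz (`NULL` = Nyquist).
#' @param sampen_m,sampen_r Sample-entropy embedding dimension and tolerance
#'   factor (tolerance = `sampen_r` times the interval SD).
#' @param dwt_levels Wavelet decomposition depth.
#' @return A list of class `pcg_spectral_config`.
#' @export
spectral_config <- function(fft_window_ms = 64, fft_stride_ms = 16,
                            psd_band_edges = c(25, 40, 60, 80, 100, 120, 140,
                                               160, 180, 200, 250, 300, 400),
                            contrast_band_edges = c(25, 50, 100, 200, 400),
                            rolloff_fraction = 0.85, n_mfcc = 13, n_mels = 26,
                            mel_fmax = NULL, sampen_m = 2, sampen_r = 0.2,
                            dwt_levels = 4) {
  stopifnot(all(diff(psd_band_edges) > 0), all(diff(contrast_band_edges) > 0))
  structure(list(fft_window_ms = fft_window_ms, fft_stride_ms = fft_stride_ms,
                 psd_band_edges = psd_band_edges,
                 contrast_band_edges = contrast_band_edges,
                 rolloff_fraction = rolloff_fraction, n_mfcc = n_mfcc,
                 n_mels = n_mels, mel_fmax = mel_fmax, sampen_m = sampen_m,
                 sampen_r = sampen_r, dwt_levels = dwt_levels),
            class = "pcg_spectral_config")
}

# Hann-windowed short-time power spectrum. Intervals shorter than one window
# are zero-padded to a single window. Returns bin frequencies and the
# bins x frames power matrix.
stft_power <- function(x, rate, window_ms = 64, stride_ms = 16) {
  wl <- round(window_ms * rate / 1000)
  hop <- round(stride_ms * rate / 1000)
  if (length(x) < wl) x <- c(x, numeric(wl - length(x)))
  starts <- seq(1, length(x) - wl + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, wl - 1) / (wl - 1)) # Hann
  nb <- wl %/% 2 + 1
  P <- matrix(0, nb, length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + wl - 1)] * w
    P[, i] <- Mod(stats::fft(seg))[seq_len(nb)]^2
  }
  list(freq = (seq_len(nb) - 1) * rate / wl, power = P)
}

# Mel filter bank (triangular, mel-spaced) over the STFT bin frequencies.
mel_filterbank <- function(freqs, n_mels, fmin = 0, fmax) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- mel2hz(seq(hz2mel(fmin), hz2mel(fmax), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ctr <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II of each column.
dct2_ortho <- function(X) {
  N <- nrow(X)
  jj <- seq_len(N) - 1
  basis <- sqrt(2 / N) * cos(pi * outer(jj, 2 * jj + 1) / (2 * N))
  basis[1, ] <- basis[1, ] / sqrt(2)
  basis %*% X
}

# First n_mfcc mel-frequency cepstral coefficients, averaged over frames.
# mfcc1 is the log-energy-bearing 0th DCT coefficient, so a pure gain change
# moves mfcc1 only.
mfcc_from_stft <- function(st, config, rate) {
  fmax <- if (is.null(config$mel_fmax)) rate / 2 else config$mel_fmax
  fb <- mel_filterbank(st$freq, config$n_mels, 0, fmax)
  melp <- fb %*% st$power
  cep <- dct2_ortho(log(melp + 1e-30))
  rowMeans(cep[seq_len(config$n_mfcc), , drop = FALSE])
}
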