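# The 177-feature per-segment catalogue and the cyclic windowed aggregation.
#
# Feature names follow the field's conventions: states are abbreviated S1,
# Sys, S2, Dia; RR denotes the whole cycle; the eight duration/amplitude
# ratios are S1/RR, Sys/RR, S2/RR, Dia/RR, S1/S2, Sys/Dia, Sys/S1, Dia/S2.

STATE_ABBR <- c(S1 = "S1", systole = "Sys", S2 = "S2", diastole = "Dia")
RATIO_PAIRS <- list(
  S1RR = c("S1", "RR"), SysRR = c("systole", "RR"), S2RR = c("S2", "RR"),
  DiaRR = c("diastole", "RR"), S1S2 = c("S1", "S2"),
  SysDia = c("systole", "diastole"), SysS1 = c("systole", "S1"),
  DiaS2 = c("diastole", "S2"))

psd_band_names <- function(config) {
  e <- config$psd_band_edges
  paste0(e[-length(e)], "_", e[-1], "Hz")
}

#' Canonical names of the 177 per-segment features
#'
#' @param config A [spectral_config()].
#' @return Character vector of length 177 in canonical order.
#' @export
pcg_feature_names <- function(config = spectral_config()) {
  st <- unname(STATE_ABBR)
  rt <- names(RATIO_PAIRS)
  bands <- psd_band_names(config)
  c("BPM",
    paste0("Dur_", st),
    paste0("Dur_Ratio_", rt),
    paste0("MeanEnv_Ratio_", rt),
    paste0("RMS_", st),
    paste0("RMS_Ratio_", rt),
    paste0("ZC_", st),
    paste0("SE_", st),
    paste0("Skewness_", st),
    paste0("Kurtosis_", st),
    paste0("PSD_Sys_", bands), paste0("PSD_Dia_", bands),
    unlist(lapply(st, function(s) paste0("mfcc", seq_len(config$n_mfcc), "_", s))),
    paste0("SpecCentroid_", st),
    paste0("SpecBandwidth_", st),
    unlist(lapply(st, function(s) paste0("SpecContrast", 2:5, "_", s))),
    paste0("SpecFlatness_", st),
    paste0("SpecRolloff_", st),
    paste0("PolyFeatures_", st),
    unlist(lapply(st, function(s) paste0("dwt", seq_len(config$dwt_levels), "_", s))))
}

state_durations_s <- function(segment, rate) {
  d <- vapply(PCG_STATES, function(s) diff(segment$intervals[[s]]), numeric(1))
  c(d, RR = (segment$rr_end - segment$rr_start)) / rate
}

#' Duration features of one cardiac segment
#'
#' BPM (60 / RR seconds), the four state durations in milliseconds, and the
#' eight duration ratios.
#'
#' @param segment A `pcg_segment`.
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector of 13 values.
#' @export
duration_features <- function(segment, rate) {
  d <- state_durations_s(segment, rate)
  if (any(d[PCG_STATES] <= 0)) stop("zero-length state interval")
  ratios <- vapply(RATIO_PAIRS, function(p) d[[p[1]]] / d[[p[2]]], numeric(1))
  out <- c(60 / d[["RR"]], d[PCG_STATES] * 1000, ratios)
  names(out) <- c("BPM", paste0("Dur_", STATE_ABBR),
                  paste0("Dur_Ratio_", names(RATIO_PAIRS)))
  out
}

safe_ratio <- function(num, den) if (!is.finite(den) || den == 0) NA_real_ else num / den

#' Amplitude features of one cardiac segment
#'
#' Mean-envelope ratios (homomorphic envelope), per-state RMS, RMS ratios, and
#' zero-crossing counts. Ratios with a zero denominator are set to `NA` (the
#' segment is then flagged and dropped before modelling).
#'
#' @param segment A `pcg_segment`.
#' @param signal Recording sample vector.
#' @param envelope Per-sample homomorphic envelope.
#' @return Named numeric vector of 24 values.
#' @export
amplitude_features <- function(segment, signal, envelope) {
  rr_idx <- (segment$rr_start + 1):segment$rr_end
  pieces <- lapply(PCG_STATES, function(s) slice_state(signal, segment$intervals[[s]]))
  names(pieces) <- PCG_STATES
  env_pieces <- lapply(PCG_STATES, function(s) slice_state(envelope, segment$intervals[[s]]))
  names(env_pieces) <- PCG_STATES
  rms <- c(vapply(pieces, function(x) sqrt(mean(x^2)), numeric(1)),
           RR = sqrt(mean(signal[rr_idx]^2)))
  menv <- c(vapply(env_pieces, mean, numeric(1)), RR = mean(envelope[rr_idx]))
  zc <- vapply(pieces, function(x) {
    n <- length(x); if (n < 2) return(NA_real_)
    sum(x[-1] * x[-n] < 0)
  }, numeric(1))
  rms_r <- vapply(RATIO_PAIRS, function(p) safe_ratio(rms[[p[1]]], rms[[p[2]]]),
                  numeric(1))
  env_r <- vapply(RATIO_PAIRS, function(p) safe_ratio(menv[[p[1]]], menv[[p[2]]]),
                  numeric(1))
  out <- c(env_r, rms[PCG_STATES], rms_r, zc)
  names(out) <- c(paste0("MeanEnv_Ratio_", names(RATIO_PAIRS)),
                  paste0("RMS_", STATE_ABBR),
                  paste0("RMS_Ratio_", names(RATIO_PAIRS)),
                  paste0("ZC_", STATE_ABBR))
  out
}

#' Statistical features of one cardiac segment
#'
#' Sample entropy (embedding `m`, tolerance `r` times the interval SD),
#' skewness, and excess kurtosis per state.
#'
#' @inheritParams amplitude_features
#' @param config A [spectral_config()] (sample-entropy parameters).
#' @return Named numeric vector of 12 values.
#' @export
statistical_features <- function(segment, signal, config = spectral_config()) {
  vals <- lapply(PCG_STATES, function(s) {
    x <- slice_state(signal, segment$intervals[[s]])
    n <- length(x)
    if (n < config$sampen_m + 2) return(c(SE = NA_real_, Sk = NA_real_, Ku = NA_real_))
    se <- sampen_cpp(x, config$sampen_m, config$sampen_r * stats::sd(x))
    m <- mean(x); m2 <- mean((x - m)^2)
    if (m2 == 0) {
      sk <- NA_real_; ku <- NA_real_
    } else {
      sk <- mean((x - m)^3) / m2^1.5
      ku <- mean((x - m)^4) / m2^2 - 3
    }
    c(SE = se, Sk = sk, Ku = ku)
  })
  out <- c(vapply(vals, `[[`, numeric(1), "SE"),
           vapply(vals, `[[`, numeric(1), "Sk"),
           vapply(vals, `[[`, numeric(1), "Ku"))
  names(out) <- c(paste0("SE_", STATE_ABBR), paste0("Skewness_", STATE_ABBR),
                  paste0("Kurtosis_", STATE_ABBR))
  out
}

band_bins <- function(freq, lo, hi, inclusive_hi = FALSE) {
  if (inclusive_hi) which(freq >= lo & freq <= hi) else which(freq >= lo & freq < hi)
}

#' Power-spectral-density band features
#'
#' Mean (over Hann-windowed short-time frames) band-summed spectral power in
#' the twelve configured bands, for the systolic and diastolic intervals.
#'
#' @inheritParams statistical_features
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector of 24 values.
#' @export
psd_band_features <- function(segment, signal, config = spectral_config(),
                              rate = 4000) {
  e <- config$psd_band_edges
  nb <- length(e) - 1
  out <- numeric(0)
  for (region in c("systole", "diastole")) {
    x <- slice_state(signal, segment$intervals[[region]])
    st <- stft_power(x, rate, config$fft_window_ms, config$fft_stride_ms)
    vals <- vapply(seq_len(nb), function(k) {
      bins <- band_bins(st$freq, e[k], e[k + 1], inclusive_hi = (k == nb))
      mean(colSums(st$power[bins, , drop = FALSE]))
    }, numeric(1))
    names(vals) <- paste0("PSD_", STATE_ABBR[region], "_", psd_band_names(config))
    out <- c(out, vals)
  }
  out
}

#' Mel-frequency cepstral coefficients per state
#'
#' First `n_mfcc` MFCCs of each state interval, frame-averaged. `mfcc1` is the
#' log-energy-bearing 0th cepstral coefficient.
#'
#' @inheritParams psd_band_features
#' @return Named numeric vector of `4 * n_mfcc` values.
#' @export
mfcc_features <- function(segment, signal, config = spectral_config(),
                          rate = 4000) {
  out <- numeric(0)
  for (s in PCG_STATES) {
    x <- slice_state(signal, segment$intervals[[s]])
    if (length(x) == 0) {
      v <- rep(NA_real_, config$n_mfcc)
    } else {
      st <- stft_power(x, rate, config$fft_window_ms, config$fft_stride_ms)
      v <- mfcc_from_stft(st, config, rate)
    }
    names(v) <- paste0("mfcc", seq_len(config$n_mfcc), "_", STATE_ABBR[s])
    out <- c(out, v)
  }
  out
}

spectral_shape_one <- function(x, config, rate) {
  st <- stft_power(x, rate, config$fft_window_ms, config$fft_stride_ms)
  S <- rowMeans(st$power)
  f <- st$freq
  tot <- sum(S)
  if (!is.finite(tot) || tot == 0) {
    return(c(centroid = NA_real_, bandwidth = NA_real_,
             contrast = rep(NA_real_, 4), flatness = NA_real_,
             rolloff = NA_real_, poly = NA_real_))
  }
  centroid <- sum(f * S) / tot
  bandwidth <- sqrt(sum((f - centroid)^2 * S) / tot)
  eps <- 1e-12
  e <- config$contrast_band_edges
  contrast <- vapply(seq_len(length(e) - 1), function(k) {
    bins <- band_bins(f, e[k], e[k + 1], inclusive_hi = (k == length(e) - 1))
    Pb <- st$power[bins, , drop = FALSE]
    mean(log(apply(Pb, 2, max) + eps) - log(apply(Pb, 2, min) + eps))
  }, numeric(1))
  flatness <- exp(mean(log(S + eps))) / (mean(S) + eps)
  rolloff <- f[which(cumsum(S) / tot >= config$rolloff_fraction)[1]]
  poly <- sum((f - mean(f)) * (S - mean(S))) / sum((f - mean(f))^2)
  c(centroid = centroid, bandwidth = bandwidth, contrast = contrast,
    flatness = flatness, rolloff = rolloff, poly = poly)
}

#' Spectral shape features per state
#'
#' Spectral centroid (power-weighted mean frequency), second-order bandwidth,
#' spectral contrast in four bands (log peak-to-valley per frame), flatness
#' (geometric/arithmetic mean ratio), 85% roll-off, and the slope of a
#' degree-1 fit to the mean spectrum.
#'
#' @inheritParams psd_band_features
#' @return Named numeric vector of 36 values.
#' @export
spectral_shape_features <- function(segment, signal, config = spectral_config(),
                                    rate = 4000) {
  res <- lapply(PCG_STATES, function(s)
    spectral_shape_one(slice_state(signal, segment$intervals[[s]]), config, rate))
  st <- unname(STATE_ABBR)
  grab <- function(key) {
    v <- vapply(res, function(r) r[[key]], numeric(1))
    names(v) <- paste0(switch(key, centroid = "SpecCentroid",
                              flatness = "SpecFlatness", rolloff = "SpecRolloff",
                              bandwidth = "SpecBandwidth", poly = "PolyFeatures"),
                       "_", st)
    v
  }
  contrast <- unlist(lapply(seq_along(res), function(i) {
    v <- res[[i]][paste0("contrast", 1:4)]
    names(v) <- paste0("SpecContrast", 2:5, "_", st[i])
    v
  }))
  c(grab("centroid"), grab("bandwidth"), contrast, grab("flatness"),
    grab("rolloff"), grab("poly"))
}

#' Discrete-wavelet features per state
#'
#' Log energy of each detail level of a 4-level Daubechies-4 decomposition of
#' the state interval.
#'
#' @inheritParams psd_band_features
#' @return Named numeric vector of 16 values.
#' @export
dwt_features <- function(segment, signal, config = spectral_config()) {
  out <- numeric(0)
  for (s in PCG_STATES) {
    x <- slice_state(signal, segment$intervals[[s]])
    if (length(x) < 16) {
      v <- rep(NA_real_, config$dwt_levels)
    } else {
      dec <- dwt_db4(x, config$dwt_levels)
      v <- vapply(dec$details, function(d) log(sum(d^2) + 1e-12), numeric(1))
    }
    names(v) <- paste0("dwt", seq_len(config$dwt_levels), "_", STATE_ABBR[s])
    out <- c(out, v)
  }
  out
}

#' Extract the full 177-feature vector of one cardiac segment
#'
#' Concatenates the duration, amplitude, statistical, PSD-band, MFCC, spectral
#' shape, and wavelet feature groups in canonical order. Segments for which
#' any feature is non-finite carry `attr(, "flagged") = TRUE` and are dropped
#' before modelling.
#'
#' @inheritParams amplitude_features
#' @param config A [spectral_config()].
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector of length 177.
#' @export
extract_segment_features <- function(segment, signal, envelope,
                                     config = spectral_config(), rate = 4000) {
  v <- c(duration_features(segment, rate),
         amplitude_features(segment, signal, envelope),
         statistical_features(segment, signal, config),
         psd_band_features(segment, signal, config, rate),
         mfcc_features(segment, signal, config, rate),
         spectral_shape_features(segment, signal, config, rate),
         dwt_features(segment, signal, config))
  canon <- pcg_feature_names(config)
  v <- v[canon]
  names(v) <- canon
  stopifnot(length(v) == length(canon))
  attr(v, "flagged") <- any(!is.finite(v))
  v
}

#' Cyclic sliding-window aggregation of per-segment features
#'
#' For each segment position, the mean (`m_`) and standard deviation (`sd_`)
#' of every feature over a window of `window` consecutive segments, wrapped
#' cyclically so each segment participates in exactly `min(n, window)`
#' windows. Smooths out per-cycle outliers.
#'
#' @param X Numeric matrix or data.frame, one row per segment (in order), one
#'   column per feature.
#' @param window Window length (default 6).
#' @return Matrix with the same number of rows and `2 * ncol(X)` columns named
#'   `m_<feature>` and `sd_<feature>`.
#' @export
cyclic_window_aggregate <- function(X, window = 6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1) stop("empty feature list")
  w <- min(window, n)
  M <- matrix(NA_real_, n, ncol(X))
  S <- matrix(NA_real_, n, ncol(X))
  for (i in seq_len(n)) {
    idx <- ((i - 1 + 0:(w - 1)) %% n) + 1
    W <- X[idx, , drop = FALSE]
    M[i, ] <- colMeans(W)
    S[i, ] <- apply(W, 2, stats::sd)
  }
  if (w == 1) S[] <- 0
  colnames(M) <- paste0("m_", colnames(X))
  colnames(S) <- paste0("sd_", colnames(X))
  cbind(M, S)
}

#' Feature table for one segmented recording
#'
#' Runs QC, extracts the 177 features of every kept segment, drops flagged
#' segments, and applies the cyclic windowed aggregation.
#'
#' @param rec A filtered, normalized [pcg_recording()].
#' @param annotation State annotation (from [viterbi_segment()] or ground
#'   truth).
#' @param config A [spectral_config()].
#' @param window Cyclic window length.
#' @return A data.frame with recording metadata, segment index, and the 354
#'   windowed features; `attr(, "qc")` holds per-segment QC statuses and
#'   `attr(, "recording_qc")` the [qc_recording()] verdict.
#' @export
featurize_recording <- function(rec, annotation, config = spectral_config(),
                                window = 6) {
  env <- homomorphic_envelope(rec$samples, rec$rate)
  segs <- extract_segments(annotation)
  segs <- qc_segments(segs, rec$samples, env)
  rec_qc <- tryCatch(qc_recording(segs), error = function(e) "ok")
  status <- vapply(segs, `[[`, character(1), "qc_status")
  kept <- segs[status == "kept"]
  rows <- list(); keep_idx <- integer(0)
  for (i in seq_along(kept)) {
    v <- extract_segment_features(kept[[i]], rec$samples, env, config, rec$rate)
    if (!attr(v, "flagged")) {
      rows[[length(rows) + 1]] <- v
      keep_idx <- c(keep_idx, i)
    }
  }
  if (length(rows) == 0) {
    out <- NULL
  } else {
    Xw <- cyclic_window_aggregate(do.call(rbind, rows), window)
    out <- data.frame(recording_id = rec$recording_id,
                      subject_id = rec$subject_id, device = rec$device,
                      phase = rec$phase, segment = keep_idx,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(Xw))
  }
  structure(out, qc = status, recording_qc = rec_qc)
}
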