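#' Acquisition-device profiles
#'
#' Two built-in profiles emulate the study's electronic stethoscopes, which
#' differ in recording length, amplitude, and the spectral roll-off of their
#' residual noise: `"setup1"` records 30 s with noise concentrated at low
#' frequencies, `"setup2"` records 15 s with broader-band noise.
#'
#' @param name `"setup1"`, `"setup2"`, or a custom name (then the remaining
#'   arguments must be supplied).
#' @param record_seconds Recording duration in seconds.
#' @param gain_dbfs Target recording loudness in dBFS (RMS re full scale).
#' @param noise_rolloff_hz Corner frequency (Hz) of the one-pole low-pass
#'   shaping the additive device noise.
#' @return A list of class `pcg_device` with the four fields above.
#' @export
device_profile <- function(name, record_seconds = NULL, gain_dbfs = NULL,
                           noise_rolloff_hz = NULL) {
  builtin <- list(
    setup1 = list(record_seconds = 30, gain_dbfs = -26, noise_rolloff_hz = 30),
    setup2 = list(record_seconds = 15, gain_dbfs = -18, noise_rolloff_hz = 300))
  if (name %in% names(builtin)) {
    p <- builtin[[name]]
    if (!is.null(record_seconds)) p$record_seconds <- record_seconds
    if (!is.null(gain_dbfs)) p$gain_dbfs <- gain_dbfs
    if (!is.null(noise_rolloff_hz)) p$noise_rolloff_hz <- noise_rolloff_hz
  } else {
    if (is.null(record_seconds) || is.null(gain_dbfs) || is.null(noise_rolloff_hz))
      stop("custom device profile needs record_seconds, gain_dbfs, noise_rolloff_hz")
    p <- list(record_seconds = record_seconds, gain_dbfs = gain_dbfs,
              noise_rolloff_hz = noise_rolloff_hz)
  }
  stopifnot(p$record_seconds > 0, p$noise_rolloff_hz > 0)
  structure(c(list(name = name), p), class = "pcg_device")
}

#' Class-conditional acoustic effect configuration
#'
#' Controls the differences the generator imposes between the decompensated
#' (phase 1) and recompensated (phase 0) classes. Defaults encode the
#' physiological picture motivating the classifier: decompensated patients have
#' a faster pulse, a relatively shorter diastole, a more prominent S3 gallop
#' sound, and altered diastolic spectral content (a 140-300 Hz band component
#' from stiffer ventricular refilling).
#'
#' @param bpm_mean_by_phase Named numeric, mean heart rate (beats/min) for
#'   phases `"0"` and `"1"`. Default 70 / 90.
#' @param bpm_sd Between-recording heart-rate SD in beats/min.
#' @param systole_fraction_by_phase Fraction of the RR interval from S1 onset
#'   to S2 onset, per phase; must lie in (0, 1).
#' @param s3_amplitude_by_phase Relative amplitude of the early-diastolic S3
#'   sound (S1 has amplitude 1), per phase; non-negative.
#' @param diastolic_band_gain_by_phase Relative amplitude of a band-limited
#'   140-300 Hz noise component present during diastole, per phase.
#' @param noise_snr_db Signal-to-noise ratio of the additive device noise in
#'   dB; `Inf` disables it.
#' @param rr_jitter_sigma SD of the multiplicative log-normal per-cycle RR
#'   jitter.
#' @param subject_bpm_sd SD of a per-subject heart-rate offset (beats/min)
#'   shared by both of a subject's recordings.
#' @return A list of class `pcg_effects`.
#' @export
phase_effects <- function(bpm_mean_by_phase = c("0" = 70, "1" = 90),
                          bpm_sd = 5,
                          systole_fraction_by_phase = c("0" = 0.35, "1" = 0.42),
                          s3_amplitude_by_phase = c("0" = 0.05, "1" = 0.35),
                          diastolic_band_gain_by_phase = c("0" = 0.10, "1" = 0.45),
                          noise_snr_db = 25,
                          rr_jitter_sigma = 0.03,
                          subject_bpm_sd = 3) {
  ef <- list(bpm_mean_by_phase = bpm_mean_by_phase, bpm_sd = bpm_sd,
             systole_fraction_by_phase = systole_fraction_by_phase,
             s3_amplitude_by_phase = s3_amplitude_by_phase,
             diastolic_band_gain_by_phase = diastolic_band_gain_by_phase,
             noise_snr_db = noise_snr_db, rr_jitter_sigma = rr_jitter_sigma,
             subject_bpm_sd = subject_bpm_sd)
  stopifnot(all(ef$bpm_mean_by_phase > 0),
            all(ef$systole_fraction_by_phase > 0),
            all(ef$systole_fraction_by_phase < 1),
            all(ef$s3_amplitude_by_phase >= 0),
            all(ef$diastolic_band_gain_by_phase >= 0))
  structure(ef, class = "pcg_effects")
}

#' Effect configuration with no class signal
#'
#' Both phases share every acoustic parameter, so any classifier can only
#' perform at chance. Used as the negative control for the end-to-end pipeline.
#'
#' @inheritParams phase_effects
#' @return A `pcg_effects` object whose per-phase parameters are equal.
#' @export
null_phase_effects <- function(noise_snr_db = 25) {
  phase_effects(bpm_mean_by_phase = c("0" = 80, "1" = 80),
                systole_fraction_by_phase = c("0" = 0.38, "1" = 0.38),
                s3_amplitude_by_phase = c("0" = 0.2, "1" = 0.2),
                diastolic_band_gain_by_phase = c("0" = 0.25, "1" = 0.25),
                noise_snr_db = noise_snr_db)
}

# One heart-sound burst: sum of damped sinusoids under a Gaussian-onset window.
# Returns a vector of length n_samp; exactly zero outside is guaranteed by the
# caller placing it only inside its state interval.
pcg_burst <- function(n_samp, rate, freqs, weights, phases) {
  if (n_samp < 2) return(numeric(n_samp))
  t <- (seq_len(n_samp) - 1) / rate
  dur <- n_samp / rate
  # raised-cosine onset/offset ramps (40% total taper) with a mild exponential
  # decay: the burst audibly occupies its whole annotated interval while
  # keeping the damped character of a valve-closure transient
  u <- t / dur
  ramp <- 0.2
  env <- ifelse(u < ramp, 0.5 * (1 - cos(pi * u / ramp)),
                ifelse(u > 1 - ramp, 0.5 * (1 - cos(pi * (1 - u) / ramp)), 1))
  env <- env * exp(-t / (1.5 * dur))
  x <- numeric(n_samp)
  for (i in seq_along(freqs)) {
    x <- x + weights[i] * sin(2 * pi * freqs[i] * t + phases[i])
  }
  env * x / max(abs(env * x) + 1e-12)
}

#' Generate one synthetic phonocardiogram with ground truth
#'
#' Synthesizes a 4 kHz mono heart-sound signal: S1 bursts of 0.12-0.15 s with
#' 10-200 Hz content and S2 bursts of 0.08-0.12 s with 20-250 Hz content at
#' cycle positions set by the recording's heart rate (with log-normal per-cycle
#' jitter), an optional early-diastolic S3, an optional 140-300 Hz diastolic
#' band component, and low-pass-shaped additive device noise. Every sample is
#' annotated with exactly one of the four states, cycling
#' S1 -> systole -> S2 -> diastole.
#'
#' @param subject_id Subject identifier.
#' @param phase 0 (recompensated) or 1 (decompensated).
#' @param device A [device_profile()].
#' @param effects A [phase_effects()].
#' @param seed Integer seed; the output is bit-identical for equal seeds.
#' @param bpm_offset Additive heart-rate offset (beats/min), used by
#'   [generate_cohort()] for subject-level effects.
#' @return A list with `recording` (a [pcg_recording()]) and `truth`, the
#'   latter holding `annotation` (data.frame `start`, `end`, `state`; 0-based
#'   half-open sample intervals), `true_bpm`, `phase`, `subject_id`.
#' @export
generate_recording <- function(subject_id, phase,
                               device = device_profile("setup1"),
                               effects = phase_effects(), seed,
                               bpm_offset = 0) {
  if (!phase %in% c(0, 1)) stop("invalid phase label: must be 0 or 1")
  key <- as.character(phase)
  with_seed(seed, {
    rate <- 4000
    n <- as.integer(round(device$record_seconds * rate))
    bpm <- stats::rnorm(1, effects$bpm_mean_by_phase[[key]] + bpm_offset,
                        effects$bpm_sd)
    bpm <- max(bpm, 30)
    if (bpm <= 0) stop("non-positive BPM")
    sys_frac <- effects$systole_fraction_by_phase[[key]]

    # --- cycle timetable in samples (0-based half-open runs) ----------------
    runs <- list(); x <- numeric(n)
    onset <- 0L
    while (onset < n) {
      rr <- (60 / bpm) * exp(stats::rnorm(1, 0, effects$rr_jitter_sigma))
      rr_s <- max(8L, as.integer(round(rr * rate)))
      d1 <- as.integer(round(stats::runif(1, 0.12, 0.15) * rate))
      d2 <- as.integer(round(stats::runif(1, 0.08, 0.12) * rate))
      dsys <- as.integer(round(sys_frac * rr_s)) - d1
      dsys <- max(dsys, as.integer(0.04 * rate))
      ddia <- rr_s - d1 - dsys - d2
      ddia <- max(ddia, as.integer(0.08 * rate))
      rr_s <- d1 + dsys + d2 + ddia
      b <- onset + cumsum(c(0L, d1, dsys, d2, ddia))
      amp1 <- exp(stats::rnorm(1, 0, 0.1))
      amp2 <- 0.8 * exp(stats::rnorm(1, 0, 0.1))
      s1 <- amp1 * pcg_burst(d1, rate, c(35, 70, 110, 150), c(1, .8, .5, .3),
                             stats::runif(4, 0, 2 * pi))
      s2 <- amp2 * pcg_burst(d2, rate, c(50, 90, 150, 220), c(1, .8, .5, .3),
                             stats::runif(4, 0, 2 * pi))
      i1 <- seq.int(b[1] + 1L, min(b[2], n)); x[i1] <- s1[seq_along(i1)]
      if (b[3] < n) {
        i2 <- seq.int(b[3] + 1L, min(b[4], n)); x[i2] <- s2[seq_along(i2)]
      }
      # S3: 0.04 s soft low-frequency thud in early diastole
      s3a <- effects$s3_amplitude_by_phase[[key]]
      if (s3a > 0 && b[4] < n) {
        d3 <- as.integer(0.04 * rate)
        o3 <- b[4] + as.integer(0.10 * ddia)
        if (o3 + d3 <= n && o3 + d3 <= b[5]) {
          s3 <- s3a * exp(stats::rnorm(1, 0, 0.1)) *
            pcg_burst(d3, rate, c(30, 45), c(1, .6), stats::runif(2, 0, 2 * pi))
          x[seq.int(o3 + 1L, o3 + d3)] <- x[seq.int(o3 + 1L, o3 + d3)] + s3
        }
      }
      for (k in 1:4) {
        runs[[length(runs) + 1L]] <-
          list(start = b[k], end = min(b[k + 1L], n), state = PCG_STATES[k])
        if (b[k + 1L] >= n) break
      }
      onset <- onset + rr_s
    }
    ann <- do.call(rbind, lapply(runs, function(r)
      data.frame(start = r$start, end = r$end, state = r$state,
                 stringsAsFactors = FALSE)))
    ann <- ann[ann$end > ann$start, , drop = FALSE]
    rownames(ann) <- NULL

    # --- diastolic 140-300 Hz band component, masked to diastole ------------
    dgain <- effects$diastolic_band_gain_by_phase[[key]]
    if (dgain > 0) {
      bp <- signal::butter(4, c(140, 300) / (rate / 2), type = "pass")
      dn <- signal::filtfilt(bp, stats::rnorm(n))
      mask <- numeric(n)
      dia <- ann[ann$state == "diastole", , drop = FALSE]
      for (j in seq_len(nrow(dia)))
        mask[seq.int(dia$start[j] + 1L, dia$end[j])] <- 1
      dn <- dn * mask
      r <- sqrt(mean(dn[mask == 1]^2))
      if (is.finite(r) && r > 0) x <- x + dn * (dgain * 0.15 / r)
    }

    # --- device noise shaped by one-pole low-pass ---------------------------
    if (is.finite(effects$noise_snr_db)) {
      a <- exp(-2 * pi * device$noise_rolloff_hz / rate)
      nz <- as.numeric(stats::filter(stats::rnorm(n) * (1 - a), a,
                                     method = "recursive"))
      sig_rms <- sqrt(mean(x^2))
      nz_rms <- sqrt(mean(nz^2))
      x <- x + nz * (sig_rms / nz_rms) * 10^(-effects$noise_snr_db / 20)
    }

    # --- device loudness ----------------------------------------------------
    rms <- sqrt(mean(x^2))
    if (rms > 0) x <- x * 10^(device$gain_dbfs / 20) / rms
    x <- pmin(1, pmax(-1, x))

    rec <- pcg_recording(x, rate, subject_id = subject_id, device = device$name,
                         phase = as.integer(phase))
    list(recording = rec,
         truth = list(annotation = ann, true_bpm = bpm,
                      phase = as.integer(phase), subject_id = subject_id))
  })
}

#' Generate a paired synthetic cohort
#'
#' Each subject contributes exactly two recordings, one per phase
#' (decompensated and recompensated), as in a hospital admission/discharge
#' design. Subjects are assigned to device profiles by `device_split`, and a
#' per-subject heart-rate offset is shared across the subject's two phases.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param device_split Named integer vector of subject counts per device, e.g.
#'   `c(setup1 = 21, setup2 = 16)`; defaults to a 21:16 proportional split.
#' @param effects A [phase_effects()].
#' @param seed Integer master seed; cohorts are reproducible bit-identically.
#' @return A list of class `pcg_cohort`; each element is the
#'   [generate_recording()] result for one recording. The cohort manifest
#'   (subject, device, phase, recording id, true BPM) is in
#'   `attr(x, "manifest")`.
#' @export
generate_cohort <- function(n_subjects, device_split = NULL,
                            effects = phase_effects(), seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (is.null(device_split)) {
    n1 <- round(n_subjects * 21 / 37)
    device_split <- c(setup1 = n1, setup2 = n_subjects - n1)
  }
  if (sum(device_split) != n_subjects)
    stop("device_split must sum to n_subjects")
  devices <- rep(names(device_split), device_split)
  offsets <- with_seed(child_seed(seed, 0),
                       stats::rnorm(n_subjects, 0, effects$subject_bpm_sd))
  out <- vector("list", 2L * n_subjects)
  manifest <- NULL
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    dev <- device_profile(devices[i])
    for (ph in c(1L, 0L)) {
      g <- generate_recording(sid, ph, dev, effects,
                              seed = child_seed(seed, 2L * i + ph),
                              bpm_offset = offsets[i])
      idx <- 2L * (i - 1L) + (2L - ph)
      out[[idx]] <- g
      manifest <- rbind(manifest, data.frame(
        recording_id = g$recording$recording_id, subject_id = sid,
        device = devices[i], phase = ph, true_bpm = g$truth$true_bpm,
        stringsAsFactors = FALSE))
    }
  }
  structure(out, class = "pcg_cohort", manifest = manifest)
}

#' @export
print.pcg_cohort <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("<pcg_cohort> %d recordings from %d subjects\n",
              nrow(m), length(unique(m$subject_id))))
  print(table(device = m$device, phase = m$phase))
  invisible(x)
}

#' Write a cohort to disk as WAV + annotation CSVs + manifest
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (with file paths), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- attr(cohort, "manifest")
  m$path <- file.path(dir, paste0(m$recording_id, ".wav"))
  m$annotation_path <- file.path(dir, paste0(m$recording_id, "_states.csv"))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]$recording
    write_wav(rec$samples, rec$rate, m$path[i])
    ann <- cohort[[i]]$truth$annotation
    utils::write.csv(
      data.frame(sample_start = ann$start, sample_end = ann$end,
                 state = ann$state),
      m$annotation_path[i], row.names = FALSE)
  }
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}
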