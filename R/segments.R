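# Cardiac-cycle slicing and segment/recording quality control.

#' Slice a state annotation into cardiac cycles
#'
#' One segment per complete S1-to-next-S1 span: the four state runs must be
#' present in cyclic order and the next S1 onset must exist (incomplete
#' leading and trailing cycles are dropped).
#'
#' @param annotation Run table (`start`, `end`, `state`; 0-based half-open).
#' @return List of `pcg_segment` objects: each has `rr_start`, `rr_end`,
#'   `intervals` (named list of `c(start, end)` per state), `qc_status`
#'   (`"kept"` until QC runs) and `qc_reason`.
#' @export
extract_segments <- function(annotation) {
  stopifnot(all(c("start", "end", "state") %in% names(annotation)))
  n <- nrow(annotation)
  segs <- list()
  for (i in seq_len(n)) {
    if (annotation$state[i] != "S1" || i + 4 > n) next
    if (!all(annotation$state[i:(i + 3)] == PCG_STATES)) next
    if (annotation$state[i + 4] != "S1") next
    iv <- lapply(0:3, function(k)
      c(annotation$start[i + k], annotation$end[i + k]))
    names(iv) <- PCG_STATES
    segs[[length(segs) + 1]] <- structure(
      list(rr_start = annotation$start[i], rr_end = annotation$start[i + 4],
           intervals = iv, qc_status = "kept", qc_reason = ""),
      class = "pcg_segment")
  }
  if (length(segs) == 0) stop("fewer than one complete cardiac cycle")
  segs
}

slice_state <- function(signal, interval) {
  if (interval[2] <= interval[1]) return(numeric(0))
  signal[(interval[1] + 1):min(interval[2], length(signal))]
}

#' Quality control of one cardiac segment
#'
#' A segment is `removed_missing_sound` when the peak envelope inside its S1
#' or S2 interval falls below `theta_presence` times the recording's median
#' per-cycle peak envelope (the sound is effectively absent), and
#' `removed_noisy` when the mean envelope over systole + diastole exceeds
#' `theta_noise` times the mean envelope over S1 + S2 (noise drowning the
#' sounds). Otherwise it is kept.
#'
#' @param segment A `pcg_segment`.
#' @param signal The recording's sample vector.
#' @param envelope Per-sample homomorphic envelope of the recording.
#' @param ref_peak The recording's median per-cycle peak envelope; defaults to
#'   this segment's own peak (so presence cannot trip on a lone segment).
#' @param theta_presence,theta_noise QC thresholds.
#' @return The segment with `qc_status` and `qc_reason` filled in.
#' @export
qc_segment <- function(segment, signal, envelope, ref_peak = NULL,
                       theta_presence = 0.25, theta_noise = 0.5) {
  env_in <- function(st) slice_state(envelope, segment$intervals[[st]])
  if (is.null(ref_peak))
    ref_peak <- max(envelope[(segment$rr_start + 1):segment$rr_end])
  pk_s1 <- max(env_in("S1"), 0)
  pk_s2 <- max(env_in("S2"), 0)
  if (pk_s1 < theta_presence * ref_peak || pk_s2 < theta_presence * ref_peak) {
    segment$qc_status <- "removed_missing_sound"
    segment$qc_reason <- sprintf("peak envelope %s below %.2f x median cycle peak",
                                 if (pk_s1 < pk_s2) "S1" else "S2",
                                 theta_presence)
    return(segment)
  }
  quiet <- c(env_in("systole"), env_in("diastole"))
  loud <- c(env_in("S1"), env_in("S2"))
  if (mean(quiet) > theta_noise * mean(loud)) {
    segment$qc_status <- "removed_noisy"
    segment$qc_reason <- "mean envelope in systole+diastole exceeds that of S1+S2"
    return(segment)
  }
  segment$qc_status <- "kept"
  segment$qc_reason <- ""
  segment
}

#' Quality control of all segments of a recording
#'
#' Computes the recording's median per-cycle peak envelope and applies
#' [qc_segment()] to each segment.
#'
#' @inheritParams qc_segment
#' @param segments List of `pcg_segment` from [extract_segments()].
#' @return The list with QC status filled in.
#' @export
qc_segments <- function(segments, signal, envelope, theta_presence = 0.25,
                        theta_noise = 0.5) {
  peaks <- vapply(segments, function(s)
    max(envelope[(s$rr_start + 1):s$rr_end]), numeric(1))
  ref <- stats::median(peaks)
  lapply(segments, qc_segment, signal = signal, envelope = envelope,
         ref_peak = ref, theta_presence = theta_presence,
         theta_noise = theta_noise)
}

#' Recording-level segmentation quality check
#'
#' Flags a recording as mis-segmented when too many of its cycles are
#' implausibly long or short: the fraction of RR lengths outside
#' `[median/rho, rho * median]` must not exceed `phi`.
#'
#' @param segments List of `pcg_segment` (at least 3).
#' @param rho RR-length tolerance factor (> 1).
#' @param phi Maximum tolerated fraction of out-of-range cycles.
#' @return `"ok"` or `"mis_segmented"`.
#' @export
qc_recording <- function(segments, rho = 1.5, phi = 0.2) {
  if (length(segments) < 3) stop("need at least 3 segments for recording QC")
  rr <- vapply(segments, function(s) s$rr_end - s$rr_start, numeric(1))
  med <- stats::median(rr)
  frac <- mean(rr < med / rho | rr > med * rho)
  if (frac > phi) "mis_segmented" else "ok"
}

#' Sample-level agreement between two state annotations
#'
#' @param pred,truth Run tables (`start`, `end`, `state`).
#' @param n_samples Number of samples both annotations cover.
#' @return Fraction of samples assigned the same state.
#' @export
segmentation_accuracy <- function(pred, truth, n_samples) {
  a <- annotation_states(pred, n_samples)
  b <- annotation_states(truth, n_samples)
  mean(a == b, na.rm = TRUE)
}
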