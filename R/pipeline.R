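# End-to-end pipeline: preprocess -> segment -> QC -> featurize for a whole
# cohort, producing the feature table and QC flags that feed cross_validate().

#' Preprocess one recording (band-pass + RMS normalization)
#'
#' @param rec A [pcg_recording()].
#' @param low_hz,high_hz,order Band-pass parameters.
#' @param target_dbfs RMS normalization target.
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, low_hz = 25, high_hz = 400, order = 4,
                                 target_dbfs = -20) {
  rms_normalize(bandpass_filter(rec, low_hz, high_hz, order), target_dbfs)
}

#' Run the full analysis pipeline on a cohort
#'
#' Preprocesses every recording, fits the HSMM segmenter on the cohort's
#' ground-truth annotations (or uses a supplied model), decodes every
#' recording by semi-Markov Viterbi, applies segment and recording QC,
#' extracts and cyclically windows the feature catalogue, and returns the
#' pooled feature table plus recording-level QC flags.
#'
#' @param cohort A [generate_cohort()] result (or any list of elements with
#'   `$recording` and `$truth$annotation`).
#' @param hsmm Optional pre-fitted [fit_hsmm()] model; fitted on the cohort's
#'   annotations when `NULL`.
#' @param config A [spectral_config()].
#' @param window Cyclic aggregation window.
#' @param use_truth_segmentation Skip Viterbi decoding and featurize on the
#'   ground-truth annotations (for diagnostics).
#' @return List with `features` (data.frame, one row per kept segment), `qc`
#'   (data.frame `recording_id`, `subject_id`, `recording_qc`,
#'   `segments_kept`, `segments_removed`), and `hsmm` (the segmenter used).
#' @export
run_pipeline <- function(cohort, hsmm = NULL, config = spectral_config(),
                         window = 6, use_truth_segmentation = FALSE) {
  pre <- lapply(cohort, function(el) {
    el$recording <- preprocess_recording(el$recording)
    el
  })
  if (is.null(hsmm) && !use_truth_segmentation) hsmm <- fit_hsmm(pre)
  feats <- list(); qc <- list()
  for (el in pre) {
    rec <- el$recording
    ann <- if (use_truth_segmentation) el$truth$annotation
           else viterbi_segment(rec, hsmm)
    ft <- tryCatch(featurize_recording(rec, ann, config, window),
                   error = function(e) NULL)
    status <- attr(ft, "qc")
    rqc <- if (is.null(ft)) "mis_segmented" else attr(ft, "recording_qc")
    qc[[length(qc) + 1]] <- data.frame(
      recording_id = rec$recording_id, subject_id = rec$subject_id,
      recording_qc = rqc,
      segments_kept = sum(status == "kept"),
      segments_removed = sum(status != "kept"))
    if (!is.null(ft) && nrow(ft) > 0) feats[[length(feats) + 1]] <- ft
  }
  list(features = do.call(rbind, feats), qc = do.call(rbind, qc), hsmm = hsmm)
}
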