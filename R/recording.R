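#' Construct a phonocardiogram recording object
#'
#' The unit of I/O throughout the package: a single-channel heart-sound signal
#' in full-scale units with its sampling rate and per-recording metadata.
#'
#' @param samples Numeric vector, amplitudes in \[-1, 1\].
#' @param rate Sampling rate in Hz (the pipeline operates at 4000 Hz).
#' @param subject_id Subject identifier.
#' @param device Acquisition-device profile name (e.g. `"setup1"`).
#' @param phase Class label: 0 = recompensated, 1 = decompensated, or `NA`.
#' @param recording_id Optional recording identifier; defaults to
#'   `<subject>_p<phase>`.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, rate, subject_id = NA_character_,
                          device = NA_character_, phase = NA_integer_,
                          recording_id = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0, rate > 0)
  if (!is.na(phase) && !phase %in% c(0L, 1L)) {
    stop("phase must be 0 (recompensated), 1 (decompensated) or NA")
  }
  if (is.null(recording_id)) {
    recording_id <- if (is.na(subject_id)) "rec" else
      paste0(subject_id, "_p", ifelse(is.na(phase), "x", phase))
  }
  structure(
    list(samples = as.numeric(samples), rate = rate,
         subject_id = as.character(subject_id), device = as.character(device),
         phase = as.integer(phase), recording_id = recording_id),
    class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %s: %.1f s at %d Hz (%d samples)\n",
              x$recording_id, length(x$samples) / x$rate, as.integer(x$rate),
              length(x$samples)))
  cat(sprintf("  subject: %s  device: %s  phase: %s\n", x$subject_id,
              x$device, ifelse(is.na(x$phase), "unknown",
                               c("recompensated", "decompensated")[x$phase + 1])))
  invisible(x)
}

# The four heart-sound states in their fixed cyclic order.
PCG_STATES <- c("S1", "systole", "S2", "diastole")

# Run a block with a private RNG stream so callers' RNG state is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed < 2^31 from a master seed and an index, deterministically.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629 + 1
}
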