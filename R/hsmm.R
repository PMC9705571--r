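# Duration-dependent hidden semi-Markov segmentation of the four heart-sound
# states. The state topology is the fixed cycle S1 -> systole -> S2 ->
# diastole; emissions are Gaussians over the four envelope features; state
# durations are Gaussians truncated to an admissible range, with the
# systole/diastole means rescaled at decode time to the recording's estimated
# heart rate.

# Expand a run-table annotation (0-based half-open sample intervals) to one
# state label per sample.
annotation_states <- function(annotation, n_samples) {
  lab <- rep(NA_character_, n_samples)
  for (i in seq_len(nrow(annotation))) {
    a <- annotation$start[i]; b <- min(annotation$end[i], n_samples)
    if (b > a) lab[(a + 1):b] <- annotation$state[i]
  }
  lab
}

# State label per envelope frame (frame centers).
frame_states <- function(annotation, hop, nf) {
  centers <- (seq_len(nf) - 1) * hop + floor(hop / 2) # 0-based sample index
  idx <- findInterval(centers, annotation$start)
  ok <- idx >= 1 & centers < annotation$end[pmax(idx, 1)]
  out <- rep(NA_character_, nf)
  out[ok] <- annotation$state[idx[ok]]
  out
}

#' Fit HSMM emission and duration models from annotated recordings
#'
#' Estimates, for each of the four states, a Gaussian emission model (mean and
#' covariance of the four envelope features over labelled frames) and Gaussian
#' duration statistics (mean and SD of run lengths in frames). The generator's
#' ground-truth annotations play the role of the labelled training data.
#'
#' @param annotated A `pcg_cohort`, or a list whose elements have
#'   `$recording` (a [pcg_recording()]) and either `$annotation` or
#'   `$truth$annotation` (run table with `start`, `end`, `state`).
#' @param feature_rate Envelope frame rate in Hz.
#' @return An object of class `pcg_hsmm`.
#' @export
fit_hsmm <- function(annotated, feature_rate = 50) {
  if (length(annotated) < 1) stop("need at least one annotated recording")
  feats <- list(); labs <- list(); durs <- list()
  for (el in annotated) {
    rec <- el$recording
    ann <- if (!is.null(el$annotation)) el$annotation else el$truth$annotation
    if (is.null(rec) || is.null(ann)) stop("elements need $recording and an annotation")
    E <- envelope_features(rec, feature_rate)
    hop <- attr(E, "hop")
    fs <- frame_states(ann, hop, nrow(E))
    keep <- !is.na(fs)
    feats[[length(feats) + 1]] <- E[keep, , drop = FALSE]
    labs[[length(labs) + 1]] <- fs[keep]
    # interior runs only: first/last runs are truncated by the recording edges
    if (nrow(ann) > 2) {
      inner <- ann[-c(1, nrow(ann)), , drop = FALSE]
      durs[[length(durs) + 1]] <-
        data.frame(state = inner$state, frames = (inner$end - inner$start) / hop)
    }
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  dd <- do.call(rbind, durs)
  missing <- setdiff(PCG_STATES, unique(y))
  if (length(missing) > 0)
    stop("state(s) absent from all annotations: ", paste(missing, collapse = ", "))
  emission <- lapply(PCG_STATES, function(s) {
    Xs <- X[y == s, , drop = FALSE]
    # maximum-likelihood covariance (divide by n): invariant under data
    # duplication, the natural estimator for HMM emissions
    ctr <- sweep(Xs, 2, colMeans(Xs))
    cv <- crossprod(ctr) / nrow(Xs) + diag(1e-4, ncol(Xs))
    list(mean = colMeans(Xs), cov = cv)
  })
  names(emission) <- PCG_STATES
  duration <- do.call(rbind, lapply(PCG_STATES, function(s) {
    d <- dd$frames[dd$state == s]
    if (length(d) == 0) d <- c(6, 6)
    data.frame(state = s, mean_frames = mean(d),
               sd_frames = max(sqrt(mean((d - mean(d))^2)), 0.7))
  }))
  structure(list(states = PCG_STATES, emission = emission, duration = duration,
                 feature_rate = feature_rate),
            class = "pcg_hsmm")
}

#' @export
print.pcg_hsmm <- function(x, ...) {
  cat("<pcg_hsmm> duration-dependent heart-sound segmenter\n")
  cat(sprintf("  feature rate: %g Hz; states: %s\n", x$feature_rate,
              paste(x$states, collapse = " -> ")))
  d <- x$duration
  cat(sprintf("  durations (frames): %s\n",
              paste(sprintf("%s %.1f±%.1f", d$state, d$mean_frames,
                            d$sd_frames), collapse = ", ")))
  invisible(x)
}

# Frame log-likelihoods under the per-state Gaussian emissions.
emission_loglik <- function(E, params) {
  k <- ncol(E)
  sapply(params$states, function(s) {
    em <- params$emission[[s]]
    ch <- chol(em$cov)
    z <- forwardsolve(t(ch), t(E) - em$mean)
    -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
  })
}

# Truncated-Gaussian duration log-pmf and log-survival per state, with the
# systole/diastole means rescaled to the recording's heart-rate estimate.
duration_model <- function(params, bpm, systole_duration_s) {
  fr <- params$feature_rate
  d <- params$duration
  mu <- stats::setNames(d$mean_frames, d$state)
  sdv <- stats::setNames(d$sd_frames, d$state)
  if (!is.null(bpm)) {
    rr <- 60 / bpm * fr
    mu["systole"] <- max(2, systole_duration_s * fr - mu["S1"])
    mu["diastole"] <- max(2, rr - mu["S1"] - mu["systole"] - mu["S2"])
    sdv["systole"] <- max(1, 0.15 * mu["systole"])
    sdv["diastole"] <- max(1.5, 0.15 * mu["diastole"])
  }
  dmin <- pmax(1, floor(mu - 3.5 * sdv))
  dmax <- ceiling(mu + 3.5 * sdv)
  D <- max(dmax)
  logpmf <- matrix(-Inf, D, length(params$states))
  logsurv <- matrix(-Inf, D, length(params$states))
  for (j in seq_along(params$states)) {
    s <- params$states[j]
    dd <- seq_len(D)
    p <- stats::dnorm(dd, mu[s], sdv[s])
    p[dd < dmin[s] | dd > dmax[s]] <- 0
    p <- p / sum(p)
    logpmf[, j] <- log(p)
    logsurv[, j] <- log(rev(cumsum(rev(p))))
  }
  list(logpmf = logpmf, logsurv = logsurv)
}

#' Segment a recording by duration-dependent Viterbi decoding
#'
#' Computes the maximum a-posteriori cyclic state path under the semi-Markov
#' model: each run's length is scored by the state's truncated-Gaussian
#' duration model (the first and last, edge-censored, runs by its survival
#' function) and each frame by the Gaussian emission likelihood of the four
#' envelope features.
#'
#' @param rec A filtered, normalized [pcg_recording()].
#' @param params A fitted [fit_hsmm()] model.
#' @param adapt_heart_rate Rescale systole/diastole duration means to the
#'   recording's estimated heart rate (default TRUE).
#' @return A state annotation: data.frame with `start`, `end` (0-based
#'   half-open sample indices) and `state`.
#' @export
viterbi_segment <- function(rec, params, adapt_heart_rate = TRUE) {
  stopifnot(inherits(params, "pcg_hsmm"))
  E <- envelope_features(rec, params$feature_rate)
  hop <- attr(E, "hop")
  hr <- if (adapt_heart_rate) {
    tryCatch(estimate_heart_rate(E, params$feature_rate),
             error = function(e) NULL)
  } else NULL
  dm <- if (is.null(hr)) duration_model(params, NULL, NULL)
        else duration_model(params, hr$bpm, hr$systole_duration_s)
  ll <- emission_loglik(E, params)
  path <- hsmm_viterbi_cpp(ll, dm$logpmf, dm$logsurv) + 1L
  r <- rle(path)
  ends_f <- cumsum(r$lengths)
  starts_f <- c(0L, ends_f[-length(ends_f)])
  ann <- data.frame(start = starts_f * hop, end = ends_f * hop,
                    state = params$states[r$values],
                    stringsAsFactors = FALSE)
  ann$end[nrow(ann)] <- length(rec$samples)
  ann
}

#' @export
predict.pcg_hsmm <- function(object, newdata, ...) {
  viterbi_segment(newdata, object, ...)
}
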