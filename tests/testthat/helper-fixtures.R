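# Shared fixtures, built once per test run, and independent oracles.

fixture_env <- new.env(parent = emptyenv())

# A small preprocessed cohort with a fitted segmenter, reused across files.
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    co <- generate_cohort(4, c(setup1 = 2, setup2 = 2), seed = 42)
    pre <- lapply(co, function(el) {
      el$recording <- preprocess_recording(el$recording)
      el
    })
    fixture_env$small <- list(raw = co, pre = pre, hsmm = fit_hsmm(pre))
  }
  fixture_env$small
}

# Features + QC of the small cohort through the full pipeline, cached.
small_pipeline <- function() {
  if (is.null(fixture_env$small_pl)) {
    fx <- small_cohort()
    fixture_env$small_pl <- run_pipeline(fx$raw, hsmm = fx$hsmm)
  }
  fixture_env$small_pl
}

# One clean preprocessed recording with ground truth and envelope.
clean_recording <- function() {
  if (is.null(fixture_env$clean)) {
    g <- generate_recording("SX", 0, device_profile("setup1"),
                            phase_effects(), seed = 21)
    rec <- preprocess_recording(g$recording)
    env <- pcgphase:::homomorphic_envelope(rec$samples, rec$rate)
    segs <- extract_segments(g$truth$annotation)
    fixture_env$clean <- list(g = g, rec = rec, env = env, segs = segs)
  }
  fixture_env$clean
}

# A synthetic "segment" wrapper around an arbitrary waveform so the feature
# operations can be exercised on constructed signals: the waveform is placed
# in every state interval of a fabricated cycle.
fake_segment <- function(state_signals, rate = 4000) {
  lens <- vapply(state_signals, length, integer(1))
  ends <- cumsum(lens)
  starts <- c(0L, ends[-4])
  iv <- Map(function(s, e) c(s, e), starts, ends)
  names(iv) <- c("S1", "systole", "S2", "diastole")
  seg <- structure(list(rr_start = 0L, rr_end = ends[4], intervals = iv,
                        qc_status = "kept", qc_reason = ""),
                   class = "pcg_segment")
  list(segment = seg, signal = unlist(state_signals, use.names = FALSE))
}

# Independent brute-force decoder: enumerates every admissible cyclic run
# decomposition and scores it with the same boundary conventions as the
# package decoder (survival terms for the edge-censored first and last runs).
oracle_viterbi <- function(loglik, logpmf, logsurv) {
  TT <- nrow(loglik); S <- ncol(loglik); D <- nrow(logpmf)
  best <- list(score = -Inf, path = NULL)
  recurse <- function(t, s, score, path) {
    for (d in seq_len(min(D, TT - t))) {
      em <- sum(loglik[(t + 1):(t + d), s])
      last <- (t + d == TT); first <- (t == 0)
      dur <- if (first || last) logsurv[d, s] else logpmf[d, s]
      sc <- score + em + dur
      if (!is.finite(sc)) next
      np <- c(path, rep(s, d))
      if (last) {
        if (sc > best$score) best <<- list(score = sc, path = np)
      } else {
        recurse(t + d, (s %% S) + 1L, sc, np)
      }
    }
  }
  for (s0 in seq_len(S)) recurse(0L, s0, 0, integer(0))
  best
}

# Independent memoized top-down recursion (R, lazy evaluation order) for the
# same quantity; tractable up to the 60-frame instances where exhaustive
# enumeration is not.
memo_viterbi_score <- function(loglik, logpmf, logsurv) {
  TT <- nrow(loglik); S <- ncol(loglik); D <- nrow(logpmf)
  memo <- array(NA_real_, c(TT, S))
  cum <- apply(loglik, 2, cumsum)
  emsum <- function(a, b, s) cum[b, s] - if (a > 1) cum[a - 1, s] else 0
  # best(t, s): best score of frames t..TT given a (non-first) run of state s
  # starting at t; interior runs use the pmf, the final run its survival
  best <- function(t, s) {
    if (!is.na(memo[t, s])) return(memo[t, s])
    out <- -Inf
    for (d in seq_len(min(D, TT - t + 1))) {
      em <- emsum(t, t + d - 1, s)
      if (t + d - 1 == TT) {
        out <- max(out, em + logsurv[d, s])
      } else {
        out <- max(out, em + logpmf[d, s] + best(t + d, (s %% S) + 1L))
      }
    }
    memo[t, s] <<- out
    out
  }
  # the edge-censored first run is scored by its survival function
  top <- -Inf
  for (s0 in seq_len(S)) for (d in seq_len(min(D, TT))) {
    em <- emsum(1, d, s0)
    if (d == TT) {
      top <- max(top, em + logsurv[d, s0])
    } else {
      top <- max(top, em + logsurv[d, s0] + best(d + 1, (s0 %% S) + 1L))
    }
  }
  top
}

# Score an arbitrary state path under the same semi-Markov conventions.
score_path <- function(path, loglik, logpmf, logsurv) {
  r <- rle(path)
  ends <- cumsum(r$lengths); starts <- c(0L, ends[-length(ends)])
  sc <- 0
  for (i in seq_along(r$values)) {
    s <- r$values[i]; d <- r$lengths[i]
    em <- sum(loglik[(starts[i] + 1):ends[i], s])
    edge <- (i == 1) || (i == length(r$values))
    sc <- sc + em + if (edge) logsurv[d, s] else logpmf[d, s]
  }
  sc
}

# Plug-in histogram mutual information on a fixed binning (test oracle).
histogram_mi <- function(x, y, breaks = 2) {
  xb <- cut(x, breaks = breaks)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  s
}
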