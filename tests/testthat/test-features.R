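test_that("the feature schema has exactly 177 canonical names with Table-style counts", {
  nm <- pcg_feature_names()
  expect_equal(length(nm), 177)
  expect_equal(anyDuplicated(nm), 0L)
  counts <- c(BPM = 1, Dur = 4, Dur_Ratio = 8, MeanEnv_Ratio = 8, RMS = 4,
              RMS_Ratio = 8, ZC = 4, SE = 4, Skewness = 4, Kurtosis = 4,
              PSD = 24, mfcc = 52, SpecCentroid = 4, SpecBandwidth = 4,
              SpecContrast = 16, SpecFlatness = 4, SpecRolloff = 4,
              PolyFeatures = 4, dwt = 16)
  expect_equal(sum(counts), 177)
  expect_equal(sum(grepl("^Dur_[^R]", nm)), 4)
  expect_equal(sum(grepl("^Dur_Ratio_", nm)), 8)
  expect_equal(sum(grepl("^PSD_", nm)), 24)
  expect_equal(sum(grepl("^mfcc", nm)), 52)
  expect_equal(sum(grepl("^SpecContrast", nm)), 16)
  expect_equal(sum(grepl("^dwt", nm)), 16)
  expect_true(all(c("m_BPM", "sd_PSD_Dia_200_250Hz") %in%
                    paste0(rep(c("m_", "sd_"), each = 177), nm)))
})

test_that("duration features follow the published definitions", {
  fs <- fake_segment(list(numeric(480), numeric(800), numeric(400),
                          numeric(2320)))
  v <- duration_features(fs$segment, 4000)
  expect_equal(unname(v["BPM"]), 60 / 1)           # RR = 4000 samples = 1 s
  expect_equal(unname(v["Dur_S1"]), 120)
  expect_equal(unname(v["Dur_Ratio_DiaRR"]), 0.58)
  expect_equal(unname(v["Dur_Ratio_S1S2"]), 1.2)
  rr_ratios <- v[paste0("Dur_Ratio_", c("S1RR", "SysRR", "S2RR", "DiaRR"))]
  expect_equal(sum(rr_ratios), 1)
  fs2 <- fake_segment(list(numeric(2000), numeric(2000), numeric(0),
                           numeric(0)))
  expect_error(duration_features(fs2$segment, 4000), "zero-length")
  fs3 <- fake_segment(list(numeric(500), numeric(500), numeric(500),
                           numeric(500)))
  expect_equal(unname(duration_features(fs3$segment, 4000)["BPM"]), 120)
})

test_that("amplitude features scale and count as defined", {
  set.seed(11)
  w <- rnorm(400)
  fs <- fake_segment(list(w, rnorm(800), w, rnorm(1200)))
  env <- abs(fs$signal) + 0.1
  v <- amplitude_features(fs$segment, fs$signal, env)
  expect_equal(unname(v["RMS_Ratio_S1S2"]), 1) # identical S1 and S2 waveforms
  v2 <- amplitude_features(fs$segment, 2 * fs$signal, env)
  expect_equal(unname(v2[paste0("RMS_", c("S1", "Sys", "S2", "Dia"))]),
               unname(2 * v[paste0("RMS_", c("S1", "Sys", "S2", "Dia"))]))
  expect_equal(v2[grep("RMS_Ratio", names(v2))], v[grep("RMS_Ratio", names(v))])
  alt <- rep(c(1, -1), 100)
  fsa <- fake_segment(list(alt, alt, alt, alt))
  va <- amplitude_features(fsa$segment, fsa$signal, abs(fsa$signal))
  expect_equal(unname(va["ZC_S1"]), length(alt) - 1)
})

test_that("statistical features match their definitions", {
  const <- rep(0.5, 300)
  fs <- fake_segment(list(const, const, const, const))
  v <- statistical_features(fs$segment, fs$signal)
  expect_equal(unname(v["SE_S1"]), 0) # constant: all templates match
  tt <- sin(2 * pi * 5 * seq(0, 1, length.out = 1200))
  fs2 <- fake_segment(list(tt[1:300], tt[301:600], tt[601:900], tt[901:1200]))
  full <- fake_segment(list(tt, tt, tt, tt))
  v2 <- statistical_features(full$segment, full$signal)
  expect_lt(abs(v2[["Skewness_S1"]]), 0.05)
  set.seed(12)
  g <- rnorm(4000)
  fs3 <- fake_segment(list(g, g, g, g))
  v3 <- statistical_features(fs3$segment, fs3$signal)
  expect_lt(abs(v3[["Kurtosis_S1"]]), 3 * sqrt(24 / 4000) + 0.1)
})

test_that("PSD band features localize energy and conserve band power", {
  t <- seq_len(2000) / 4000
  tone <- sin(2 * pi * 150 * t)
  fs <- fake_segment(list(numeric(400), numeric(800), numeric(400), tone * 1))
  v <- psd_band_features(fs$segment, fs$signal)
  dia <- v[grep("^PSD_Dia_", names(v))]
  expect_equal(names(which.max(dia)), "PSD_Dia_140_160Hz")
  expect_true(all(v[grep("^PSD_Sys_", names(v))] == 0)) # silent systole
  # band powers tile total 25-400 Hz power (same STFT, direct integration)
  set.seed(13)
  wn <- rnorm(2000)
  fsn <- fake_segment(list(numeric(400), wn, numeric(400), wn))
  vn <- psd_band_features(fsn$segment, fsn$signal)
  st <- pcgphase:::stft_power(wn, 4000)
  total <- mean(colSums(st$power[st$freq >= 25 & st$freq <= 400, ]))
  expect_lt(abs(sum(vn[grep("^PSD_Sys_", names(vn))]) - total) / total, 0.02)
})

test_that("MFCCs respond to gain only through the energy coefficient", {
  set.seed(14)
  w <- rnorm(1000)
  fs <- fake_segment(list(w, w, rnorm(600), rnorm(1400)))
  v <- mfcc_features(fs$segment, fs$signal)
  expect_equal(length(v), 52)
  # identical waveforms in two states give identical coefficients
  expect_equal(unname(v[paste0("mfcc", 1:13, "_S1")]),
               unname(v[paste0("mfcc", 1:13, "_Sys")]))
  v2 <- mfcc_features(fs$segment, 2 * fs$signal)
  d <- abs(v2 - v)
  expect_gt(d[["mfcc1_S1"]], 0.1)
  expect_true(all(d[grep("^mfcc(1[0-3]|[2-9])_", names(d))] < 1e-6))
})

test_that("spectral shape features behave at their limiting cases", {
  t <- seq_len(4000) / 4000
  tone <- sin(2 * pi * 100 * t)
  fs <- fake_segment(list(tone, tone, tone, tone))
  v <- spectral_shape_features(fs$segment, fs$signal)
  bin <- 4000 / 256
  expect_lt(abs(v[["SpecCentroid_S1"]] - 100), bin)
  expect_lt(v[["SpecBandwidth_S1"]], bin)
  expect_lt(v[["SpecFlatness_S1"]], 0.1)
  set.seed(15)
  wn <- rnorm(8000)
  fsn <- fake_segment(list(wn[1:2000], wn[2001:4000], wn[4001:6000],
                           wn[6001:8000]))
  vn <- spectral_shape_features(fsn$segment, fsn$signal)
  expect_gt(vn[["SpecFlatness_S1"]], 0.9)
  # spectrum with power growing in frequency has positive spectral slope
  ramp <- stats::filter(rnorm(8000), c(1, -0.9), method = "convolution")
  ramp <- ramp[!is.na(ramp)]
  fsr <- fake_segment(list(ramp[1:1500], ramp[1501:3000], ramp[3001:4500],
                           ramp[4501:6000]))
  vr <- spectral_shape_features(fsr$segment, fsr$signal)
  expect_gt(vr[["PolyFeatures_S1"]], 0)
})

test_that("wavelet features come from an orthogonal decomposition", {
  set.seed(16)
  x <- rnorm(512)
  dec <- dwt_db4(x, 4)
  energy <- sum(vapply(dec$details, function(d) sum(d^2), numeric(1))) +
    sum(dec$approx^2)
  expect_equal(energy, sum(x^2), tolerance = 1e-6) # Parseval, orthogonal DWT
  z <- numeric(300)
  fs <- fake_segment(list(z, z, z, z))
  v <- dwt_features(fs$segment, fs$signal)
  expect_equal(length(v), 16)
  expect_true(all(v == log(1e-12)))
})

test_that("the full extractor emits 177 finite named values deterministically", {
  fx <- clean_recording()
  s <- fx$segs[[4]]
  v1 <- extract_segment_features(s, fx$rec$samples, fx$env)
  v2 <- extract_segment_features(s, fx$rec$samples, fx$env)
  expect_equal(length(v1), 177)
  expect_identical(names(v1), pcg_feature_names())
  expect_true(all(is.finite(v1)))
  expect_false(attr(v1, "flagged"))
  expect_identical(as.numeric(v1), as.numeric(v2))
  # whole-sample time shift: durations identical, spectra nearly so
  s2 <- s
  shift <- 4000L
  s2$rr_start <- s$rr_start + shift; s2$rr_end <- s$rr_end + shift
  s2$intervals <- lapply(s$intervals, `+`, shift)
  xs <- c(numeric(shift), fx$rec$samples)
  es <- c(numeric(shift) + fx$env[1], fx$env)
  v3 <- extract_segment_features(s2, xs, es)
  expect_equal(unname(v3["BPM"]), unname(v1["BPM"]))
  spec_cols <- grep("^(PSD|mfcc|Spec|Poly|dwt)", names(v1))
  expect_equal(as.numeric(v3[spec_cols]), as.numeric(v1[spec_cols]),
               tolerance = 1e-6)
})

test_that("cyclic windowing averages with wrap-around and equal representation", {
  X <- matrix(rep(5, 6), ncol = 1, dimnames = list(NULL, "f"))
  W <- cyclic_window_aggregate(X)
  expect_true(all(W[, "m_f"] == 5) && all(W[, "sd_f"] == 0))
  # n = 6: every cyclic window covers all segments
  X2 <- matrix(1:6, ncol = 1, dimnames = list(NULL, "f"))
  W2 <- cyclic_window_aggregate(X2)
  expect_true(all(W2[, "m_f"] == 3.5))
  # n = 12, values 1..12: window at position 1 covers indices 1..6
  X3 <- matrix(1:12, ncol = 1, dimnames = list(NULL, "f"))
  W3 <- cyclic_window_aggregate(X3)
  expect_equal(unname(W3[1, "m_f"]), mean(1:6))
  expect_equal(unname(W3[12, "m_f"]), mean(c(12, 1:5))) # wraps cyclically
  # participation count equals min(n, 6)
  for (n in c(3, 6, 12)) {
    counts <- integer(n)
    w <- min(n, 6)
    for (i in seq_len(n)) {
      idx <- ((i - 1 + 0:(w - 1)) %% n) + 1
      counts[idx] <- counts[idx] + 1
    }
    expect_true(all(counts == w))
  }
  expect_equal(ncol(cyclic_window_aggregate(matrix(1:4, 2,
    dimnames = list(NULL, c("a", "b"))))), 4)
  expect_error(cyclic_window_aggregate(matrix(numeric(0), 0, 1)), "empty")
})
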