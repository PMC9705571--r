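test_that("mutual information tracks dependence and vanishes under independence", {
  set.seed(21)
  y <- rep(c(0, 1), each = 250)
  # feature identical to the balanced label: MI = H(Y) = ln 2
  x_id <- y + rnorm(500, 0, 1e-6)
  expect_lt(abs(mutual_information(x_id, y) - log(2)), 0.05)
  x_ind <- rnorm(1000)
  y_ind <- rep(c(0, 1), 500)
  expect_lt(mutual_information(x_ind, y_ind), 0.05)
  # informative beats uninformative, in agreement with a histogram oracle
  x_sig <- y + rnorm(500, 0, 0.3)
  x_nse <- rnorm(500)
  expect_gt(mutual_information(x_sig, y), mutual_information(x_nse, y))
  expect_gt(histogram_mi(x_sig, y), histogram_mi(x_nse, y))
  expect_error(mutual_information(rnorm(10), rep(1, 10)), "single class")
})

test_that("MI feature selection returns the top-k deterministically", {
  set.seed(22)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 50), n, 50,
              dimnames = list(NULL, paste0("f", 1:50)))
  X[, "f7"] <- y # a feature equal to the label
  sel <- select_features(X, y, k = 10, seed = 5)
  expect_equal(sel[1], "f7")
  expect_equal(length(select_features(X, y, k = 40, seed = 5)), 40)
  # identical call is bit-reproducible; shuffling rows cannot displace a
  # perfectly informative feature from the top
  expect_identical(as.character(select_features(X, y, k = 10, seed = 5)),
                   as.character(sel))
  perm <- sample(n)
  sel2 <- select_features(X[perm, ], y[perm], k = 10, seed = 5)
  expect_equal(sel2[1], "f7")
  expect_error(select_features(X, y, k = 60), "exceeds")
})

test_that("folds are subject-wise and device-stratified", {
  meta <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:37), each = 2),
    device = rep(c(rep("setup1", 21), rep("setup2", 16)), each = 2),
    phase = rep(0:1, 37))
  folds <- make_folds(meta, 10, seed = 3)
  expect_equal(length(folds), 37)
  per_dev <- table(folds, rep(c(rep("setup1", 21), rep("setup2", 16)),
                              1)[match(names(folds),
                                       sprintf("S%02d", 1:37))])
  expect_true(all(per_dev[, "setup1"] %in% 2:3))
  expect_true(all(per_dev[, "setup2"] %in% 1:2))
  # both recordings of a subject share the fold by construction
  f_rec <- folds[meta$subject_id]
  expect_true(all(tapply(f_rec, meta$subject_id,
                         function(v) length(unique(v))) == 1))
  expect_identical(folds, make_folds(meta, 10, seed = 3))
  expect_false(identical(folds, make_folds(meta, 10, seed = 4)))
  expect_error(make_folds(meta[1:6, ], 10), "fewer subjects")
})

test_that("mis-segmented subjects leave training sets but not test sets", {
  qc <- data.frame(subject_id = c("A", "A", "B", "C"),
                   recording_qc = c("ok", "mis_segmented", "ok", "ok"))
  expect_equal(exclude_missegmented_from_training(c("A", "B", "C"), qc),
               c("B", "C"))
  expect_equal(exclude_missegmented_from_training(c("B", "C"), NULL),
               c("B", "C"))
})

test_that("recording-level majority vote follows threshold and tie rules", {
  p <- c(rep(0.9, 7), rep(0.1, 3))
  expect_equal(predict_recording(p)$class, 1L)
  tie_hi <- c(rep(0.9, 5), rep(0.2, 5)) # mean 0.55 breaks toward 1
  expect_equal(predict_recording(tie_hi)$class, 1L)
  tie_lo <- c(rep(0.6, 5), rep(0.1, 5)) # mean 0.35 breaks toward 0
  expect_equal(predict_recording(tie_lo)$class, 0L)
  expect_equal(predict_recording(rep(0.51, 4))$class, 1L)
  expect_equal(predict_recording(rep(0.5, 3))$class, 1L) # 0.5 votes class 1
  expect_error(predict_recording(numeric(0)), "empty")
})

test_that("classification metrics reproduce the published formulas", {
  m <- classification_metrics(c(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(unname(m), c(0.7, 0.75, 0.6, 2 * 0.75 * 0.6 / 1.35))
  perfect <- classification_metrics(c(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_true(all(perfect == 1))
  und <- classification_metrics(c(TP = 0, FP = 0, TN = 3, FN = 2))
  expect_true(is.na(und["precision"]))
  # exhaustive small-count check against direct arithmetic
  for (tp in 0:3) for (fp in 0:3) for (tn in 0:3) for (fn in 0:3) {
    if (tp + fp + tn + fn == 0) next
    m <- classification_metrics(c(TP = tp, FP = fp, TN = tn, FN = fn))
    expect_equal(unname(m["accuracy"]), (tp + tn) / (tp + fp + tn + fn))
    if (tp + fp > 0) expect_equal(unname(m["precision"]), tp / (tp + fp))
    if (tp + fn > 0) expect_equal(unname(m["recall"]), tp / (tp + fn))
    if (!anyNA(m[c("precision", "recall")]) && sum(m[2:3]) > 0) {
      expect_equal(unname(m["f1"]),
                   2 / (1 / m[["precision"]] + 1 / m[["recall"]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("t-based confidence intervals match the t quantile", {
  ci <- tdist_ci(rep(0.7, 5))
  expect_equal(unname(ci[c("lo", "hi")]), c(0.7, 0.7))
  set.seed(23)
  v <- rnorm(10, 0.72, 0.15)
  ci2 <- tdist_ci(v)
  hw <- stats::qt(0.975, 9) * sd(v) / sqrt(10)
  expect_equal(unname(ci2["hi"] - ci2["mean"]), hw)
  expect_equal(unname(ci2["mean"] - ci2["lo"]), hw)
  expect_true(ci2["lo"] <= ci2["mean"] && ci2["mean"] <= ci2["hi"])
  # half-width at n=10, SD 0.15 is 2.262 * 0.15 / sqrt(10)
  expect_equal(stats::qt(0.975, 9) * 0.15 / sqrt(10), 0.1073, tolerance = 1e-3)
  expect_error(tdist_ci(0.5), "at least 2")
})

test_that("McNemar p-values agree with exhaustive binomial enumeration", {
  expect_equal(mcnemar_pvalue(5, 5), 1)
  expect_equal(mcnemar_pvalue(10, 0), 2 * 0.5^10)
  expect_equal(mcnemar_pvalue(0, 0), 1)
  # oracle: two-sided exact binomial tail sums by direct enumeration
  for (b in 0:12) for (cc in 0:(12 - b)) {
    n <- b + cc
    if (n == 0) next
    probs <- vapply(0:n, function(k) choose(n, k) * 0.5^n, numeric(1))
    p_oracle <- if (b == cc) 1 else
      min(1, sum(probs[probs <= probs[b + 1] + 1e-12]))
    expect_equal(mcnemar_pvalue(b, cc), p_oracle, tolerance = 1e-12,
                 info = sprintf("b=%d c=%d", b, cc))
  }
  # identical predictions give p = 1 through the vector interface
  truth <- rep(c(0, 1), 10)
  pr <- rep(c(0, 1, 1, 0), 5)
  expect_equal(mcnemar_test(pr, pr, truth), 1)
})

test_that("random scores give chance-level ROC AUC", {
  set.seed(24)
  auc <- replicate(20, {
    y <- rep(c(0, 1), each = 100)
    pcgphase:::rank_auc(y, runif(200))
  })
  expect_lt(abs(mean(auc) - 0.5), 0.05)
  expect_true(all(abs(auc - 0.5) < 0.12))
  expect_equal(pcgphase:::rank_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
})

test_that("the expert baseline reproduces the packaged assessment table", {
  eb <- expert_baseline()
  expect_equal(unname(round(eb$per_expert, 2)), c(0.58, 0.67, 0.25))
  expect_equal(eb$overall, 0.5)
  expect_equal(eb$per_pcg[4], 1)
  tab <- read.csv(system.file("extdata", "expert_classification.csv",
                              package = "pcgphase"))
  wrong <- tab
  for (e in c("expert1", "expert2", "expert3")) wrong[[e]] <- 1 - tab$class
  eb2 <- expert_baseline(wrong)
  expect_true(all(eb2$per_expert == 0) && eb2$overall == 0)
  bad <- tab; bad$expert1[1] <- 2
  expect_error(expert_baseline(bad), "binary")
})

test_that("every probabilistic classifier separates an easy problem", {
  set.seed(25)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[, 1] <- X[, 1] + 2.5 * y
  Xte <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  yte <- rep(c(0, 1), each = 20)
  Xte[, 1] <- Xte[, 1] + 2.5 * yte
  for (kind in pcg_classifiers()) {
    mdl <- fit_classifier(kind, X, y, seed = 1)
    p <- mdl$predict(Xte)
    expect_true(all(p >= 0 & p <= 1), info = kind)
    expect_gt(mean((p >= 0.5) == yte), 0.8)
  }
})
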