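# Cross-validated evaluation: subject-wise stratified folds, MI feature
# selection per training fold, recording-level majority voting, Table-style
# metric aggregation with t-based confidence intervals, and McNemar model
# comparison.

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = harmonic mean of precision and recall. A metric
#' with a zero denominator is reported as `NA` (undefined).
#'
#' @param counts Named list or vector with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  tot <- tp + tn + fp + fn
  acc <- if (tot > 0) (tp + tn) / tot else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Student-t 95% confidence interval over fold values
#'
#' @param values Per-fold metric values (>= 2, NAs dropped).
#' @param level Confidence level (default 0.95).
#' @return Named vector `mean`, `sd`, `lo`, `hi` with
#'   `mean +/- t(1-(1-level)/2, n-1) * sd / sqrt(n)`.
#' @export
tdist_ci <- function(values, level = 0.95) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 2) stop("need at least 2 fold values")
  m <- mean(v); s <- stats::sd(v)
  hw <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  c(mean = m, sd = s, lo = m - hw, hi = m + hw)
}

#' McNemar test between two classifiers' predictions
#'
#' Operates on the discordant pairs: `b` cases where A is right and B wrong,
#' `c` the reverse. Exact two-sided binomial p for `b + c < 25`, else the
#' continuity-corrected chi-square. `b + c = 0` gives p = 1 by convention.
#'
#' @param preds_a,preds_b Equal-length 0/1 prediction vectors.
#' @param truth True 0/1 labels.
#' @param exact_limit Discordant-pair count below which the exact test is used.
#' @return Two-sided p-value.
#' @export
mcnemar_test <- function(preds_a, preds_b, truth, exact_limit = 25) {
  stopifnot(length(preds_a) == length(preds_b),
            length(preds_a) == length(truth))
  b <- sum(preds_a == truth & preds_b != truth)
  cc <- sum(preds_a != truth & preds_b == truth)
  mcnemar_pvalue(b, cc, exact_limit)
}

#' @rdname mcnemar_test
#' @param b,c Discordant-pair counts.
#' @export
mcnemar_pvalue <- function(b, c, exact_limit = 25) {
  n <- b + c
  if (n == 0) return(1)
  if (n < exact_limit) {
    lo <- min(b, c)
    p <- 2 * stats::pbinom(lo, n, 0.5)
    if (b == c) p <- 1 # both tails coincide
    return(min(1, p))
  }
  x2 <- (abs(b - c) - 1)^2 / n
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Recording-level decision by majority vote over segments
#'
#' Each segment is classed by its probability against the threshold; the
#' recording's class is the majority. Ties are broken by the mean segment
#' probability against the threshold, and class 0 if that too is tied. The
#' recording's ROC score is the mean segment probability.
#'
#' @param probs Segment-level probabilities of class 1 (>= 1 value).
#' @param threshold Decision threshold (default 0.5).
#' @return List with `class` (0/1) and `score` (mean probability).
#' @export
predict_recording <- function(probs, threshold = 0.5) {
  if (length(probs) == 0) stop("empty segment prediction list")
  votes1 <- sum(probs >= threshold)
  votes0 <- length(probs) - votes1
  score <- mean(probs)
  cls <- if (votes1 > votes0) 1L
         else if (votes1 < votes0) 0L
         else if (score > threshold) 1L else 0L
  list(class = cls, score = score)
}

#' Subject-wise stratified fold assignment
#'
#' All recordings of a subject share a fold; folds are stratified with
#' respect to the acquisition device by assigning each device's subjects
#' round-robin after a seeded shuffle (per-device fold counts differ by at
#' most one).
#'
#' @param meta Data.frame with `subject_id` and `device` (one row per
#'   recording or per subject).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Named integer vector: fold per subject.
#' @export
make_folds <- function(meta, n_folds = 10, seed = 0) {
  subj <- unique(meta[, c("subject_id", "device")])
  if (nrow(subj) < n_folds) stop("fewer subjects than folds")
  fold <- integer(nrow(subj))
  names(fold) <- subj$subject_id
  with_seed(seed, {
    offset <- 0L
    for (dev in sort(unique(subj$device))) {
      ids <- sample(subj$subject_id[subj$device == dev])
      fold[ids] <- ((seq_along(ids) - 1L + offset) %% n_folds) + 1L
      offset <- offset + length(ids)
    }
  })
  fold
}

#' Remove mis-segmented subjects from a training set
#'
#' Subjects having any recording flagged `mis_segmented` are excluded from
#' training folds only; they are still scored when they fall in a test fold.
#'
#' @param train_subjects Character vector of training-fold subjects.
#' @param qc Data.frame with `subject_id` and `recording_qc`.
#' @return The reduced subject vector.
#' @export
exclude_missegmented_from_training <- function(train_subjects, qc) {
  if (is.null(qc) || nrow(qc) == 0) return(train_subjects)
  bad <- unique(qc$subject_id[qc$recording_qc == "mis_segmented"])
  setdiff(train_subjects, bad)
}

rank_auc <- function(truth, score) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validated evaluation of the classifier suite
#'
#' For each fold: mis-segmented subjects are dropped from training, the top
#' `n_features` features by average mutual information are selected on
#' training rows only, every classifier is fitted on the selected training
#' segments and scored on the test recordings via segment-majority voting.
#' Metrics are aggregated as mean, SD, and t-based 95% CI across folds; a
#' McNemar p-value matrix compares the pooled recording-level predictions.
#'
#' @param features Feature table from [featurize_recording()] rows bound
#'   together: metadata columns `recording_id`, `subject_id`, `device`,
#'   `phase` plus the windowed feature columns.
#' @param classifiers Subset of [pcg_classifiers()].
#' @param n_folds Number of subject-wise folds.
#' @param n_features Features selected per fold (default 40).
#' @param seed Master seed (folds, selection, classifier fits).
#' @param qc Optional recording-QC table (`subject_id`, `recording_qc`).
#' @param threshold Segment decision threshold.
#' @return An object of class `pcg_cv_report`.
#' @export
cross_validate <- function(features, classifiers = pcg_classifiers(),
                           n_folds = 10, n_features = 40, seed = 0,
                           qc = NULL, threshold = 0.5) {
  meta_cols <- c("recording_id", "subject_id", "device", "phase", "segment")
  stopifnot(all(meta_cols %in% names(features)))
  fcols <- setdiff(names(features), meta_cols)
  folds <- make_folds(features, n_folds, seed)
  rec_meta <- unique(features[, c("recording_id", "subject_id", "phase")])

  fold_rows <- list()
  sel_by_fold <- list()
  mi_by_fold <- list()
  audit <- list()
  rec_pred <- list() # pooled recording predictions per classifier
  rec_truth <- list()
  for (f in seq_len(n_folds)) {
    test_subj <- names(folds)[folds == f]
    train_subj <- setdiff(names(folds), test_subj)
    train_subj <- exclude_missegmented_from_training(train_subj, qc)
    tr <- features[features$subject_id %in% train_subj, , drop = FALSE]
    te <- features[features$subject_id %in% test_subj, , drop = FALSE]
    if (nrow(te) == 0) next
    sel <- select_features(tr[, fcols], tr$phase, k = n_features,
                           seed = child_seed(seed, f))
    sel_by_fold[[f]] <- as.character(sel)
    mi_by_fold[[f]] <- attr(sel, "mi")
    audit[[f]] <- list(train_subjects = sort(unique(tr$subject_id)),
                       test_subjects = sort(test_subj),
                       selection_rows = nrow(tr))
    Xtr <- tr[, sel_by_fold[[f]], drop = FALSE]
    Xte <- te[, sel_by_fold[[f]], drop = FALSE]
    te_recs <- unique(te$recording_id)
    te_truth <- rec_meta$phase[match(te_recs, rec_meta$recording_id)]
    for (kind in classifiers) {
      model <- fit_classifier(kind, Xtr, tr$phase,
                              seed = child_seed(seed, 100 + f))
      p_seg <- model$predict(Xte)
      pr <- vapply(te_recs, function(rid)
        unlist(predict_recording(p_seg[te$recording_id == rid], threshold)),
        numeric(2))
      cls <- as.integer(pr["class", ]); score <- pr["score", ]
      counts <- c(TP = sum(cls == 1 & te_truth == 1),
                  FP = sum(cls == 1 & te_truth == 0),
                  TN = sum(cls == 0 & te_truth == 0),
                  FN = sum(cls == 0 & te_truth == 1))
      met <- classification_metrics(counts)
      fold_rows[[length(fold_rows) + 1]] <- data.frame(
        fold = f, classifier = kind, t(met),
        roc_auc = rank_auc(te_truth, score), t(counts))
      rec_pred[[kind]] <- rbind(rec_pred[[kind]],
                                data.frame(recording_id = te_recs, class = cls))
      if (kind == classifiers[1])
        rec_truth[[f]] <- data.frame(recording_id = te_recs, phase = te_truth)
    }
  }
  fold_metrics <- do.call(rbind, fold_rows)
  metric_names <- c("accuracy", "precision", "recall", "f1", "roc_auc")
  summary_tab <- do.call(rbind, lapply(classifiers, function(kind) {
    rows <- fold_metrics[fold_metrics$classifier == kind, ]
    do.call(rbind, lapply(metric_names, function(mn) {
      ci <- tdist_ci(rows[[mn]])
      data.frame(classifier = kind, metric = mn, t(ci))
    }))
  }))
  truth_tab <- do.call(rbind, rec_truth)
  # McNemar matrix over pooled predictions (each recording scored once)
  K <- length(classifiers)
  mcn <- matrix(NA_real_, K, K, dimnames = list(classifiers, classifiers))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    a <- rec_pred[[classifiers[i]]]
    b <- rec_pred[[classifiers[j]]]
    ord <- match(truth_tab$recording_id, a$recording_id)
    mcn[i, j] <- mcnemar_test(a$class[ord],
                              b$class[match(truth_tab$recording_id,
                                            b$recording_id)],
                              truth_tab$phase)
  }
  # MI ranking averaged across folds (Table-7-style report)
  mi_avg <- Reduce(`+`, mi_by_fold) / length(mi_by_fold)
  mi_rank <- data.frame(feature = names(sort(mi_avg, decreasing = TRUE)),
                        mi = as.numeric(sort(mi_avg, decreasing = TRUE)))
  structure(list(fold_metrics = fold_metrics, summary = summary_tab,
                 mcnemar = mcn,
                 mi_ranking = utils::head(mi_rank, n_features),
                 selected_features = sel_by_fold,
                 predictions = rec_pred, truth = truth_tab,
                 audit = audit, folds = folds, n_folds = n_folds, seed = seed),
            class = "pcg_cv_report")
}

#' @export
print.pcg_cv_report <- function(x, digits = 2, ...) {
  cat(sprintf("<pcg_cv_report> %d-fold subject-wise cross-validation\n",
              x$n_folds))
  s <- x$summary
  wide <- stats::reshape(
    s[, c("classifier", "metric", "mean")], idvar = "classifier",
    timevar = "metric", direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  ord <- order(-wide$accuracy)
  fmt <- function(cl, mn) {
    r <- s[s$classifier == cl & s$metric == mn, ]
    sprintf("%.2f (%.2f; %.2f-%.2f)", r$mean, r$sd, r$lo, r$hi)
  }
  for (cl in wide$classifier[ord]) {
    cat(sprintf("  %-5s acc %s  f1 %s  auc %s\n", cl,
                fmt(cl, "accuracy"), fmt(cl, "f1"), fmt(cl, "roc_auc")))
  }
  invisible(x)
}

#' @export
summary.pcg_cv_report <- function(object, ...) {
  print(object)
  cat("\nTop features by average mutual information:\n")
  print(utils::head(object$mi_ranking, 10), row.names = FALSE)
  invisible(object$summary)
}

#' Mean cross-validated metric for one classifier
#'
#' @param report A `pcg_cv_report`.
#' @param classifier Classifier code.
#' @param metric Metric name (default `"accuracy"`).
#' @return The across-fold mean.
#' @export
cv_metric <- function(report, classifier, metric = "accuracy") {
  s <- report$summary
  s$mean[s$classifier == classifier & s$metric == metric]
}

#' Cardiologist baseline from an expert-classification table
#'
#' @param table Data.frame with columns `pcg`, `class`, and one 0/1 column
#'   per expert; defaults to the packaged expert-classification fixture.
#' @return List with `per_expert` (accuracy per expert), `per_pcg` (fraction
#'   of experts correct per recording), and `overall` (mean of the per-expert
#'   accuracies).
#' @export
expert_baseline <- function(table = NULL) {
  if (is.null(table)) {
    table <- utils::read.csv(system.file("extdata",
                                         "expert_classification.csv",
                                         package = "pcgphase"))
  }
  expert_cols <- setdiff(names(table), c("pcg", "class"))
  vals <- as.matrix(table[, expert_cols])
  if (!all(vals %in% c(0, 1)) || !all(table$class %in% c(0, 1)))
    stop("expert table entries must be binary")
  correct <- vals == table$class
  per_expert <- colMeans(correct)
  per_pcg <- rowMeans(correct)
  list(per_expert = per_expert, per_pcg = per_pcg,
       overall = mean(per_expert))
}
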