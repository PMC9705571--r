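# The ten probabilistic classifiers of the evaluation suite. Each returns a
# fitted object plus a predict function giving P(class 1). Inputs are
# standardized with training-set statistics (harmless for trees, essential
# for the distance- and margin-based models given the features' mixed units).

#' Names of the ten classifiers in the evaluation suite
#' @return Character vector of classifier codes.
#' @export
pcg_classifiers <- function() {
  c("LR", "LGBM", "SVC", "RF", "DT", "GB", "XGB", "KN", "SGD", "GNB")
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(apply = function(Z) sweep(sweep(as.matrix(Z), 2, mu), 2, sg, "/"))
}

xgb_fit <- function(X, y, seed, params, nrounds) {
  dtr <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  xgboost::xgb.train(params = c(params, list(objective = "binary:logistic",
                                             nthread = 1, seed = seed)),
                     data = dtr, nrounds = nrounds, verbose = 0)
}

# Logistic regression by stochastic gradient descent (log loss, constant
# step with 1/sqrt(t) decay, seeded shuffles).
sgd_logistic <- function(X, y, epochs = 50, eta0 = 0.05, seed = 0) {
  X1 <- cbind(1, X)
  w <- numeric(ncol(X1))
  n <- nrow(X1)
  with_seed(seed, {
    t <- 0
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        p <- stats::plogis(sum(X1[i, ] * w))
        w <- w + (eta0 / sqrt(t)) * (y[i] - p) * X1[i, ]
      }
    }
  })
  w
}

#' Fit one classifier of the suite
#'
#' @param kind One of [pcg_classifiers()]: logistic regression (LR),
#'   leaf-wise histogram gradient boosting (LGBM), support-vector classifier
#'   with probability outputs (SVC), random forest (RF), decision tree (DT),
#'   gradient boosting (GB), extreme gradient boosting (XGB), k-nearest
#'   neighbours (KN), stochastic-gradient linear model (SGD), Gaussian naive
#'   Bayes (GNB).
#' @param X Training feature matrix/data.frame.
#' @param y Binary outcome (0/1) per row.
#' @param seed Integer seed fixing any stochastic element of the fit.
#' @return A list with `kind` and `predict(newX)` returning P(class 1).
#' @export
fit_classifier <- function(kind, X, y, seed = 0) {
  X <- as.matrix(X)
  y <- as.integer(y)
  std <- standardizer(X)
  Xs <- std$apply(X)
  yf <- factor(y, levels = c(0, 1))
  pred <- switch(
    kind,
    LR = {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, Xs), y,
                                             family = stats::binomial()))
      w <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      function(Z) as.numeric(stats::plogis(cbind(1, std$apply(Z)) %*% w))
    },
    DT = {
      df <- data.frame(y = yf, Xs)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      function(Z) stats::predict(fit, data.frame(std$apply(Z)), type = "prob")[, "1"]
    },
    RF = {
      fit <- with_seed(seed, randomForest::randomForest(Xs, yf, ntree = 500))
      function(Z) stats::predict(fit, std$apply(Z), type = "prob")[, "1"]
    },
    GB = {
      fit <- xgb_fit(Xs, y, seed, list(eta = 0.1, max_depth = 3, subsample = 1),
                     nrounds = 100)
      function(Z) stats::predict(fit, xgboost::xgb.DMatrix(std$apply(Z)))
    },
    XGB = {
      fit <- xgb_fit(Xs, y, seed, list(eta = 0.3, max_depth = 6), nrounds = 100)
      function(Z) stats::predict(fit, xgboost::xgb.DMatrix(std$apply(Z)))
    },
    LGBM = {
      fit <- xgb_fit(Xs, y, seed,
                     list(eta = 0.1, max_depth = 0, tree_method = "hist",
                          grow_policy = "lossguide", max_leaves = 31),
                     nrounds = 100)
      function(Z) stats::predict(fit, xgboost::xgb.DMatrix(std$apply(Z)))
    },
    SVC = {
      fit <- with_seed(seed, e1071::svm(Xs, yf, probability = TRUE))
      function(Z) {
        p <- stats::predict(fit, std$apply(Z), probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }
    },
    KN = {
      fit <- caret::knn3(Xs, yf, k = 5)
      function(Z) stats::predict(fit, std$apply(Z), type = "prob")[, "1"]
    },
    GNB = {
      fit <- e1071::naiveBayes(Xs, yf)
      function(Z) stats::predict(fit, std$apply(Z), type = "raw")[, "1"]
    },
    SGD = {
      w <- sgd_logistic(Xs, y, seed = seed)
      function(Z) as.numeric(stats::plogis(cbind(1, std$apply(Z)) %*% w))
    },
    stop("unknown classifier kind: ", kind)
  )
  list(kind = kind, predict = pred)
}
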