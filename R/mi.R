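# Mutual information between a continuous feature and the discrete outcome,
# and MI-based filter feature selection.

#' Mutual information between a feature and a binary label
#'
#' Nearest-neighbour estimator for a continuous variable against a discrete
#' label (the Kozachenko-Leonenko construction adapted to the mixed case):
#' for each point, the distance to its k-th neighbour within the same class
#' sets a radius, and the number of points of any class inside that radius
#' enters a digamma average. Non-negative by clipping; zero in expectation for
#' independent variables.
#'
#' @param x Numeric feature vector.
#' @param y Class labels (two or more classes, >= 2 samples per class).
#' @param k Number of neighbours (default 3).
#' @param jitter_sd Relative amplitude of the deterministic-seeded tie-breaking
#'   noise.
#' @param seed Seed for the tie-breaking noise.
#' @return MI estimate in nats.
#' @export
mutual_information <- function(x, y, k = 3, jitter_sd = 1e-10, seed = 0) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("labels contain a single class")
  n <- length(x)
  stopifnot(length(y) == n)
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  scale <- stats::sd(x)
  if (!is.finite(scale) || scale == 0) return(0)
  x <- x + with_seed(seed, stats::rnorm(n, 0, jitter_sd * scale))
  kk <- pmin(k, table(y)[y] - 1)
  r <- numeric(n)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    ord <- order(x[idx])
    xs <- x[idx][ord]
    m <- length(xs)
    kc <- min(k, m - 1)
    # kth-NN distance in 1-d: minimum over the k+1 contiguous windows of
    # size kc+1 containing each point, of the window's wider side
    rs <- rep(Inf, m)
    for (j in 0:kc) {
      ii <- seq_len(m)
      right <- ifelse(ii + j <= m, xs[pmin(ii + j, m)] - xs, Inf)
      left <- ifelse(ii - (kc - j) >= 1, xs - xs[pmax(ii - (kc - j), 1)], Inf)
      rs <- pmin(rs, pmax(right, left))
    }
    r[idx[ord]] <- rs
  }
  xs_all <- sort(x)
  lo_ct <- findInterval(x - r, xs_all, left.open = TRUE)
  hi_ct <- findInterval(x + r, xs_all)
  m_i <- pmax(hi_ct - lo_ct - 1, 1) # neighbours within radius, excluding self
  n_y <- as.numeric(table(y)[y])
  mi <- digamma(n) + mean(digamma(kk)) - mean(digamma(n_y)) - mean(digamma(m_i))
  max(mi, 0)
}

# Class-stratified assignment of rows into `nf` subfolds, seeded.
stratified_subfolds <- function(y, nf, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(nf), length(idx))
    }
  })
  fold
}

#' Select the top-k features by average mutual information
#'
#' The training rows are divided into five class-stratified subfolds; the MI
#' of every feature with the outcome is computed on each subfold and averaged;
#' the k features with the highest average MI are returned in descending
#' order. Deterministic given the seed.
#'
#' @param X Numeric matrix or data.frame of features (training rows only).
#' @param y Binary outcome for those rows.
#' @param k Number of features to keep (default 40).
#' @param subfolds Number of stratified subfolds (default 5).
#' @param seed Seed controlling subfold assignment and MI tie-breaking.
#' @return Character vector of `k` feature names, descending by average MI,
#'   with the per-feature average MI attached as `attr(, "mi")`.
#' @export
select_features <- function(X, y, k = 40, subfolds = 5, seed = 0) {
  X <- as.matrix(X)
  if (k > ncol(X)) stop("k exceeds the number of features")
  if (min(table(y)) < subfolds) stop("need >= subfolds samples per class")
  fold <- stratified_subfolds(y, subfolds, seed)
  mi_mat <- matrix(0, subfolds, ncol(X))
  for (f in seq_len(subfolds)) {
    rows <- fold == f
    yy <- y[rows]
    mi_mat[f, ] <- vapply(seq_len(ncol(X)), function(j)
      mutual_information(X[rows, j], yy, seed = child_seed(seed, j)),
      numeric(1))
  }
  avg <- colMeans(mi_mat)
  names(avg) <- colnames(X)
  ord <- order(avg, decreasing = TRUE)
  sel <- colnames(X)[ord[seq_len(k)]]
  attr(sel, "mi") <- avg
  sel
}
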