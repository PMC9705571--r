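# Daubechies-4 discrete wavelet transform (orthonormal, periodic boundary).
# The scaling filter is the standard 4-tap D4; the wavelet filter is its
# quadrature mirror. Signals are zero-padded to a multiple of 2^levels so the
# pyramid stays orthogonal (Parseval holds on the padded vector).

db4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)
  list(h = h, g = g)
}

dwt_step_db4 <- function(x) {
  f <- db4_filters()
  n <- length(x)
  half <- n %/% 2
  idx <- outer((seq_len(half) - 1) * 2, 0:3, "+") %% n + 1
  xm <- matrix(x[idx], nrow = half)
  list(approx = as.numeric(xm %*% f$h), detail = as.numeric(xm %*% f$g))
}

#' Multi-level Daubechies-4 wavelet decomposition
#'
#' @param x Numeric signal; zero-padded to a multiple of `2^levels`.
#' @param levels Number of decomposition levels (default 4).
#' @return List with `details` (list of detail-coefficient vectors, level 1 =
#'   finest) and `approx` (coarsest approximation coefficients).
#' @export
dwt_db4 <- function(x, levels = 4) {
  stopifnot(levels >= 1)
  block <- 2^levels
  pad <- (block - length(x) %% block) %% block
  if (pad > 0) x <- c(x, numeric(pad))
  if (length(x) < block) x <- c(x, numeric(block - length(x)))
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step_db4(a)
    details[[j]] <- st$detail
    a <- st$approx
  }
  list(details = details, approx = a)
}

# Undecimated (a-trous) detail band of the db4 pyramid at a given level,
# evaluated sample-synchronously; used as the wavelet envelope for
# segmentation. Periodic boundary.
swt_detail_db4 <- function(x, level = 4) {
  f <- db4_filters()
  n <- length(x)
  a <- x
  conv4 <- function(v, taps, spacing) {
    out <- numeric(n)
    for (k in 0:3) {
      shift <- k * spacing
      out <- out + taps[k + 1] * v[((seq_len(n) - 1 + shift) %% n) + 1]
    }
    out
  }
  for (j in seq_len(level - 1)) a <- conv4(a, f$h / sqrt(2), 2^(j - 1))
  conv4(a, f$g / sqrt(2), 2^(level - 1))
}
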