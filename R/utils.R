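# Small shared numerical helpers.

#' Highest density interval of a sample of draws
#'
#' Narrowest contiguous interval containing a given posterior mass, found by
#' scanning all windows of the sorted draws (exact for unimodal samples).
#'
#' @param draws numeric vector of posterior draws.
#' @param prob probability mass the interval must contain (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, prob = 0.95) {
  stopifnot(is.numeric(draws), length(draws) > 1, prob > 0, prob < 1)
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  m <- max(2L, ceiling(prob * n))  # points the interval must contain
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Maximum a posteriori estimate from draws
#'
#' Mode of a Gaussian kernel density fitted to the draws (bandwidth by
#' Silverman's rule, the [stats::density()] default).
#'
#' @param draws numeric vector of posterior draws.
#' @return scalar mode estimate.
#' @export
map_estimate <- function(draws) {
  stopifnot(is.numeric(draws), length(draws) > 1)
  d <- density(draws[is.finite(draws)])
  d$x[which.max(d$y)]
}

# Split-chain potential scale reduction factor (R-hat) for one parameter.
# `mat` is iterations x chains.
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Standardize columns to mean 0, SD 1; constant columns left untouched.
# Returns matrix with "center"/"scale" attributes for later reuse.
scale_columns <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  Xs
}

# deterministic sub-seed derivation; keeps results well below 2^31
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(salt) * 12347) %% 2000000011)
}
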