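# Shared numerical helpers.

#' Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse with a relative singular-value cutoff. Singular
#' values below `rcond * max(d)` are treated as zero.
#'
#' @param x numeric matrix.
#' @param rcond relative cutoff for small singular values (default `1e-10`).
#' @return the pseudoinverse, a `ncol(x)` by `nrow(x)` matrix.
#' @export
pseudoinverse <- function(x, rcond = 1e-10) {
  x <- as.matrix(x)
  s <- svd(x)
  keep <- s$d > rcond * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(x), nrow(x)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# 2-norm condition number of a matrix (ratio of extreme singular values).
condition_number <- function(x) {
  d <- svd(as.matrix(x), nu = 0, nv = 0)$d
  if (min(d) == 0) Inf else max(d) / min(d)
}

#' Gaussian smoothing of a vector or matrix rows
#'
#' Discrete Gaussian convolution with reflect padding at the edges, so that
#' trial onsets do not produce roll-on artifacts. With `sigma_bins = 0` the
#' input is returned unchanged.
#'
#' @param x numeric vector, or matrix smoothed row-wise.
#' @param sigma_bins Gaussian standard deviation in bins.
#' @return smoothed object of the same shape.
#' @export
gaussian_smooth <- function(x, sigma_bins) {
  stopifnot(is.numeric(sigma_bins), length(sigma_bins) == 1, sigma_bins >= 0)
  if (sigma_bins == 0) return(x)
  if (is.matrix(x)) {
    return(t(apply(x, 1, gaussian_smooth, sigma_bins = sigma_bins)))
  }
  radius <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  # reflect padding (edge value not repeated), clamped for very short inputs
  pre <- x[pmin(n, pmax(1, (radius + 1):2))]
  post <- x[pmin(n, pmax(1, (n - 1):(n - radius)))]
  xp <- c(pre, x, post)
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(radius + 1):(radius + n)])
}

# consistent stop()s with a class so tests can assert on them
lp_abort <- function(msg, class) {
  abort(msg, class = paste0("laminpop_", class))
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
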