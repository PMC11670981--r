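# Statistical baselines: PCA and ICA decompositions of the same
# channels x time field matrices.

new_component_set <- function(spatial, temporal, method, center,
                              explained_var = NULL, converged = TRUE) {
  labels <- paste0(toupper(substr(method, 1, 2)), "_", seq_len(ncol(spatial)))
  colnames(spatial) <- labels
  rownames(temporal) <- labels
  structure(
    list(spatial = spatial, temporal = temporal, method = method,
         center = center, explained_var = explained_var,
         converged = converged),
    class = "component_set"
  )
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set:%s> %d components, %d channels x %d bins\n",
              x$method, ncol(x$spatial), nrow(x$spatial), ncol(x$temporal)))
  if (!is.null(x$explained_var)) {
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * x$explained_var), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-component field matrices
#'
#' @param x a `component_set`.
#' @return named list of channels x bins rank-1 matrices, one per component.
#' @export
component_fields <- function(x) {
  stopifnot(inherits(x, "component_set"))
  out <- lapply(seq_len(ncol(x$spatial)), function(k) {
    outer(x$spatial[, k], x$temporal[k, ])
  })
  names(out) <- colnames(x$spatial)
  out
}

#' PCA decomposition of a field matrix
#'
#' Rank-`k` singular value decomposition of the per-channel time-mean-centred
#' matrix. Component `i`'s field is the outer product of its spatial map
#' (left singular vector) and temporal course (singular value times right
#' singular vector); explained-variance fractions are reported. Summing all
#' `min(N_ch, B)` component fields plus the channel means reproduces the input
#' exactly.
#'
#' @param field channels x bins matrix (e.g. a CSD [recording_matrix()]).
#' @param k number of components, `<= min(N_ch, B)`.
#' @return a `component_set` with `explained_var`.
#' @export
decompose_pca <- function(field, k) {
  x <- unclass(as.matrix(field))
  if (k > min(dim(x))) {
    lp_abort(sprintf("k = %d exceeds min(N_ch, B) = %d.", k, min(dim(x))),
             "parameter_error")
  }
  center <- rowMeans(x)
  xc <- x - center
  s <- svd(xc)
  ev <- s$d^2 / sum(s$d^2)
  spatial <- s$u[, seq_len(k), drop = FALSE]
  temporal <- (s$d[seq_len(k)] * t(s$v[, seq_len(k), drop = FALSE]))
  new_component_set(spatial, temporal, "pca", center,
                    explained_var = ev[seq_len(k)])
}

#' ICA decomposition of a field matrix
#'
#' Fixed-point (FastICA-style) independent component analysis of the
#' per-channel time-mean-centred matrix, extracting `k` maximally
#' statistically independent temporal sources with their spatial mixing maps.
#' Uses PCA whitening, the logcosh contrast and symmetric decorrelation.
#' Component order and sign carry no meaning. Deterministic for a fixed seed;
#' non-convergence within `maxit` yields a warning and the flagged partial
#' result.
#'
#' @param field channels x bins matrix.
#' @param k number of components, `<= N_ch`.
#' @param seed RNG seed for the random orthogonal initialization.
#' @param maxit,tol fixed-point iteration cap and convergence tolerance.
#' @return a `component_set` with a `converged` flag.
#' @export
decompose_ica <- function(field, k, seed = 1L, maxit = 200, tol = 1e-6) {
  x <- unclass(as.matrix(field))
  if (k > nrow(x)) {
    lp_abort(sprintf("k = %d exceeds the channel count %d.", k, nrow(x)),
             "parameter_error")
  }
  center <- rowMeans(x)
  xc <- x - center
  b <- ncol(xc)
  # PCA whitening down to k dimensions
  s <- svd(xc, nu = k, nv = 0)
  d <- s$d[seq_len(k)]
  if (any(d < 1e-12 * max(s$d))) {
    lp_abort("field has rank below k; reduce k.", "parameter_error")
  }
  wh <- (t(s$u) / d) * sqrt(b)          # whitening: z = wh %*% xc has unit cov
  dewh <- s$u * rep(d, each = nrow(xc)) / sqrt(b)
  z <- wh %*% xc

  set.seed(seed)
  w <- qr.Q(qr(matrix(rnorm(k * k), k)))  # random orthogonal start
  sym_decorrelate <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    e$vectors %*% (t(e$vectors) / sqrt(e$values)) %*% w
  }
  w <- sym_decorrelate(w)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    w_new <- sym_decorrelate(g %*% t(z) / b - gp * w)
    delta <- max(abs(abs(rowSums(w_new * w)) - 1))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("ICA did not converge within %d iterations (last step %.3g); returning partial result.",
                 maxit, delta), class = "laminpop_nonconvergence")
  }
  sources <- w %*% z                      # k x B temporal sources, unit variance
  mixing <- dewh %*% t(w)                 # channels x k maps: xc ~= mixing %*% sources
  new_component_set(mixing, sources, "ica", center, converged = converged)
}
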