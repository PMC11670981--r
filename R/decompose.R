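# Linear-algebra core shared by the MUA and CSD decomposition steps.

#' Infer population firing rates from MUA by pseudoinverse
#'
#' Given the spatial matrix `M` (populations x channels) and the recorded MUA
#' envelope (channels x bins), the least-squares optimal temporal profiles are
#' `r = (M^T)^+ phi_M`, computed with an SVD pseudoinverse (relative singular
#' value cutoff 1e-10).
#'
#' @param m spatial matrix from [build_spatial_matrix()] (N_pop x N_ch).
#' @param phi_m MUA envelope, [recording_matrix()] or matrix (N_ch x B).
#' @return a [rate_matrix()] (N_pop x B). Rates can be negative: they are
#'   least-squares amplitudes in MUA units, not spike counts.
#' @export
infer_rates <- function(m, phi_m) {
  m <- as.matrix(m)
  zero_rows <- rowSums(abs(m)) == 0
  if (any(zero_rows)) {
    nm <- rownames(m) %||% paste0("pop_", seq_len(nrow(m)))
    lp_abort(paste0("spatial matrix is rank deficient; zero-support population(s): ",
                    paste(nm[zero_rows], collapse = ", ")), "rank_error")
  }
  vals <- pseudoinverse(t(m)) %*% unclass(phi_m)
  dt <- if (inherits(phi_m, "recording_matrix")) rec_dt(phi_m) else 1
  t0 <- if (inherits(phi_m, "recording_matrix")) rec_t0(phi_m) else 0
  rate_matrix(vals, dt_ms = dt, t0_ms = t0,
              populations = rownames(m), source = "internal")
}

#' Reconstruct a signal from spatial and temporal profiles
#'
#' Computes the matrix product `spatial %*% temporal` where `spatial` is
#' channels x populations and `temporal` is populations x bins. For the MUA
#' model pass `t(M)`. With `contributions = TRUE` the rank-1 per-population
#' contribution matrices (outer products of column n and row n) are attached;
#' they sum to the total reconstruction exactly.
#'
#' @param spatial channels x populations matrix.
#' @param temporal populations x bins matrix.
#' @param contributions attach per-population contribution matrices?
#' @return channels x bins matrix; if `contributions`, a list with elements
#'   `total` and `contributions` (named list of matrices).
#' @export
reconstruct_signal <- function(spatial, temporal, contributions = FALSE) {
  spatial <- as.matrix(spatial)
  temporal <- unclass(as.matrix(temporal))
  if (ncol(spatial) != nrow(temporal)) {
    lp_abort(sprintf("spatial has %d populations but temporal has %d rows.",
                     ncol(spatial), nrow(temporal)), "dimension_error")
  }
  if (!contributions) return(spatial %*% temporal)
  labels <- rownames(temporal) %||% paste0("pop_", seq_len(nrow(temporal)))
  per_pop <- lapply(seq_len(nrow(temporal)), function(n) {
    outer(unname(spatial[, n]), temporal[n, ])
  })
  names(per_pop) <- labels
  # the total is the literal sum of the per-population matrices, so the
  # "contributions sum to the reconstruction" identity holds bit-exactly
  list(total = Reduce(`+`, per_pop), contributions = per_pop)
}

#' Relative mean square error
#'
#' `sum((truth - estimate)^2) / sum(truth^2)`: 0 for a perfect estimate, 1 for
#' an all-zero estimate.
#'
#' @param truth,estimate same-shaped numeric arrays; `truth` must not be
#'   all-zero.
#' @return non-negative scalar.
#' @export
relative_mse <- function(truth, estimate) {
  truth <- unclass(as.matrix(truth)); estimate <- unclass(as.matrix(estimate))
  if (!identical(dim(truth), dim(estimate))) {
    lp_abort("`truth` and `estimate` must have the same shape.", "dimension_error")
  }
  denom <- sum(truth^2)
  if (denom == 0) lp_abort("`truth` is all-zero; relative MSE is undefined.",
                           "parameter_error")
  sum((truth - estimate)^2) / denom
}

#' Infer per-population spatial field profiles
#'
#' Given postsynaptic temporal profiles `R_est` (populations x bins), the
#' least-squares spatial profiles of the field (LFP or CSD) are
#' `L = field R_est^+`. Near-collinear temporal profiles -- the failure mode
#' produced by synchronous population firing -- are reported with a warning
#' naming the most correlated pair when the condition number exceeds
#' `cond_warn`.
#'
#' @param field channels x bins field matrix (LFP or CSD).
#' @param r_est populations x bins postsynaptic temporal profiles.
#' @param cond_warn condition-number warning threshold (default 1e6).
#' @param quiet suppress the collinearity warning (used inside optimizer loops).
#' @return channels x populations matrix `L_est`.
#' @export
infer_spatial_field <- function(field, r_est, cond_warn = 1e6, quiet = FALSE) {
  field <- unclass(as.matrix(field))
  r <- unclass(as.matrix(r_est))
  if (ncol(field) != ncol(r)) {
    lp_abort("field and temporal profiles must share the time axis.",
             "dimension_error")
  }
  if (!quiet) {
    kappa <- condition_number(r)
    if (kappa > cond_warn) {
      cm <- suppressWarnings(stats::cor(t(r)))
      diag(cm) <- -Inf
      cm[!is.finite(cm)] <- -Inf
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      nm <- rownames(r) %||% paste0("pop_", seq_len(nrow(r)))
      warn(sprintf(
        "temporal profiles are near-collinear (condition number %.3g); most correlated pair: %s / %s",
        kappa, nm[ij[1]], nm[ij[2]]), class = "laminpop_collinear")
    }
  }
  l <- field %*% pseudoinverse(r)
  colnames(l) <- rownames(r)
  l
}

#' CSD cost with zero-sum penalty
#'
#' The decomposition cost is the relative mean square error of the estimate
#' plus `lambda` times the channel-sum deviation of the estimate (time-averaged
#' absolute channel sum, normalized by the peak |CSD estimate|). With
#' `lambda = 0` it reduces exactly to the relative MSE.
#'
#' @param csd_true,csd_est same-shaped CSD matrices.
#' @param lambda non-negative penalty weight.
#' @return scalar cost.
#' @export
csd_cost <- function(csd_true, csd_est, lambda = 0) {
  if (lambda < 0) lp_abort("`lambda` must be >= 0.", "parameter_error")
  err <- relative_mse(csd_true, csd_est)
  if (lambda == 0) return(err)
  err + lambda * channel_sum_deviation(as.matrix(csd_est))
}
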