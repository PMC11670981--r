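# Steps 2-4 of the decomposition: kernel fitting, spatial field profiles and
# per-population CSD/LFP contributions, with the zero-sum channel penalty.

#' Append external-structure firing rates
#'
#' Row-stacks the firing rates of external presynaptic structures (e.g.
#' thalamic input or cortical feedback) under the internal laminar rates.
#' External rows take part in the field decomposition but are exempt from the
#' MUA spatial model. The optional `standardize` switch rescales every row to
#' unit peak absolute value, for use when MUA-derived internal amplitudes and
#' spike-derived external rates are not on a comparable scale.
#'
#' @param internal,external [rate_matrix()] objects on the same time base.
#' @param standardize rescale each row to unit peak |rate|?
#' @return a combined [rate_matrix()] with provenance preserved in
#'   [rate_source()].
#' @export
append_external_rates <- function(internal, external = NULL,
                                  standardize = FALSE) {
  stopifnot(inherits(internal, "rate_matrix"))
  if (is.null(external)) {
    out <- internal
  } else {
    stopifnot(inherits(external, "rate_matrix"))
    if (!same_timebase(internal, external)) {
      lp_abort("internal and external rates must share dt, t0 and bin count.",
               "dimension_error")
    }
    out <- rate_matrix(rbind(unclass(internal), unclass(external)),
                       rec_dt(internal), rec_t0(internal),
                       populations = c(rownames(internal), rownames(external)),
                       source = c(rate_source(internal),
                                  rep("external", nrow(external))))
  }
  if (standardize) {
    v <- unclass(out)
    peak <- apply(abs(v), 1, max)
    peak[peak == 0] <- 1
    out <- rate_matrix(v / peak, rec_dt(out), rec_t0(out),
                       populations = rownames(out), source = rate_source(out))
  }
  out
}

#' Merge populations by groups
#'
#' Sums (or cell-count-weights) the rate rows of grouped populations, e.g.
#' merging all laminar populations into a single structure-wide rate, or
#' L2/3 + L4 into an upper-layer and L5 + L6 into a deep-layer population.
#' External rows not named in `grouping` are carried through unchanged.
#'
#' @param rates a [rate_matrix()].
#' @param grouping named list of character vectors; the vectors must partition
#'   the internal population labels. Group names label the merged rows.
#' @param weights optional named cell counts; when given, groups are combined
#'   by the cell-count-weighted mean instead of the sum.
#' @return a [rate_matrix()].
#' @export
merge_populations <- function(rates, grouping, weights = NULL) {
  stopifnot(inherits(rates, "rate_matrix"))
  members <- unlist(grouping, use.names = FALSE)
  internal <- rownames(rates)[rate_source(rates) == "internal"]
  if (anyDuplicated(members) || !setequal(members, internal)) {
    lp_abort("`grouping` must partition the internal population labels.",
             "parameter_error")
  }
  if (is.null(names(grouping)) || any(names(grouping) == "")) {
    names(grouping) <- vapply(grouping, paste, character(1), collapse = "+")
  }
  v <- unclass(rates)
  merged <- t(vapply(grouping, function(g) {
    rows <- v[g, , drop = FALSE]
    if (is.null(weights)) {
      colSums(rows)
    } else {
      w <- as.numeric(weights[g])
      colSums(rows * w) / sum(w)
    }
  }, numeric(ncol(rates))))
  ext <- rate_source(rates) == "external"
  rate_matrix(rbind(merged, v[ext, , drop = FALSE]),
              rec_dt(rates), rec_t0(rates),
              populations = c(names(grouping), rownames(rates)[ext]),
              source = c(rep("internal", length(grouping)),
                         rep("external", sum(ext))))
}

#' Fit postsynaptic kernels and decompose a field into population contributions
#'
#' Seeded differential evolution over the per-population kernel time constants
#' and delays. For every candidate the presynaptic rates are convolved with
#' the kernels ([postsynaptic_profiles()]), the least-squares spatial profiles
#' follow from the pseudoinverse ([infer_spatial_field()]), and the cost is
#' [csd_cost()] -- the relative MSE of the reconstruction plus `lambda` times
#' the channel-sum deviation of the estimate. The returned contributions (one
#' channels x bins matrix per presynaptic population) sum to the total
#' reconstruction exactly.
#'
#' @param field the signal to decompose (CSD, or LFP), a [recording_matrix()].
#' @param rates presynaptic rates, a [rate_matrix()] -- internal populations
#'   plus any appended external structures ([append_external_rates()]).
#' @param config an [analysis_config()]; kernel bounds, optimizer settings and
#'   `rng_seed` are used.
#' @param lambda penalty weight; defaults to `config$lambda_penalty`.
#' @return an `lpa_csd_fit`: kernel table, postsynaptic temporal profiles,
#'   spatial profiles, per-population contributions, fitted field, error
#'   metrics and convergence info. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_csd <- function(field, rates, config, lambda = NULL) {
  stopifnot(inherits(field, "recording_matrix"), inherits(rates, "rate_matrix"),
            inherits(config, "analysis_config"))
  if (!same_timebase(field, rates)) {
    lp_abort("field and rates must share dt, t0 and bin count.",
             "dimension_error")
  }
  lambda <- lambda %||% config$lambda_penalty
  if (!is_number(lambda) || lambda < 0) {
    lp_abort("`lambda` must be >= 0.", "parameter_error")
  }
  n_pop <- nrow(rates)
  c_mat <- unclass(field)
  r_mat <- unclass(rates)
  dt <- rec_dt(rates)
  ss <- sum(c_mat^2)
  if (ss == 0) lp_abort("field is all-zero.", "parameter_error")
  # warn upfront when the presynaptic rates themselves are near-collinear:
  # no kernel choice can separate populations that fire in lockstep
  kappa_r <- condition_number(r_mat)
  if (kappa_r > 1e6) {
    cm <- suppressWarnings(stats::cor(t(r_mat)))
    diag(cm) <- -Inf
    cm[!is.finite(cm)] <- -Inf
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    warn(sprintf(
      "presynaptic rates are near-collinear (condition number %.3g); most correlated pair: %s / %s",
      kappa_r, rownames(r_mat)[ij[1]], rownames(r_mat)[ij[2]]),
      class = "laminpop_collinear")
  }
  tb <- config$tau_bounds_ms
  db <- config$delta_bounds_ms

  cost <- function(u) {
    tau <- tb[1] + u[seq_len(n_pop)] * diff(tb)
    del <- db[1] + u[n_pop + seq_len(n_pop)] * diff(db)
    r_est <- matrix(0, n_pop, ncol(r_mat))
    for (n in seq_len(n_pop)) {
      r_est[n, ] <- convolve_exp(r_mat[n, ], tau[n], del[n], dt)
    }
    l <- c_mat %*% pseudoinverse(r_est)
    est <- l %*% r_est
    val <- sum((c_mat - est)^2) / ss
    if (lambda > 0) {
      peak <- max(abs(est))
      if (peak > 0) val <- val + lambda * mean(abs(colSums(est))) / peak
    }
    val
  }

  opt <- run_de(cost, 2 * n_pop, config)
  tau <- tb[1] + opt$par[seq_len(n_pop)] * diff(tb)
  del <- db[1] + opt$par[n_pop + seq_len(n_pop)] * diff(db)
  kernels <- kernel_params(tau, del, populations = rownames(rates))

  r_est <- postsynaptic_profiles(rates, kernels)
  l_est <- infer_spatial_field(c_mat, r_est)  # collinearity warning if due
  rec <- reconstruct_signal(l_est, r_est, contributions = TRUE)
  fitted <- recording_matrix(rec$total, rec_dt(field), rec_t0(field),
                             rec_kind(field), depths_um = attr(field, "depths_um"))
  err <- relative_mse(c_mat, rec$total)
  pen <- channel_sum_deviation(rec$total)
  structure(
    list(kernels = kernels, postsynaptic = r_est, spatial = l_est,
         contributions = rec$contributions, fitted = fitted, data = field,
         rates = rates, lambda = lambda, e_c = err + lambda * pen,
         rel_mse = err, penalty_term = pen,
         correlation = stats::cor(as.numeric(c_mat), as.numeric(rec$total)),
         convergence = opt$convergence, config = config),
    class = "lpa_csd_fit"
  )
}

#' @export
print.lpa_csd_fit <- function(x, ...) {
  cat(sprintf("<lpa_csd_fit> %d presynaptic populations, lambda = %g\n",
              nrow(x$kernels), x$lambda))
  cat(sprintf("  rel. MSE = %.4g, channel-sum deviation = %.4g, correlation = %.3f\n",
              x$rel_mse, x$penalty_term, x$correlation))
  print(x$kernels)
  invisible(x)
}

#' Scan the zero-sum penalty weight
#'
#' Fits the field decomposition over a grid of penalty weights and selects the
#' lambda at which the channel-sum deviation of the estimate is smallest
#' (ties go to the smallest lambda).
#'
#' @inheritParams fit_csd
#' @param lambdas numeric grid of candidate penalty weights (default `0:8`).
#' @return a `lambda_scan`: `table` (tibble with lambda, deviation, rel_mse,
#'   correlation), `lambda_best` and `best_fit`. Methods: [tidy()],
#'   [autoplot()].
#' @export
select_lambda <- function(field, rates, config, lambdas = 0:8) {
  fits <- lapply(lambdas, function(l) {
    suppressWarnings(fit_csd(field, rates, config, lambda = l))
  })
  table <- tibble(
    lambda = as.numeric(lambdas),
    deviation = vapply(fits, function(f) f$penalty_term, numeric(1)),
    rel_mse = vapply(fits, function(f) f$rel_mse, numeric(1)),
    correlation = vapply(fits, function(f) f$correlation, numeric(1))
  )
  best <- which.min(table$deviation)  # which.min takes the first = smallest lambda
  structure(
    list(table = table, lambda_best = table$lambda[best],
         best_fit = fits[[best]],
         data_deviation = channel_sum_deviation(as.matrix(field))),
    class = "lambda_scan"
  )
}

#' @export
print.lambda_scan <- function(x, ...) {
  cat(sprintf("<lambda_scan> best lambda = %g (deviation %.4g; data deviation %.4g)\n",
              x$lambda_best, min(x$table$deviation), x$data_deviation))
  print(x$table)
  invisible(x)
}
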