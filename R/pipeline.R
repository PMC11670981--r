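# End-to-end pipeline: band split -> MUA fit -> kernels -> field decomposition.

#' Run the full decomposition pipeline
#'
#' Executes the four analysis steps on a recording: (1) fit trapezoid
#' population profiles and firing rates to the trial-averaged MUA envelope,
#' (2) convolve the rates (plus any external-structure rates) with exponential
#' kernels, (3) decompose the CSD (or LFP) into per-population spatial
#' profiles, (4) reconstruct per-population contributions. Deterministic for a
#' fixed `config$rng_seed`.
#'
#' @param config an [analysis_config()].
#' @param recording a [trial_ensemble()] of kind `"ecp"` (band-split
#'   internally), or of kind `"mua"`/`"lfp"`/`"csd"` when already processed.
#'   A list of such ensembles is also accepted (e.g.
#'   `list(mua = ..., lfp = ...)`).
#' @param external_rates optional [rate_matrix()] of external presynaptic
#'   structures appended before the field decomposition.
#' @param scan_lambda fit over a lambda grid ([select_lambda()]) and keep the
#'   deviation-minimizing fit instead of using `config$lambda_penalty`.
#' @param lambdas grid used when `scan_lambda = TRUE`.
#' @return an `lpa_result` with fields `mua_fit`, `csd_fit`, `lambda_scan`
#'   (when scanned), `mua`, `lfp`, `csd`, `config`.
#' @export
run_pipeline <- function(config, recording, external_rates = NULL,
                         scan_lambda = FALSE, lambdas = 0:8) {
  stopifnot(inherits(config, "analysis_config"))
  sig <- pipeline_signals(config, recording)
  if (is.null(sig$mua)) {
    lp_abort("no MUA (or ECP) signal available for step 1.", "parameter_error")
  }
  mua_fit <- fit_mua(sig$mua, sig$geometry, config)

  field <- sig$csd
  if (is.null(field) && !is.null(sig$lfp)) {
    field <- if (config$csd_method == "delta_icsd") {
      delta_icsd(sig$lfp, sig$geometry)
    } else {
      traditional_csd(sig$lfp, sig$geometry)
    }
  }
  csd_fit <- NULL; scan <- NULL
  if (!is.null(field)) {
    rates <- append_external_rates(mua_fit$rates, external_rates)
    if (scan_lambda) {
      scan <- select_lambda(field, rates, config, lambdas = lambdas)
      csd_fit <- scan$best_fit
    } else {
      csd_fit <- fit_csd(field, rates, config)
    }
  }
  structure(
    list(mua_fit = mua_fit, csd_fit = csd_fit, lambda_scan = scan,
         mua = sig$mua, lfp = sig$lfp, csd = field, config = config),
    class = "lpa_result"
  )
}

# normalize the recording argument into trial-averaged mua/lfp/csd signals
pipeline_signals <- function(config, recording) {
  if (inherits(recording, "trial_ensemble")) recording <- list(recording)
  out <- list(mua = NULL, lfp = NULL, csd = NULL, geometry = NULL)
  for (ens in recording) {
    stopifnot(inherits(ens, "trial_ensemble"))
    out$geometry <- out$geometry %||% ens$geometry
    if (ens$kind == "ecp") {
      lfp_tr <- vector("list", n_trials(ens))
      mua_tr <- vector("list", n_trials(ens))
      for (k in seq_len(n_trials(ens))) {
        one <- recording_matrix(ens$trials[[k]], ens$dt_ms, ens$t0_ms, "ecp",
                                depths_um = ens$geometry$depths_um)
        bands <- split_bands(one, config$cutoff_hz, config$filter_order)
        lfp_tr[[k]] <- bands$lfp
        mua_tr[[k]] <- mua_envelope(bands$mua_raw, config$smooth_ms)
      }
      out$lfp <- trial_average(lfp_tr)
      out$mua <- trial_average(mua_tr)
    } else {
      avg <- trial_average(ens)
      out[[ens$kind]] <- if (ens$kind == "mua") {
        mua_envelope(recording_matrix(abs(unclass(avg)), ens$dt_ms, ens$t0_ms,
                                      "mua", depths_um = ens$geometry$depths_um),
                     config$smooth_ms)
      } else {
        avg
      }
    }
  }
  out
}

#' @export
print.lpa_result <- function(x, ...) {
  cat("<lpa_result>\n  step 1 (MUA): ")
  cat(sprintf("%d populations, e_M = %.4g\n",
              nrow(x$mua_fit$populations), x$mua_fit$e_m))
  if (!is.null(x$csd_fit)) {
    cat(sprintf("  steps 2-4 (%s): rel. MSE = %.4g, lambda = %g\n",
                rec_kind(x$csd_fit$data), x$csd_fit$rel_mse, x$csd_fit$lambda))
  }
  invisible(x)
}

#' Write a decomposition result bundle
#'
#' HDF5 layout: `/spatial` (MUA trapezoid matrix and field profiles),
#' `/temporal` (rates and postsynaptic profiles), `/contributions` (one
#' dataset per presynaptic population) and `/metrics`. Kernel and trapezoid
#' parameter tables are additionally written as flat TSV files next to the
#' bundle (same stem, `_kernels.tsv` / `_trapezoids.tsv`) for inspection.
#'
#' @param result an `lpa_result`.
#' @param path output `.h5` path.
#' @return `path`, invisibly.
#' @export
write_result_bundle <- function(result, path) {
  stopifnot(inherits(result, "lpa_result"))
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  for (g in c("spatial", "temporal", "contributions", "metrics")) {
    rhdf5::h5createGroup(path, g)
  }
  mf <- result$mua_fit
  rhdf5::h5write(unclass(mf$spatial), path, "spatial/mua_profiles")
  rhdf5::h5write(unclass(mf$rates), path, "temporal/rates")
  metrics <- c(e_m = mf$e_m, mua_correlation = mf$correlation)
  if (!is.null(result$csd_fit)) {
    cf <- result$csd_fit
    rhdf5::h5write(unclass(cf$spatial), path, "spatial/field_profiles")
    rhdf5::h5write(unclass(cf$postsynaptic), path, "temporal/postsynaptic")
    for (nm in names(cf$contributions)) {
      rhdf5::h5write(cf$contributions[[nm]], path,
                     paste0("contributions/", gsub("/", "_", nm)))
    }
    metrics <- c(metrics, e_c = cf$e_c, rel_mse = cf$rel_mse,
                 penalty_term = cf$penalty_term, lambda = cf$lambda,
                 csd_correlation = cf$correlation)
  }
  rhdf5::h5write(metrics, path, "metrics/values")
  rhdf5::h5write(names(metrics), path, "metrics/names")
  stem <- sub("\\.h5$", "", path)
  readr::write_tsv(as_tibble(mf$populations), paste0(stem, "_trapezoids.tsv"))
  if (!is.null(result$csd_fit)) {
    readr::write_tsv(result$csd_fit$kernels, paste0(stem, "_kernels.tsv"))
  }
  invisible(path)
}

#' Summary metrics table of a result
#'
#' @param result an `lpa_result`.
#' @return one-row tibble of headline fit metrics.
#' @export
pipeline_report <- function(result) {
  stopifnot(inherits(result, "lpa_result"))
  tb <- tibble(n_populations = nrow(result$mua_fit$populations),
               e_m = result$mua_fit$e_m,
               mua_correlation = result$mua_fit$correlation)
  if (!is.null(result$csd_fit)) {
    tb$rel_mse_csd <- result$csd_fit$rel_mse
    tb$csd_correlation <- result$csd_fit$correlation
    tb$channel_sum_deviation <- result$csd_fit$penalty_term
    tb$lambda <- result$csd_fit$lambda
  }
  tb
}
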