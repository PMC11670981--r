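# Band splitting, MUA envelope, trial averaging and spike-based firing rates.

#' Split the extracellular potential into LFP and MUA bands
#'
#' Applies a zero-phase (forward-backward) Butterworth filter to every channel:
#' the low-pass output is the local field potential, the high-pass output with
#' the same cutoff and order is the raw multi-unit activity band.
#'
#' @param ecp a [recording_matrix()] of kind `"ecp"`.
#' @param cutoff_hz cutoff frequency (default 300 Hz); must be below Nyquist.
#' @param order Butterworth filter order (default 5).
#' @return list with elements `lfp` and `mua_raw`, both [recording_matrix()].
#' @export
split_bands <- function(ecp, cutoff_hz = 300, order = 5) {
  stopifnot(inherits(ecp, "recording_matrix"))
  if (rec_kind(ecp) != "ecp") {
    lp_abort("`split_bands()` expects an ECP recording.", "parameter_error")
  }
  fs <- 1000 / rec_dt(ecp)
  if (cutoff_hz >= fs / 2) {
    lp_abort(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz.",
                     cutoff_hz, fs / 2), "parameter_error")
  }
  wc <- cutoff_hz / (fs / 2)
  bl <- signal::butter(order, wc, type = "low")
  bh <- signal::butter(order, wc, type = "high")
  lfp <- t(apply(ecp, 1, function(v) signal::filtfilt(bl, v)))
  mua <- t(apply(ecp, 1, function(v) signal::filtfilt(bh, v)))
  list(
    lfp = recording_matrix(lfp, rec_dt(ecp), rec_t0(ecp), "lfp",
                           depths_um = attr(ecp, "depths_um")),
    mua_raw = recording_matrix(mua, rec_dt(ecp), rec_t0(ecp), "mua",
                               depths_um = attr(ecp, "depths_um"))
  )
}

#' Non-negative MUA envelope
#'
#' Rectifies the high-pass band (absolute value) and smooths it with a
#' Gaussian of standard deviation `smooth_ms`, using reflect padding at the
#' trial edges. The result is the slowly varying, non-negative amplitude
#' signal that the population decomposition is fitted to.
#'
#' @param mua_raw a [recording_matrix()] of kind `"mua"`.
#' @param smooth_ms positive Gaussian sd in ms (default 2).
#' @return a [recording_matrix()] of kind `"mua"`, non-negative.
#' @export
mua_envelope <- function(mua_raw, smooth_ms = 2) {
  stopifnot(inherits(mua_raw, "recording_matrix"))
  if (rec_kind(mua_raw) != "mua") {
    lp_abort("`mua_envelope()` expects a MUA-band recording.", "parameter_error")
  }
  if (!is_number(smooth_ms) || smooth_ms <= 0) {
    lp_abort("`smooth_ms` must be positive.", "parameter_error")
  }
  env <- gaussian_smooth(abs(unclass(mua_raw)), smooth_ms / rec_dt(mua_raw))
  recording_matrix(env, rec_dt(mua_raw), rec_t0(mua_raw), "mua",
                   depths_um = attr(mua_raw, "depths_um"))
}

#' Element-wise mean across trials
#'
#' @param trials a [trial_ensemble()], or a list of [recording_matrix()]
#'   objects sharing shape and time base.
#' @return a [recording_matrix()] of the shared kind.
#' @export
trial_average <- function(trials) {
  if (inherits(trials, "trial_ensemble")) {
    avg <- Reduce(`+`, trials$trials) / length(trials$trials)
    return(recording_matrix(avg, trials$dt_ms, trials$t0_ms, trials$kind,
                            depths_um = trials$geometry$depths_um))
  }
  if (!is.list(trials) || length(trials) == 0) {
    lp_abort("`trials` must be a non-empty list or a trial_ensemble.",
             "parameter_error")
  }
  first <- trials[[1]]
  stopifnot(inherits(first, "recording_matrix"))
  for (tr in trials[-1]) {
    if (!identical(dim(tr), dim(first)) || !same_timebase(tr, first)) {
      lp_abort("trials must share shape, dt and t0.", "dimension_error")
    }
  }
  avg <- Reduce(`+`, lapply(trials, unclass)) / length(trials)
  recording_matrix(avg, rec_dt(first), rec_t0(first), rec_kind(first),
                   depths_um = attr(first, "depths_um"))
}

#' Population firing rates from spike events
#'
#' Bins spikes per population at `bin_ms` resolution (1 ms by default), smooths
#' the counts with a Gaussian of `gauss_sigma_bins` bins (default 2), averages
#' over trials, and scales to spikes per second per cell when cell counts are
#' given (otherwise rates are per-population spikes/s).
#'
#' @param events data frame with columns `population_id`, `trial`, `time_ms`.
#' @param populations character vector of population labels (row order of the
#'   result); every label in `events` must be listed here.
#' @param t0_ms,n_bins time window: bins start at `t0_ms` and there are
#'   `n_bins` of width `bin_ms`.
#' @param bin_ms bin width in ms (default 1).
#' @param gauss_sigma_bins Gaussian smoothing sd in bins (default 2).
#' @param n_trials number of trials averaged over; defaults to the number of
#'   distinct trials in `events`.
#' @param cell_counts optional named vector of cells per population.
#' @param source `"internal"` or `"external"`, per population (recycled).
#' @return a [rate_matrix()], non-negative.
#' @export
firing_rate_from_spikes <- function(events, populations, t0_ms, n_bins,
                                    bin_ms = 1, gauss_sigma_bins = 2,
                                    n_trials = NULL, cell_counts = NULL,
                                    source = "internal") {
  events <- as_tibble(events)
  unknown <- setdiff(unique(events$population_id), populations)
  if (length(unknown) > 0) {
    lp_abort(paste0("unknown population label(s): ",
                    paste(unknown, collapse = ", ")), "parameter_error")
  }
  n_trials <- n_trials %||% max(1L, length(unique(events$trial)))
  t_end <- t0_ms + n_bins * bin_ms
  if (nrow(events) > 0 &&
      (any(events$time_ms < t0_ms) || any(events$time_ms >= t_end))) {
    lp_abort("spike times fall outside the recording window.", "parameter_error")
  }
  breaks <- t0_ms + bin_ms * (0:n_bins)
  rates <- matrix(0, length(populations), n_bins,
                  dimnames = list(populations, NULL))
  for (p in populations) {
    tp <- events$time_ms[events$population_id == p]
    if (length(tp) > 0) {
      counts <- as.numeric(graphics::hist(tp, breaks = breaks, plot = FALSE)$counts)
      n_cells <- if (!is.null(cell_counts)) cell_counts[[p]] else 1
      # counts -> spikes/s per cell, trial-averaged
      rates[p, ] <- gaussian_smooth(counts, gauss_sigma_bins) /
        (n_trials * n_cells * bin_ms / 1000)
    }
  }
  rate_matrix(rates, dt_ms = bin_ms, t0_ms = t0_ms,
              populations = populations, source = source)
}
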