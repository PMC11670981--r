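# File formats: HDF5 recording bundles, CSV single-trial matrices,
# delimited spike events, YAML analysis configuration.

#' Read a laminar recording
#'
#' Two formats are supported. An HDF5 file must contain a dataset `/ecp` with
#' dimensions trials x channels x bins (a channels x bins matrix is accepted as
#' a single trial), a dataset `/depths_um`, and root attributes `dt_ms`,
#' `t0_ms` and optionally `kind` and `units`. A CSV file holds one
#' channels x bins matrix (one row per channel, no header) and is read as a
#' single trial; the time base is then taken from `dt_ms`/`t0_ms`.
#'
#' @param path recording file (`.h5`/`.hdf5` or `.csv`).
#' @param geometry a [probe_geometry()] or path to a geometry YAML file. For
#'   HDF5 input it may be omitted; a geometry is then built from `/depths_um`.
#' @param dt_ms,t0_ms time base used for CSV input (ignored for HDF5).
#' @param kind signal kind used when the file does not record one.
#' @return a [trial_ensemble()].
#' @export
read_recording <- function(path, geometry = NULL, dt_ms = 1, t0_ms = 0,
                           kind = "ecp") {
  if (!file.exists(path)) lp_abort(paste0("no such file: ", path), "io_error")
  if (is.character(geometry)) geometry <- read_probe_geometry(geometry)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    read_recording_h5(path, geometry, kind)
  } else if (ext == "csv") {
    m <- as.matrix(readr::read_csv(path, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_double())))
    dimnames(m) <- NULL
    if (is.null(geometry)) {
      lp_abort("CSV recordings need an explicit `geometry`.", "config_error")
    }
    check_channel_count(nrow(m), geometry)
    trial_ensemble(list(m), geometry, dt_ms = dt_ms, t0_ms = t0_ms, kind = kind)
  } else {
    lp_abort(paste0("unsupported recording format: .", ext), "io_error")
  }
}

read_recording_h5 <- function(path, geometry, kind) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  if (!"ecp" %in% ls$name) lp_abort("HDF5 file has no /ecp dataset.", "io_error")
  arr <- rhdf5::h5read(path, "ecp")
  at <- rhdf5::h5readAttributes(path, "/")
  dt_ms <- as.numeric(at$dt_ms %||% 1)
  t0_ms <- as.numeric(at$t0_ms %||% 0)
  kind <- as.character(at$kind %||% kind)
  units <- as.character(at$units %||% "uV")
  depths <- if ("depths_um" %in% ls$name) {
    as.numeric(rhdf5::h5read(path, "depths_um"))
  } else NULL
  if (is.null(geometry)) {
    if (is.null(depths)) {
      lp_abort("HDF5 file has no /depths_um; supply `geometry`.", "config_error")
    }
    geometry <- probe_geometry(depths)
  }
  if (length(dim(arr)) == 2) arr <- array(arr, c(1, dim(arr)))
  check_channel_count(dim(arr)[2], geometry)
  trials <- lapply(seq_len(dim(arr)[1]), function(k) arr[k, , , drop = TRUE])
  trial_ensemble(trials, geometry, dt_ms = dt_ms, t0_ms = t0_ms,
                 kind = kind, units = units)
}

check_channel_count <- function(n_rows, geometry) {
  if (n_rows != n_channels(geometry)) {
    lp_abort(sprintf("recording has %d channels but geometry has %d.",
                     n_rows, n_channels(geometry)), "dimension_error")
  }
  invisible(TRUE)
}

#' Write a recording ensemble
#'
#' HDF5 layout: `/ecp` (trials x channels x bins), `/depths_um`, root
#' attributes `dt_ms`, `t0_ms`, `kind`, `units`. A `.csv` path writes the
#' single trial it contains (error if there are several).
#'
#' @param x a [trial_ensemble()].
#' @param path output file (`.h5` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "trial_ensemble"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    if (n_trials(x) != 1) {
      lp_abort("CSV output holds a single trial; this ensemble has several.",
               "io_error")
    }
    readr::write_csv(as.data.frame(x$trials[[1]]), path, col_names = FALSE)
    return(invisible(path))
  }
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  arr <- array(0, c(n_trials(x), n_channels(x$geometry), ncol(x$trials[[1]])))
  for (k in seq_len(n_trials(x))) arr[k, , ] <- x$trials[[k]]
  rhdf5::h5write(arr, path, "ecp")
  rhdf5::h5write(x$geometry$depths_um, path, "depths_um")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(x$dt_ms, fid, "dt_ms")
  rhdf5::h5writeAttribute(x$t0_ms, fid, "t0_ms")
  rhdf5::h5writeAttribute(x$kind, fid, "kind")
  rhdf5::h5writeAttribute(x$units, fid, "units")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read / write spike events
#'
#' Spike events travel as delimited text with columns `population_id`, `trial`
#' and `time_ms` (tab- or comma-separated, header required).
#'
#' @param path file path.
#' @return `read_spike_events()` returns a tibble with those three columns.
#' @export
read_spike_events <- function(path) {
  if (!file.exists(path)) lp_abort(paste0("no such file: ", path), "io_error")
  ev <- readr::read_delim(path, col_types = readr::cols(
    population_id = readr::col_character(),
    trial = readr::col_integer(),
    time_ms = readr::col_double()
  ), delim = NULL, show_col_types = FALSE)
  need <- c("population_id", "trial", "time_ms")
  if (!all(need %in% names(ev))) {
    lp_abort("spike file needs columns population_id, trial, time_ms.", "io_error")
  }
  as_tibble(ev[need])
}

#' @rdname read_spike_events
#' @param events data frame of spike events.
#' @export
write_spike_events <- function(events, path) {
  need <- c("population_id", "trial", "time_ms")
  if (!all(need %in% names(events))) {
    lp_abort("spike events need columns population_id, trial, time_ms.", "io_error")
  }
  readr::write_tsv(as.data.frame(events)[need], path)
  invisible(path)
}

#' Read / write a firing-rate matrix as TSV
#'
#' Wide layout: columns `population`, `source`, `dt_ms`, `t0_ms`, then one
#' column per time bin.
#'
#' @param path file path.
#' @return `read_rates()` returns a [rate_matrix()].
#' @export
read_rates <- function(path) {
  if (!file.exists(path)) lp_abort(paste0("no such file: ", path), "io_error")
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- c("population", "source", "dt_ms", "t0_ms")
  if (!all(meta %in% names(tb))) {
    lp_abort("rate file needs columns population, source, dt_ms, t0_ms.", "io_error")
  }
  vals <- as.matrix(tb[setdiff(names(tb), meta)])
  rate_matrix(vals, dt_ms = tb$dt_ms[1], t0_ms = tb$t0_ms[1],
              populations = tb$population, source = tb$source)
}

#' @rdname read_rates
#' @param rates a [rate_matrix()].
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "rate_matrix"))
  vals <- as.data.frame(unclass(rates))
  names(vals) <- paste0("b", seq_len(ncol(vals)))
  tb <- dplyr::bind_cols(
    tibble(population = rownames(rates), source = rate_source(rates),
           dt_ms = rec_dt(rates), t0_ms = rec_t0(rates)),
    vals
  )
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles every tunable of the decomposition pipeline: the assumed number of
#' laminar populations, the band-split filter, the CSD estimator, the
#' channel-sum penalty weight lambda, optimizer settings, the RNG seed, and the
#' search bounds for kernel and trapezoid parameters (ms and um).
#'
#' @param n_populations number of laminar populations assumed a priori (>= 1).
#' @param cutoff_hz band-split cutoff frequency (default 300 Hz).
#' @param filter_order Butterworth order (default 5).
#' @param csd_method `"delta_icsd"` or `"traditional"`.
#' @param disc_radius_um delta-iCSD disc radius (default 400 um).
#' @param lambda_penalty non-negative weight of the zero-sum CSD penalty.
#' @param optimizer list with `np` (population size; `NULL` means 10 x the
#'   number of free parameters), `maxiter`, `reltol` and `polish` (logical:
#'   run a local refinement from the differential-evolution optimum).
#' @param rng_seed integer seed controlling the stochastic search.
#' @param tau_bounds_ms,delta_bounds_ms kernel time-constant and delay bounds.
#' @param a_bounds_um,b_bounds_um trapezoid plateau and ramp width bounds.
#' @param smooth_ms Gaussian sd of the MUA envelope smoother, ms.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(n_populations,
                            cutoff_hz = 300,
                            filter_order = 5,
                            csd_method = c("delta_icsd", "traditional"),
                            disc_radius_um = 400,
                            lambda_penalty = 0,
                            optimizer = list(),
                            rng_seed = 1L,
                            tau_bounds_ms = c(1, 100),
                            delta_bounds_ms = c(0, 50),
                            a_bounds_um = c(0, 1000),
                            b_bounds_um = c(5, 500),
                            smooth_ms = 2) {
  csd_method <- match.arg(csd_method)
  if (!is_number(n_populations) || n_populations < 1 ||
      n_populations != round(n_populations)) {
    lp_abort("`n_populations` must be a positive integer.", "config_error")
  }
  if (!is_number(lambda_penalty) || lambda_penalty < 0) {
    lp_abort("`lambda_penalty` must be >= 0.", "config_error")
  }
  for (b in list(tau_bounds_ms, delta_bounds_ms, a_bounds_um, b_bounds_um)) {
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2]) {
      lp_abort("all bounds must be finite with min < max.", "config_error")
    }
  }
  if (tau_bounds_ms[1] <= 0) {
    lp_abort("`tau_bounds_ms` must be positive (tau > 0).", "config_error")
  }
  if (delta_bounds_ms[1] < 0 || b_bounds_um[1] <= 0 || a_bounds_um[1] < 0) {
    lp_abort("delay >= 0, plateau >= 0 and ramp > 0 are required.", "config_error")
  }
  opt <- utils::modifyList(
    list(np = NULL, maxiter = 250L, reltol = 1e-8, polish = TRUE),
    optimizer
  )
  structure(
    list(n_populations = as.integer(n_populations),
         cutoff_hz = cutoff_hz, filter_order = as.integer(filter_order),
         csd_method = csd_method, disc_radius_um = disc_radius_um,
         lambda_penalty = lambda_penalty, optimizer = opt,
         rng_seed = as.integer(rng_seed),
         tau_bounds_ms = as.numeric(tau_bounds_ms),
         delta_bounds_ms = as.numeric(delta_bounds_ms),
         a_bounds_um = as.numeric(a_bounds_um),
         b_bounds_um = as.numeric(b_bounds_um),
         smooth_ms = smooth_ms),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> N_pop = %d, cutoff = %g Hz (order %d), csd = %s, lambda = %g, seed = %d\n",
              x$n_populations, x$cutoff_hz, x$filter_order, x$csd_method,
              x$lambda_penalty, x$rng_seed))
  cat(sprintf("  tau in [%g, %g] ms, delta in [%g, %g] ms\n",
              x$tau_bounds_ms[1], x$tau_bounds_ms[2],
              x$delta_bounds_ms[1], x$delta_bounds_ms[2]))
  invisible(x)
}

#' Read / write an analysis configuration as YAML
#'
#' Keys mirror the arguments of [analysis_config()]; `overrides` (e.g. from
#' command-line flags) take precedence over file values.
#'
#' @param path YAML file.
#' @param overrides named list overriding file values.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path, overrides = list()) {
  if (!file.exists(path)) lp_abort(paste0("no such file: ", path), "io_error")
  y <- utils::modifyList(yaml::read_yaml(path), overrides)
  known <- names(formals(analysis_config))
  do.call(analysis_config, y[intersect(names(y), known)])
}

#' @rdname read_analysis_config
#' @param config an [analysis_config()].
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
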