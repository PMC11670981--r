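#' Channels-by-time signal matrix
#'
#' The basic signal container: a numeric matrix with channels as rows and time
#' bins as columns, a bin width `dt_ms`, the time of the first bin relative to
#' stimulus onset `t0_ms`, and a signal kind (`"ecp"`, `"mua"`, `"lfp"` or
#' `"csd"`). Values are in microvolts for potentials and in (planar) current
#' source density units for CSD.
#'
#' @param values numeric matrix, channels x bins, all finite, >= 2 bins.
#' @param dt_ms positive bin width in ms.
#' @param t0_ms time of the first bin relative to stimulus onset, ms.
#' @param kind one of `"ecp"`, `"mua"`, `"lfp"`, `"csd"`.
#' @param depths_um optional channel depths carried along for convenience.
#' @return a `recording_matrix`.
#' @examples
#' rm <- recording_matrix(matrix(rnorm(20), 4), dt_ms = 1, t0_ms = -5, kind = "ecp")
#' rec_times(rm)
#' @export
recording_matrix <- function(values, dt_ms, t0_ms = 0,
                             kind = c("ecp", "mua", "lfp", "csd"),
                             depths_um = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2) lp_abort("need at least 2 time bins.", "recording_error")
  if (any(!is.finite(values))) {
    lp_abort("recording values must all be finite.", "recording_error")
  }
  if (!is_number(dt_ms) || dt_ms <= 0) {
    lp_abort("`dt_ms` must be a positive number.", "recording_error")
  }
  if (!is_number(t0_ms)) lp_abort("`t0_ms` must be a number.", "recording_error")
  if (!is.null(depths_um) && length(depths_um) != nrow(values)) {
    lp_abort("`depths_um` length must equal the channel count.", "dimension_error")
  }
  structure(values, dt_ms = dt_ms, t0_ms = t0_ms, kind = kind,
            depths_um = depths_um,
            class = c("recording_matrix", "matrix", "array"))
}

#' @export
print.recording_matrix <- function(x, ...) {
  cat(sprintf("<recording_matrix:%s> %d channels x %d bins, dt = %g ms, t0 = %g ms\n",
              rec_kind(x), nrow(x), ncol(x), rec_dt(x), rec_t0(x)))
  invisible(x)
}

#' Accessors for recording / rate matrices
#'
#' @param x a [recording_matrix()] or [rate_matrix()].
#' @return `rec_dt()`, `rec_t0()` a number; `rec_kind()` a string;
#'   `rec_times()` the bin-centre time axis in ms.
#' @export
rec_dt <- function(x) attr(x, "dt_ms")

#' @rdname rec_dt
#' @export
rec_t0 <- function(x) attr(x, "t0_ms")

#' @rdname rec_dt
#' @export
rec_kind <- function(x) attr(x, "kind")

#' @rdname rec_dt
#' @export
rec_times <- function(x) rec_t0(x) + (seq_len(ncol(x)) - 1) * rec_dt(x)

# same time base? (dt, t0 and bin count)
same_timebase <- function(x, y) {
  isTRUE(all.equal(rec_dt(x), rec_dt(y))) &&
    isTRUE(all.equal(rec_t0(x), rec_t0(y))) &&
    ncol(x) == ncol(y)
}

#' Populations-by-time firing-rate matrix
#'
#' Holds one firing-rate (or MUA-scaled amplitude) time course per population.
#' Row names are the population labels; the `source` attribute records, per
#' row, whether the population is internal to the probed structure or an
#' external presynaptic structure.
#'
#' @param values numeric matrix, populations x bins.
#' @param dt_ms,t0_ms time base, as in [recording_matrix()].
#' @param populations character labels, one per row.
#' @param source `"internal"` or `"external"`, recycled across rows.
#' @return a `rate_matrix`.
#' @export
rate_matrix <- function(values, dt_ms, t0_ms = 0,
                        populations = NULL, source = "internal") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) {
    lp_abort("rate values must all be finite.", "recording_error")
  }
  if (!is_number(dt_ms) || dt_ms <= 0) {
    lp_abort("`dt_ms` must be a positive number.", "recording_error")
  }
  populations <- populations %||% rownames(values) %||%
    paste0("pop_", seq_len(nrow(values)))
  if (length(populations) != nrow(values)) {
    lp_abort("one population label per row is required.", "dimension_error")
  }
  source <- rep_len(source, nrow(values))
  if (!all(source %in% c("internal", "external"))) {
    lp_abort("`source` entries must be 'internal' or 'external'.", "recording_error")
  }
  rownames(values) <- populations
  structure(values, dt_ms = dt_ms, t0_ms = t0_ms, source = source,
            class = c("rate_matrix", "matrix", "array"))
}

#' @export
print.rate_matrix <- function(x, ...) {
  src <- attr(x, "source")
  cat(sprintf("<rate_matrix> %d populations (%d internal, %d external) x %d bins, dt = %g ms\n",
              nrow(x), sum(src == "internal"), sum(src == "external"),
              ncol(x), rec_dt(x)))
  cat("  populations:", paste(rownames(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname rec_dt
#' @export
rate_source <- function(x) attr(x, "source")

#' Multi-trial recording ensemble
#'
#' A list of same-shaped trials of one signal kind, stimulus-aligned on a
#' common time base, with the probe geometry attached.
#'
#' @param trials list of channels x bins numeric matrices, identical shapes.
#' @param geometry a [probe_geometry()]; channel count must match.
#' @param dt_ms,t0_ms,kind as in [recording_matrix()].
#' @param units free-text unit label kept as metadata (default `"uV"`).
#' @return a `trial_ensemble`.
#' @export
trial_ensemble <- function(trials, geometry, dt_ms, t0_ms = 0,
                           kind = c("ecp", "mua", "lfp", "csd"), units = "uV") {
  kind <- match.arg(kind)
  stopifnot(inherits(geometry, "probe_geometry"))
  if (!is.list(trials) || length(trials) == 0) {
    lp_abort("`trials` must be a non-empty list of matrices.", "recording_error")
  }
  trials <- lapply(trials, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  dims <- vapply(trials, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    lp_abort("all trials must share the same channels x bins shape.", "dimension_error")
  }
  if (dims[1, 1] != n_channels(geometry)) {
    lp_abort(sprintf("trial has %d rows but geometry has %d channels.",
                     dims[1, 1], n_channels(geometry)), "dimension_error")
  }
  structure(list(trials = trials, geometry = geometry, dt_ms = dt_ms,
                 t0_ms = t0_ms, kind = kind, units = units),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble:%s> %d trials, %d channels x %d bins, dt = %g ms, t0 = %g ms (%s)\n",
              x$kind, length(x$trials), nrow(x$trials[[1]]), ncol(x$trials[[1]]),
              x$dt_ms, x$t0_ms, x$units))
  invisible(x)
}

#' Number of trials in an ensemble
#' @param x a [trial_ensemble()].
#' @return integer.
#' @export
n_trials <- function(x) {
  stopifnot(inherits(x, "trial_ensemble"))
  length(x$trials)
}

#' Tidy a signal matrix into a long tibble
#'
#' @param x a [recording_matrix()].
#' @param ... unused.
#' @return tibble with columns `channel`, `depth_um` (if known), `time_ms`,
#'   `value`.
#' @export
tidy.recording_matrix <- function(x, ...) {
  tb <- tibble(
    channel = rep(seq_len(nrow(x)), times = ncol(x)),
    time_ms = rep(rec_times(x), each = nrow(x)),
    value = as.numeric(unclass(x))
  )
  d <- attr(x, "depths_um")
  if (!is.null(d)) tb <- dplyr::mutate(tb, depth_um = d[.data$channel],
                                       .after = "channel")
  tb
}

#' @rdname tidy.recording_matrix
#' @export
tidy.rate_matrix <- function(x, ...) {
  tibble(
    population = rep(rownames(x), times = ncol(x)),
    source = rep(attr(x, "source"), times = ncol(x)),
    time_ms = rep(rec_times(x), each = nrow(x)),
    rate = as.numeric(unclass(x))
  )
}
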