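# Causal exponential postsynaptic kernels and rate-to-field convolution.

#' Causal exponential postsynaptic kernel
#'
#' Samples `h(t) = (1/tau) exp(-(t - delta)/tau)` for `t >= delta`, 0 before
#' (causality). On a grid long relative to `tau` the kernel mass
#' `sum(h) * dt` approaches 1, so convolution preserves the scale of a steady
#' firing rate.
#'
#' @param tau_ms time constant, ms (> 0).
#' @param delta_ms delay, ms (>= 0).
#' @param dt_ms bin width, ms.
#' @param n_bins number of samples.
#' @param integrated return bin-averaged values instead of point samples.
#' @return numeric vector of length `n_bins` (kernel at t = 0, dt, ...).
#' With `integrated = TRUE` the kernel is averaged over each time bin
#' (`h_m = (1/dt) * integral of h over [t_m, t_m + dt)`), which is what the
#' convolution machinery uses: it agrees with the point samples as
#' `dt -> 0` but varies continuously with `delta_ms`, keeping the kernel-fit
#' cost surface smooth.
#'
#' @examples
#' h <- exp_kernel(tau_ms = 5, delta_ms = 3, dt_ms = 1, n_bins = 50)
#' h[4]  # t = 3 ms: 1/tau = 0.2
#' @export
exp_kernel <- function(tau_ms, delta_ms, dt_ms, n_bins, integrated = FALSE) {
  if (!is_number(tau_ms) || tau_ms <= 0) {
    lp_abort("`tau_ms` must be positive.", "parameter_error")
  }
  if (!is_number(delta_ms) || delta_ms < 0) {
    lp_abort("`delta_ms` must be >= 0.", "parameter_error")
  }
  t <- (seq_len(n_bins) - 1) * dt_ms
  if (!integrated) {
    return(ifelse(t >= delta_ms, exp(-(t - delta_ms) / tau_ms) / tau_ms, 0))
  }
  lo <- pmax(t, delta_ms)
  hi <- t + dt_ms
  ifelse(hi > delta_ms,
         (exp(-(lo - delta_ms) / tau_ms) - exp(-(hi - delta_ms) / tau_ms)) / dt_ms,
         0)
}

#' Kernel parameter table
#'
#' @param tau_ms,delta_ms numeric vectors, one entry per population.
#' @param populations labels (default `pop_<k>`).
#' @return tibble with columns `population`, `tau_ms`, `delta_ms`.
#' @export
kernel_params <- function(tau_ms, delta_ms, populations = NULL) {
  if (length(tau_ms) != length(delta_ms)) {
    lp_abort("`tau_ms` and `delta_ms` must have the same length.",
             "dimension_error")
  }
  if (any(tau_ms <= 0) || any(delta_ms < 0)) {
    lp_abort("need tau > 0 and delta >= 0.", "parameter_error")
  }
  tibble(population = populations %||% paste0("pop_", seq_along(tau_ms)),
         tau_ms = as.numeric(tau_ms), delta_ms = as.numeric(delta_ms))
}

# causal convolution of one rate trace with the bin-integrated exponential
# kernel, scaled by dt. Past the (possibly partial) first bin the integrated
# kernel obeys the AR(1) recursion h[m+1] = h[m] * exp(-dt/tau), so the cost
# is O(B); the result matches the naive O(B^2) sum with the same kernel.
convolve_exp <- function(r, tau_ms, delta_ms, dt_ms) {
  n <- length(r)
  m0 <- floor(delta_ms / dt_ms) + 1L   # first bin whose interval passes delta
  if (m0 > n) return(numeric(n))
  t0 <- (m0 - 1) * dt_ms
  alpha <- exp(-dt_ms / tau_ms)
  h0 <- (exp(-(max(t0, delta_ms) - delta_ms) / tau_ms) -
           exp(-(t0 + dt_ms - delta_ms) / tau_ms)) / dt_ms
  shift <- function(s) if (s == 0) r else c(numeric(s), r[seq_len(n - s)])
  y <- h0 * shift(m0 - 1L)
  if (m0 < n) {
    h1 <- exp(-(m0 * dt_ms - delta_ms) / tau_ms) * (1 - alpha) / dt_ms
    y <- y + as.numeric(stats::filter(h1 * shift(m0), alpha,
                                      method = "recursive"))
  }
  dt_ms * y
}

#' Postsynaptic temporal profiles
#'
#' Convolves each population's firing rate with its own causal exponential
#' kernel (`R_est = h (*) r`, truncated to the recording length and scaled by
#' the bin width so kernel mass is dimensionless).
#'
#' @param rates a [rate_matrix()] (populations x bins).
#' @param kernels a [kernel_params()] table aligned with the rate rows (matched
#'   by population label when present, by order otherwise).
#' @return a [rate_matrix()] of postsynaptic temporal profiles.
#' @export
postsynaptic_profiles <- function(rates, kernels) {
  stopifnot(inherits(rates, "rate_matrix"))
  k <- as_tibble(kernels)
  if (nrow(k) != nrow(rates)) {
    lp_abort("one kernel per population is required.", "dimension_error")
  }
  if ("population" %in% names(k) && all(rownames(rates) %in% k$population)) {
    k <- k[match(rownames(rates), k$population), ]
  }
  out <- matrix(0, nrow(rates), ncol(rates))
  for (n in seq_len(nrow(rates))) {
    out[n, ] <- convolve_exp(unclass(rates)[n, ], k$tau_ms[n], k$delta_ms[n],
                             rec_dt(rates))
  }
  rate_matrix(out, rec_dt(rates), rec_t0(rates),
              populations = rownames(rates), source = rate_source(rates))
}
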