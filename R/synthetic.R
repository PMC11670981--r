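# Forward-model ground-truth generator: laminar probe, trapezoid populations,
# evoked firing rates with controllable inter-population synchrony, balanced
# sink/source field profiles, and MUA/CSD/LFP/spikes with stored truth.

#' Configuration of the synthetic laminar recording
#'
#' Defaults emulate a desk-scale laminar probe recording: 26 channels at 40 um
#' spacing spanning ~1000 um across five cortical layers (L1, L2/3, L4, L5,
#' L6), 750 ms stimulus-aligned trials (onset at 0 ms, a 250 ms stimulus,
#' 100 ms pre-stimulus baseline) at 1 ms resolution, 10 trials, evoked
#' firing-rate transients peaking ~50 ms after stimulus onset and offset,
#' three external presynaptic structures (feedforward "LGN", feedback "FB",
#' and a weak diffuse background "BKG"), and noise-free signals.
#'
#' @param n_trials trials per condition.
#' @param dt_ms,t0_ms,n_bins time base (defaults 1 ms, -100 ms, 750 bins).
#' @param stim_on_ms,stim_off_ms stimulus onset/offset, ms.
#' @param latency_ms mean evoked-transient latency after onset/offset.
#' @param rho inter-population rate synchrony in `[0, 1]`: 0 gives private
#'   evoked responses per population, 1 makes all internal rates share one
#'   temporal profile (identical up to amplitude).
#' @param noise_sd_mua,noise_sd_csd additive Gaussian noise sd, as a fraction
#'   of the peak |signal| (default 0: noise-free).
#' @param imbalance channel-sum imbalance injected into one population's field
#'   profile (0 = all profiles exactly charge-balanced).
#' @param imbalance_population population receiving the imbalance.
#' @param n_cells cells per population for Poisson spike generation.
#' @param seed RNG seed.
#' @return a `synth_config` list (geometry, populations, rate and kernel
#'   tables included).
#' @export
synth_config <- function(n_trials = 10, dt_ms = 1, t0_ms = -100, n_bins = 750,
                         stim_on_ms = 0, stim_off_ms = 250, latency_ms = 50,
                         rho = 0, noise_sd_mua = 0, noise_sd_csd = 0,
                         imbalance = 0, imbalance_population = "LGN",
                         n_cells = 50, seed = 1L) {
  if (!is_number(rho) || rho < 0 || rho > 1) {
    lp_abort("`rho` must lie in [0, 1].", "parameter_error")
  }
  layers <- tibble(
    layer = c("L1", "L2/3", "L4", "L5", "L6"),
    top_um = c(0, 100, 340, 540, 780),
    bottom_um = c(100, 340, 540, 780, 1040)
  )
  geometry <- probe_geometry(seq(20, 1020, by = 40), sigma_s_per_m = 0.3,
                             disc_radius_um = 400, layers = layers)
  # one trapezoid per layer, covering every contact of the layer and reaching
  # 15 um into the 40 um inter-layer gap -> supports stay pairwise disjoint
  pops <- tibble(
    population = layers$layer,
    z_um = c(40, 200, 420, 640, 900),
    a_um = c(30, 150, 110, 150, 190),
    b_um = c(20, 40, 40, 40, 40)
  )
  internal <- tibble(
    population = layers$layer,
    amplitude = c(30, 55, 70, 45, 35),        # spikes/s scale of the evoked peak
    latency_ms = latency_ms + c(-15, -7, 0, 8, 16),
    width_ms = c(8, 11, 14, 17, 20),
    offset_gain = c(0.5, 0.6, 0.8, 0.7, 0.55),
    tau_ms = c(6, 9, 12, 15, 18),
    delta_ms = c(2, 4, 6, 8, 10)
  )
  external <- tibble(
    population = c("LGN", "FB", "BKG"),
    amplitude = c(80, 40, 10),
    latency_ms = c(30, 75, NA),               # BKG carries no evoked transient
    width_ms = c(6, 20, NA),
    offset_gain = c(0.9, 0.6, NA),
    tau_ms = c(4, 20, 30),
    delta_ms = c(1, 8, 3)
  )
  structure(
    list(geometry = geometry, populations = pops, internal = internal,
         external = external, n_trials = n_trials, dt_ms = dt_ms,
         t0_ms = t0_ms, n_bins = n_bins, stim_on_ms = stim_on_ms,
         stim_off_ms = stim_off_ms, rho = rho,
         noise_sd_mua = noise_sd_mua, noise_sd_csd = noise_sd_csd,
         imbalance = imbalance, imbalance_population = imbalance_population,
         n_cells = n_cells, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# alpha-function evoked transient peaking `width` ms after `latency`
alpha_transient <- function(t, latency, width) {
  x <- (t - latency) / width
  ifelse(x > 0, x * exp(1 - x), 0)
}

#' Generate population firing rates
#'
#' Every internal population's rate is a baseline plus alpha-function
#' transients after stimulus onset and offset:
#' `r_n(t) = A_n * max(0, (1 - rho) * private_n(t) + rho * shared(t))`.
#' The private component has population-specific latency, width and smooth
#' noise; the shared component is one common template, so pairwise rate
#' correlation increases monotonically with the synchrony `rho` and at
#' `rho = 1` all internal rates are identical up to amplitude. External
#' structures (feedforward, feedback, background) are generated independently
#' of `rho`.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a [rate_matrix()] with internal rows first, labelled by source.
#' @export
make_rates <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  t <- config$t0_ms + (seq_len(config$n_bins) - 1) * config$dt_ms
  on <- config$stim_on_ms; off <- config$stim_off_ms
  base0 <- 0.2
  smooth_noise <- function(sd) gaussian_smooth(rnorm(length(t), sd = sd), 5)
  shared <- base0 +
    alpha_transient(t, on + 50, 14) + 0.7 * alpha_transient(t, off + 50, 14) +
    smooth_noise(0.04)
  int <- config$internal
  internal <- t(vapply(seq_len(nrow(int)), function(n) {
    private <- base0 +
      alpha_transient(t, on + int$latency_ms[n], int$width_ms[n]) +
      int$offset_gain[n] * alpha_transient(t, off + int$latency_ms[n],
                                           int$width_ms[n]) +
      smooth_noise(0.04)
    int$amplitude[n] *
      pmax(0, (1 - config$rho) * private + config$rho * shared)
  }, numeric(length(t))))
  ext <- config$external
  external <- t(vapply(seq_len(nrow(ext)), function(n) {
    shape <- if (is.na(ext$latency_ms[n])) {
      # background: constant-rate drive whose rate trace, as in practice, is
      # estimated from spikes -- trial-averaged binned counts keep fast
      # stochastic fluctuations around the mean after light smoothing
      base0 * (1 + 0.15 * gaussian_smooth(rnorm(length(t)), 2))
    } else {
      base0 + alpha_transient(t, on + ext$latency_ms[n], ext$width_ms[n]) +
        ext$offset_gain[n] * alpha_transient(t, off + ext$latency_ms[n],
                                             ext$width_ms[n]) +
        smooth_noise(0.04)
    }
    ext$amplitude[n] * pmax(0, shape)
  }, numeric(length(t))))
  rate_matrix(rbind(internal, external), config$dt_ms, config$t0_ms,
              populations = c(int$population, ext$population),
              source = rep(c("internal", "external"),
                           c(nrow(int), nrow(ext))))
}

#' Charge-balanced per-population field profiles
#'
#' Builds one signed sink/source depth profile per presynaptic population as a
#' Gaussian sink paired with a Gaussian source whose amplitude is chosen so
#' the profile's channel sum is exactly zero (a discrete dipole). A nonzero
#' `config$imbalance` adds an unbalanced bump of that relative magnitude to
#' one population's profile, giving the total CSD a nonzero channel sum for
#' penalty experiments.
#'
#' @param config a [synth_config()].
#' @return channels x populations matrix `L_true` (internal then external
#'   columns), in CSD units.
#' @export
make_balanced_profiles <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  z <- config$geometry$depths_um
  dip <- function(sink_um, sep_um = 160, width_um = 60, gain = 1) {
    g1 <- exp(-((z - sink_um)^2) / (2 * width_um^2))
    g2 <- exp(-((z - sink_um - sep_um)^2) / (2 * width_um^2))
    p <- -g1 + (sum(g1) / sum(g2)) * g2    # exact zero channel sum
    gain * p
  }
  sinks <- c(60, 220, 430, 650, 880,        # internal: within own layer
             440, 80, 500)                  # LGN mid-depth, FB superficial, BKG broad
  seps <- c(120, 160, 160, 160, 120, 200, 180, 300)
  widths <- c(40, 60, 60, 60, 60, 60, 50, 200)
  gains <- c(1, 1, 1, 1, 1, 1.2, 1, 0.15)
  labels <- c(config$internal$population, config$external$population)
  l_true <- vapply(seq_along(labels), function(k) {
    dip(sinks[k], seps[k], widths[k], gains[k])
  }, numeric(length(z)))
  colnames(l_true) <- labels
  if (config$imbalance != 0) {
    k <- match(config$imbalance_population, labels)
    if (is.na(k)) {
      lp_abort("`imbalance_population` is not a known population.",
               "parameter_error")
    }
    bump <- exp(-((z - sinks[k])^2) / (2 * widths[k]^2))
    l_true[, k] <- l_true[, k] +
      config$imbalance * max(abs(l_true[, k])) * bump / max(bump)
  }
  l_true
}

#' Generate a full synthetic recording with stored ground truth
#'
#' Applies the forward model: MUA from the trapezoid spatial profiles and
#' internal rates, per-population CSD contributions from the balanced field
#' profiles and kernel-convolved rates, total CSD as their (optionally noisy)
#' sum, LFP from the CSD via the disc forward model, and inhomogeneous
#' Poisson spike trains realizing the rates. Everything needed to score a
#' decomposition is kept: the stored per-population contributions sum to the
#' stored noise-free total CSD exactly.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return an `lpa_synth_truth` with fields `geometry`, `populations` (with
#'   layer labels), `rates`, `kernels`, `profiles`, `contributions`,
#'   `csd_clean`, `mua`, `csd`, `lfp`, `spikes`, `config`.
#' @export
make_recordings <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  geom <- config$geometry
  rates <- make_rates(config, seed = seed)
  l_true <- make_balanced_profiles(config)
  kernels <- kernel_params(
    c(config$internal$tau_ms, config$external$tau_ms),
    c(config$internal$delta_ms, config$external$delta_ms),
    populations = rownames(rates))
  pops <- assign_layers(population_model(config$populations, geom), geom)
  m <- build_spatial_matrix(pops, geom)

  internal_rows <- rate_source(rates) == "internal"
  mua_clean <- t(m) %*% unclass(rates)[internal_rows, , drop = FALSE]
  r_post <- postsynaptic_profiles(rates, kernels)
  rec <- reconstruct_signal(l_true, r_post, contributions = TRUE)

  set.seed(seed + 1L)
  noise <- function(mat, frac) {
    if (frac <= 0) return(mat)
    mat + rnorm(length(mat), sd = frac * max(abs(mat)))
  }
  mua_vals <- noise(mua_clean, config$noise_sd_mua)
  mua_vals[mua_vals < 0] <- 0
  mua <- recording_matrix(mua_vals,
                          config$dt_ms, config$t0_ms, "mua",
                          depths_um = geom$depths_um)
  csd_vals <- noise(rec$total, config$noise_sd_csd)
  csd <- recording_matrix(csd_vals, config$dt_ms, config$t0_ms, "csd",
                          depths_um = geom$depths_um)
  lfp <- forward_lfp_from_csd(csd, geom)
  spikes <- draw_poisson_spikes(rates, config)

  structure(
    list(geometry = geom, populations = pops, rates = rates,
         kernels = kernels, profiles = l_true,
         contributions = rec$contributions,
         csd_clean = recording_matrix(rec$total, config$dt_ms, config$t0_ms,
                                      "csd", depths_um = geom$depths_um),
         mua = mua, csd = csd, lfp = lfp, spikes = spikes,
         config = config, seed = as.integer(seed)),
    class = "lpa_synth_truth"
  )
}

#' @export
print.lpa_synth_truth <- function(x, ...) {
  cat(sprintf("<lpa_synth_truth> %d channels x %d bins, %d internal + %d external populations, rho = %g, seed = %d\n",
              nrow(x$mua), ncol(x$mua), sum(rate_source(x$rates) == "internal"),
              sum(rate_source(x$rates) == "external"), x$config$rho, x$seed))
  invisible(x)
}

# inhomogeneous Poisson spike trains realizing the population rates
draw_poisson_spikes <- function(rates, config) {
  v <- unclass(rates)
  t <- rec_t0(rates) + (seq_len(ncol(v)) - 1) * rec_dt(rates)
  dt_s <- rec_dt(rates) / 1000
  out <- vector("list", nrow(v) * config$n_trials)
  idx <- 1L
  for (n in seq_len(nrow(v))) {
    lam <- pmax(0, v[n, ]) * config$n_cells * dt_s
    for (trial in seq_len(config$n_trials)) {
      counts <- rpois(length(lam), lam)
      nz <- which(counts > 0)
      if (length(nz) > 0) {
        times <- rep(t[nz], counts[nz]) +
          runif(sum(counts[nz]), 0, rec_dt(rates))
        out[[idx]] <- tibble(population_id = rownames(v)[n],
                             trial = as.integer(trial), time_ms = times)
        idx <- idx + 1L
      }
    }
  }
  ev <- dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
  dplyr::arrange(ev, .data$population_id, .data$trial, .data$time_ms)
}
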