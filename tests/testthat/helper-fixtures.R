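# Small fixtures shared across test files; everything is generated in code.

# uniform toy probe, no layers
toy_geometry <- function(n_ch = 6, spacing = 40, sigma = 0.3, radius = 400) {
  probe_geometry(seq(spacing, by = spacing, length.out = n_ch),
                 sigma_s_per_m = sigma, disc_radius_um = radius)
}

# the default 26-channel probe with layer boundaries
default_geometry <- function() synth_config()$geometry

toy_recording <- function(values, dt = 1, t0 = 0, kind = "csd") {
  recording_matrix(values, dt_ms = dt, t0_ms = t0, kind = kind)
}

# two disjoint trapezoid populations on the toy probe
toy_populations <- function() {
  population_model(tibble::tibble(
    population = c("upper", "lower"),
    z_um = c(70, 200), a_um = c(40, 40), b_um = c(20, 20)
  ))
}

# tiny synthetic problem for fast end-to-end fits: 3 populations on a
# 12-channel probe, 200 bins
tiny_truth <- function(seed = 1, n_ch = 12, n_bins = 200) {
  geom <- probe_geometry(seq(20, by = 40, length.out = n_ch))
  pops <- population_model(tibble::tibble(
    population = c("A", "B", "C"),
    z_um = c(60, 220, 390), a_um = c(70, 70, 80), b_um = c(25, 25, 25)
  ), geom)
  set.seed(seed)
  t <- 0:(n_bins - 1)
  rates <- rbind(
    5 + 40 * laminpop:::alpha_transient(t, 30, 8),
    5 + 55 * laminpop:::alpha_transient(t, 55, 12),
    5 + 30 * laminpop:::alpha_transient(t, 80, 18)
  ) + matrix(abs(rnorm(3 * n_bins, sd = 0.3)), 3)
  rates <- rate_matrix(rates, dt_ms = 1, populations = pops$population)
  m <- build_spatial_matrix(pops, geom)
  mua <- recording_matrix(t(m) %*% unclass(rates), 1, 0, "mua",
                          depths_um = geom$depths_um)
  kernels <- kernel_params(c(5, 10, 20), c(2, 6, 11),
                           populations = pops$population)
  z <- geom$depths_um
  l_true <- vapply(c(100, 260, 420), function(zc) {
    g1 <- exp(-((z - zc)^2) / (2 * 50^2))
    g2 <- exp(-((z - zc - 120)^2) / (2 * 50^2))
    -g1 + (sum(g1) / sum(g2)) * g2
  }, numeric(n_ch))
  colnames(l_true) <- pops$population
  r_post <- postsynaptic_profiles(rates, kernels)
  rec <- reconstruct_signal(l_true, r_post, contributions = TRUE)
  list(geom = geom, pops = pops, rates = rates, m = m, mua = mua,
       kernels = kernels, l_true = l_true, r_post = r_post,
       contributions = rec$contributions,
       csd = recording_matrix(rec$total, 1, 0, "csd",
                              depths_um = geom$depths_um))
}

fast_config <- function(n_pop, seed = 1, ...) {
  analysis_config(n_pop, rng_seed = seed,
                  optimizer = list(maxiter = 120, np = 60), ...)
}
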