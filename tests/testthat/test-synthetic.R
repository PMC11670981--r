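test_that("ground-truth bookkeeping: contributions sum to the clean CSD exactly", {
  tr <- make_recordings(synth_config(seed = 21))
  expect_identical(Reduce(`+`, tr$contributions), unclass(tr$csd_clean),
                   ignore_attr = TRUE)
  expect_true(all(is.finite(unclass(tr$mua))))
  expect_true(all(unclass(tr$mua) >= 0))
  # noise-free: stored CSD equals the clean CSD and the LFP inverts back to it
  expect_identical(unclass(tr$csd), unclass(tr$csd_clean))
  expect_lt(max(abs(unclass(delta_icsd(tr$lfp, tr$geometry)) -
                      unclass(tr$csd))), 1e-9)
})

test_that("generation is deterministic for a fixed seed", {
  a <- make_recordings(synth_config(seed = 33))
  b <- make_recordings(synth_config(seed = 33))
  expect_identical(unclass(a$mua), unclass(b$mua))
  expect_identical(unclass(a$rates), unclass(b$rates))
  expect_identical(as.data.frame(a$spikes), as.data.frame(b$spikes))
  c <- make_recordings(synth_config(seed = 34))
  expect_false(identical(as.data.frame(a$spikes), as.data.frame(c$spikes)))
})

test_that("synchrony rho controls pairwise rate correlation monotonically", {
  mean_pair_cor <- function(rho) {
    r <- make_rates(synth_config(rho = rho, seed = 11))
    v <- unclass(r)[rate_source(r) == "internal", ]
    cm <- cor(t(v))
    mean(cm[upper.tri(cm)])
  }
  cors <- vapply(c(0, 0.3, 0.6, 0.9, 1), mean_pair_cor, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[4], 0.8)               # rho = 0.9: the "all above 0.83" regime
  # rho = 1: all internal rates identical up to amplitude
  r1 <- make_rates(synth_config(rho = 1, seed = 11))
  v1 <- unclass(r1)[rate_source(r1) == "internal", ]
  v1 <- v1 / apply(v1, 1, max)
  expect_lt(max(abs(sweep(v1, 2, v1[1, ]))), 1e-12)
})

test_that("synchrony worsens the conditioning of the postsynaptic profiles", {
  kappa_at <- function(rho) {
    cfg <- synth_config(rho = rho, seed = 11)
    tr <- make_recordings(cfg)
    int <- rate_source(tr$rates) == "internal"
    r_post <- postsynaptic_profiles(tr$rates, tr$kernels)
    laminpop:::condition_number(unclass(r_post)[int, ])
  }
  kappas <- vapply(c(0, 0.5, 0.9, 0.99), kappa_at, numeric(1))
  expect_true(all(diff(kappas) > 0))
  expect_gt(kappas[4] / kappas[1], 10)
})

test_that("balanced profiles have zero channel sum; imbalance breaks it", {
  cfg <- synth_config(seed = 2)
  l <- make_balanced_profiles(cfg)
  expect_equal(max(abs(colSums(l))), 0, tolerance = 1e-12)
  tr <- make_recordings(cfg)
  expect_lt(channel_sum_deviation(tr$csd), 1e-12)
  for (nm in names(tr$contributions)) {
    expect_lt(channel_sum_deviation(toy_recording(tr$contributions[[nm]])),
              1e-9)
  }
  cfg_imb <- synth_config(imbalance = 0.3, seed = 2)
  tr_imb <- make_recordings(cfg_imb)
  expect_gt(channel_sum_deviation(tr_imb$csd), 0.01)
  # a dipole profile produces an antisymmetric-looking, zero-sum forward LFP
  lfp <- forward_lfp_from_csd(tr$csd, tr$geometry)
  expect_true(all(is.finite(unclass(lfp))))
})

test_that("evoked transients peak ~latency+width after stimulus onset and offset", {
  tr <- make_recordings(synth_config(seed = 8))
  t <- rec_times(tr$rates)
  r_l4 <- unclass(tr$rates)["L4", ]
  onset_window <- t >= 0 & t < 150
  pk <- t[onset_window][which.max(r_l4[onset_window])]
  expect_gt(pk, 30); expect_lt(pk, 100)
  offset_window <- t >= 250 & t < 400
  pk2 <- t[offset_window][which.max(r_l4[offset_window])]
  expect_gt(pk2, 280); expect_lt(pk2, 350)
})

test_that("poisson spikes land in-window and realize the planted rates", {
  cfg <- synth_config(seed = 13, n_trials = 20)
  tr <- make_recordings(cfg)
  sp <- tr$spikes
  expect_true(all(sp$time_ms >= -100 & sp$time_ms < 650))
  expect_setequal(unique(sp$population_id), rownames(tr$rates))
  # empirical rate of one population tracks the planted rate
  r_hat <- firing_rate_from_spikes(
    dplyr::filter(sp, .data$population_id == "L4"), "L4",
    t0_ms = -100, n_bins = 750, n_trials = cfg$n_trials,
    cell_counts = c(L4 = cfg$n_cells))
  expect_gt(cor(unclass(r_hat)[1, ], unclass(tr$rates)["L4", ]), 0.9)
})
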