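test_that("band split keeps a 10 Hz tone in the LFP and rejects it from MUA", {
  dt <- 0.1                              # 10 kHz sampling
  t <- seq(0, 1000 - dt, by = dt)        # 1 s
  tone <- sin(2 * pi * 10 * t / 1000)
  ecp <- recording_matrix(rbind(tone, tone), dt, 0, "ecp")
  bands <- split_bands(ecp, cutoff_hz = 300, order = 5)
  mid <- 2000:8000                       # avoid filter edges
  ratio <- sd(unclass(bands$lfp)[1, mid]) / sd(tone[mid])
  expect_gt(ratio, 0.99)
  expect_lt(max(abs(unclass(bands$mua_raw)[1, mid])), 0.02)
})

test_that("band split sends a 1 kHz tone to MUA, attenuated > 20 dB in LFP", {
  dt <- 0.1
  t <- seq(0, 1000 - dt, by = dt)
  tone <- sin(2 * pi * 1000 * t / 1000)
  ecp <- recording_matrix(matrix(tone, 1, byrow = TRUE), dt, 0, "ecp")
  bands <- split_bands(ecp, 300, 5)
  mid <- 2000:8000
  expect_gt(sd(unclass(bands$mua_raw)[1, mid]) / sd(tone[mid]), 0.99)
  atten_db <- 20 * log10(sd(tone[mid]) / sd(unclass(bands$lfp)[1, mid]))
  expect_gt(atten_db, 20)
})

test_that("band powers of white noise add up to the total power", {
  set.seed(42)
  dt <- 0.5
  x <- rnorm(8000)
  ecp <- recording_matrix(matrix(x, 1), dt, 0, "ecp")
  bands <- split_bands(ecp, 300, 5)
  mid <- 500:7500
  p_tot <- mean(x[mid]^2)
  p_sum <- mean((unclass(bands$lfp)[1, mid] + unclass(bands$mua_raw)[1, mid])^2)
  # complementary 5th-order Butterworth pair overlaps slightly at the cutoff
  expect_equal(p_sum, p_tot, tolerance = 0.05)
})

test_that("filtering is zero-phase: no lag between input and passband output", {
  dt <- 0.1
  t <- seq(0, 500 - dt, by = dt)
  x <- sin(2 * pi * 40 * t / 1000)       # well inside the passband
  ecp <- recording_matrix(matrix(x, 1), dt, 0, "ecp")
  lfp <- unclass(split_bands(ecp, 300, 5)$lfp)[1, ]
  cc <- stats::ccf(x, lfp, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("cutoff at or above Nyquist is rejected", {
  ecp <- recording_matrix(matrix(rnorm(100), 1), 1, 0, "ecp")  # fs = 1 kHz
  expect_error(split_bands(ecp, 500, 5), class = "laminpop_parameter_error")
})

test_that("the MUA envelope rectifies and preserves flat signals", {
  z <- recording_matrix(matrix(0, 2, 100), 1, 0, "mua")
  expect_equal(unclass(mua_envelope(z)), matrix(0, 2, 100), ignore_attr = TRUE)
  a <- recording_matrix(matrix(3, 1, 100), 1, 0, "mua")
  expect_equal(unclass(mua_envelope(a))[1, ], rep(3, 100), tolerance = 1e-10)
  # alternating +-A square wave smoothed far beyond its period -> ~ A
  sq <- recording_matrix(matrix(rep(c(2, -2), 200), 1), 1, 0, "mua")
  env <- unclass(mua_envelope(sq, smooth_ms = 20))[1, ]
  expect_equal(env[50:350], rep(2, 301), tolerance = 1e-6)
  expect_error(mua_envelope(sq, smooth_ms = 0),
               class = "laminpop_parameter_error")
})

test_that("trial averaging is the element-wise mean with symmetry cases", {
  m <- matrix(rnorm(20), 4)
  tr <- toy_recording(m, kind = "mua")
  expect_equal(unclass(trial_average(list(tr, tr))), m, ignore_attr = TRUE)
  neg <- toy_recording(-m, kind = "mua")
  expect_equal(unclass(trial_average(list(tr, neg))), matrix(0, 4, 5),
               ignore_attr = TRUE)
  expect_error(trial_average(list()), class = "laminpop_parameter_error")
})

test_that("averaging 10 noisy trials shrinks residual noise like 1/sqrt(10)", {
  set.seed(7)
  template <- matrix(sin(seq(0, 6 * pi, length.out = 500)), 1)
  sigma <- 0.8
  reps <- 200
  resid_sd <- replicate(reps, {
    trials <- lapply(1:10, function(i) {
      toy_recording(template + matrix(rnorm(500, sd = sigma), 1), kind = "mua")
    })
    sd(unclass(trial_average(trials)) - template)
  })
  expect_equal(mean(resid_sd), sigma / sqrt(10), tolerance = 0.02)
})

test_that("firing rates: Poisson mean, mass conservation, unknown labels", {
  # homogeneous Poisson at 10 Hz, 1 cell, 100 trials of 1 s
  set.seed(11)
  ev <- dplyr::bind_rows(lapply(1:100, function(tr) {
    n <- rpois(1, 10)
    tibble::tibble(population_id = "p", trial = tr,
                   time_ms = runif(n, 0, 1000))
  }))
  r <- firing_rate_from_spikes(ev, "p", t0_ms = 0, n_bins = 1000,
                               n_trials = 100)
  expect_equal(mean(unclass(r)), 10, tolerance = 0.1 * 10)

  # a single spike smoothed into a unit-mass bump
  one <- tibble::tibble(population_id = "p", trial = 1L, time_ms = 100.2)
  r1 <- firing_rate_from_spikes(one, "p", t0_ms = 0, n_bins = 500,
                                n_trials = 1)
  mass <- sum(unclass(r1)) * 1 / 1000    # rate * dt integrates to spike count
  expect_equal(mass, 1, tolerance = 1e-6)
  expect_equal(which.max(unclass(r1)[1, ]), 101, tolerance = 1)

  # no spikes -> all-zero; unknown population -> error
  r0 <- firing_rate_from_spikes(one[0, ], c("p", "q"), t0_ms = 0, n_bins = 100)
  expect_equal(unclass(r0), matrix(0, 2, 100), ignore_attr = TRUE)
  bad <- tibble::tibble(population_id = "zz", trial = 1L, time_ms = 1)
  expect_error(firing_rate_from_spikes(bad, "p", 0, 100),
               class = "laminpop_parameter_error")
})

test_that("firing rates conserve total spike count across populations", {
  set.seed(3)
  ev <- tibble::tibble(
    population_id = sample(c("a", "b"), 400, replace = TRUE),
    trial = sample(1:5, 400, replace = TRUE),
    time_ms = runif(400, 50, 450))
  r <- firing_rate_from_spikes(ev, c("a", "b"), t0_ms = 0, n_bins = 500,
                               n_trials = 5)
  # sum over bins of rate * dt * n_trials = spikes per population
  recovered <- rowSums(unclass(r)) * (1 / 1000) * 5
  expect_equal(unname(recovered), as.numeric(table(ev$population_id)[c("a", "b")]),
               tolerance = 1e-6)
})
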