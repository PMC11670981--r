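test_that("fit_mua recovers planted trapezoids and rates on noise-free data", {
  tt <- tiny_truth(seed = 1)
  fit <- suppressWarnings(fit_mua(tt$mua, tt$geom, fast_config(3, seed = 2)))
  expect_lt(fit$e_m, 0.01)
  # recovered channel ownership matches the planted populations
  planted <- classify_channels(tt$pops, tt$geom)
  recovered <- classify_channels(fit$populations, tt$geom)
  map <- match(recovered$population, unique(recovered$population))
  expect_equal(map, match(planted$population, unique(planted$population)))
  # rates recovered up to the near-exact fit
  expect_gt(cor(as.numeric(unclass(fit$rates)), as.numeric(unclass(tt$rates))),
            0.999)
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 3)
})

test_that("a single population fits constant-depth MUA almost perfectly", {
  geom <- toy_geometry(8)
  mua <- recording_matrix(matrix(rep(4 + sin(1:100 / 9), each = 8), 8),
                          1, 0, "mua")
  cfg <- analysis_config(1, rng_seed = 3,
                         optimizer = list(maxiter = 80, np = 30))
  fit <- suppressWarnings(fit_mua(mua, geom, cfg))
  expect_lt(fit$e_m, 1e-4)
  # the lone trapezoid spans (essentially) the whole probe
  expect_true(all(fit$spatial > 0.9))
})

test_that("repeated fits with different optimizer seeds agree within tolerance", {
  tt <- tiny_truth(seed = 6)
  f1 <- suppressWarnings(fit_mua(tt$mua, tt$geom, fast_config(3, seed = 10)))
  f2 <- suppressWarnings(fit_mua(tt$mua, tt$geom, fast_config(3, seed = 20)))
  expect_lt(abs(f1$e_m - f2$e_m), 0.01)
})

test_that("fit_mua is deterministic for a fixed seed and rejects infeasible configs", {
  tt <- tiny_truth(seed = 2)
  cfg <- analysis_config(3, rng_seed = 5,
                         optimizer = list(maxiter = 30, np = 20))
  f1 <- suppressWarnings(fit_mua(tt$mua, tt$geom, cfg))
  f2 <- suppressWarnings(fit_mua(tt$mua, tt$geom, cfg))
  expect_identical(tidy(f1), tidy(f2))
  # too many wide populations for the probe span
  big <- analysis_config(30, a_bounds_um = c(100, 200), b_bounds_um = c(50, 80))
  expect_error(fit_mua(tt$mua, tt$geom, big), class = "laminpop_config_error")
})

test_that("fit_csd recovers planted kernels and contributions on the tiny fixture", {
  tt <- tiny_truth(seed = 3)
  fit <- suppressWarnings(fit_csd(tt$csd, tt$rates, fast_config(3, seed = 4)))
  k <- tidy(fit)
  expect_equal(k$tau_ms, tt$kernels$tau_ms, tolerance = 0.1)
  expect_equal(k$delta_ms, tt$kernels$delta_ms, tolerance = 0.1)
  mc <- match_contributions(fit$contributions, tt$contributions)
  expect_gt(min(mc$correlation), 0.95)
  # contributions sum to the reconstruction bit-exactly
  expect_identical(Reduce(`+`, fit$contributions), unclass(fit$fitted),
                   ignore_attr = TRUE)
  expect_true(all(c("e_c", "rel_mse", "penalty_term") %in% names(glance(fit))))
})

test_that("fit_csd with identical rate rows warns about collinearity", {
  tt <- tiny_truth(seed = 5)
  v <- unclass(tt$rates)
  v[2, ] <- v[1, ]
  v[3, ] <- v[1, ] * 2
  rates_bad <- rate_matrix(v, 1, populations = rownames(tt$rates))
  cfg <- analysis_config(3, rng_seed = 1,
                         optimizer = list(maxiter = 20, np = 20, polish = FALSE))
  expect_warning(fit_csd(tt$csd, rates_bad, cfg),
                 class = "laminpop_collinear")
})

test_that("lambda scan picks the deviation-minimizing penalty", {
  tt <- tiny_truth(seed = 7)
  # inject an imbalanced component so the penalty has something to remove
  imb <- outer(exp(-((tt$geom$depths_um - 260)^2) / (2 * 60^2)),
               unclass(tt$r_post)[2, ])
  csd_imb <- recording_matrix(unclass(tt$csd) + 0.5 * imb, 1, 0, "csd")
  cfg <- analysis_config(3, rng_seed = 2,
                         optimizer = list(maxiter = 40, np = 30, polish = FALSE))
  scan <- select_lambda(csd_imb, tt$rates, cfg, lambdas = c(0, 2, 4))
  expect_s3_class(tidy(scan), "tbl_df")
  dev <- scan$table$deviation
  expect_lte(dev[scan$table$lambda == scan$lambda_best][1], dev[1])
  expect_identical(scan$best_fit$lambda, scan$lambda_best)
})
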