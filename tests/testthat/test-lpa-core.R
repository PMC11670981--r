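test_that("trapezoid evaluation: plateau, ramp midpoint, outside support", {
  expect_equal(trapezoid_eval(0, z_um = 0, a_um = 100, b_um = 50), 1)
  expect_equal(trapezoid_eval(75, 0, 100, 50), 0.5)
  expect_equal(trapezoid_eval(200, 0, 100, 50), 0)
  # vectorized and symmetric
  expect_equal(trapezoid_eval(c(-75, 75), 0, 100, 50), c(0.5, 0.5))
  expect_error(trapezoid_eval(0, 0, 100, 0), class = "laminpop_parameter_error")
})

test_that("population model enforces non-overlap and probe span", {
  expect_error(population_model(tibble::tibble(
    z_um = c(100, 150), a_um = c(60, 60), b_um = c(30, 30))),
    class = "laminpop_overlap_error")
  g <- toy_geometry(6)  # span 40..240, padded by 40
  expect_error(population_model(tibble::tibble(
    z_um = 500, a_um = 40, b_um = 20), g),
    class = "laminpop_overlap_error")
  ok <- population_model(tibble::tibble(
    z_um = c(200, 70), a_um = c(40, 40), b_um = c(20, 20)), g)
  expect_equal(ok$population, c("pop_2", "pop_1"))  # reordered by depth
})

test_that("spatial matrix matches direct evaluation and flags empty rows", {
  g <- toy_geometry(6)
  pops <- toy_populations()
  m <- build_spatial_matrix(pops, g)
  # hand oracle: evaluate each trapezoid at each depth
  oracle <- t(sapply(seq_len(nrow(pops)), function(n) {
    sapply(g$depths_um, trapezoid_eval, z_um = pops$z_um[n],
           a_um = pops$a_um[n], b_um = pops$b_um[n])
  }))
  expect_equal(unname(m), oracle, tolerance = 1e-12)
  # disjoint supports -> each channel claimed by at most one population
  expect_true(all(colSums(m > 0) <= 1))
  # a trapezoid falling between channels yields a warning
  g2 <- probe_geometry(c(0, 200, 400))
  skinny <- population_model(tibble::tibble(z_um = 100, a_um = 10, b_um = 10))
  expect_warning(build_spatial_matrix(skinny, g2),
                 class = "laminpop_zero_support")
})

test_that("planted five-layer spatial matrix matches hand-computed weights", {
  g <- default_geometry()
  cfg <- synth_config()
  m <- build_spatial_matrix(population_model(cfg$populations, g), g)
  expect_equal(dim(m), c(5L, 26L))
  # every channel positive for exactly its own layer's population
  lab <- channel_layers(g)
  for (ch in 1:26) {
    expect_equal(names(which(m[, ch] > 0)), lab[ch])
  }
  # spot-check a ramp weight: L2/3 trapezoid (z 200, a 150, b 40) at 100 um
  expect_equal(unname(m["L2/3", 3]), 1 - (abs(100 - 200) - 75) / 40)
})

test_that("infer_rates is the least-squares solution (normal-equations oracle)", {
  # identity spatial matrix passes the signal through
  phi <- toy_recording(matrix(rnorm(12), 3), kind = "mua")
  r_id <- infer_rates(diag(3), phi)
  expect_equal(unclass(r_id), unclass(phi), tolerance = 1e-12,
               ignore_attr = TRUE)

  # exact factorization is recovered to machine precision
  set.seed(2)
  m <- rbind(c(1, 1, 0.5, 0, 0), c(0, 0, 0.2, 1, 1))
  r0 <- matrix(rnorm(2 * 30), 2)
  phi0 <- toy_recording(t(m) %*% r0, kind = "mua")
  expect_equal(unclass(infer_rates(m, phi0)), r0, tolerance = 1e-10,
               ignore_attr = TRUE)

  # noisy case equals (M M^T)^-1 M phi computed independently
  set.seed(3)
  m2 <- rbind(c(1, 0.5, 0), c(0, 0.3, 1))
  phi2 <- toy_recording(t(m2) %*% r0[, 1:10] + matrix(rnorm(30, sd = 0.1), 3),
                        kind = "mua")
  oracle <- solve(m2 %*% t(m2), m2 %*% unclass(phi2))
  expect_equal(unclass(infer_rates(m2, phi2)), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)

  # zero-support rows are named in the error
  m3 <- rbind(c(1, 1, 0), c(0, 0, 0))
  rownames(m3) <- c("ok", "empty")
  expect_error(infer_rates(m3, phi2), "empty",
               class = "laminpop_rank_error")
})

test_that("no alternative temporal matrix beats the pseudoinverse solution", {
  set.seed(8)
  m <- rbind(c(1, 0.7, 0.2, 0), c(0, 0.1, 0.9, 1))
  phi <- matrix(rnorm(4 * 25), 4)
  r_hat <- unclass(infer_rates(m, toy_recording(phi, kind = "mua")))
  base <- sum((phi - t(m) %*% r_hat)^2)
  for (k in 1:20) {
    alt <- r_hat + matrix(rnorm(length(r_hat), sd = 0.05), nrow(r_hat))
    expect_gte(sum((phi - t(m) %*% alt)^2), base)
  }
})

test_that("reconstruction equals the naive double loop and sums contributions", {
  set.seed(3)
  m <- matrix(runif(3 * 7), 3, 7)      # populations x channels
  r <- matrix(rnorm(3 * 11), 3, 11)
  rec <- reconstruct_signal(t(m), r, contributions = TRUE)
  oracle <- matrix(0, 7, 11)
  for (i in 1:7) for (j in 1:11) for (n in 1:3) {
    oracle[i, j] <- oracle[i, j] + m[n, i] * r[n, j]
  }
  expect_equal(rec$total, oracle, tolerance = 1e-12)
  expect_identical(Reduce(`+`, rec$contributions), rec$total)  # bit-exact
  # one population, unit profile, constant rate -> constant matrix
  one <- reconstruct_signal(matrix(1, 5, 1), matrix(1, 1, 6))
  expect_equal(one, matrix(1, 5, 6))
  expect_error(reconstruct_signal(matrix(1, 5, 2), matrix(1, 3, 6)),
               class = "laminpop_dimension_error")
})

test_that("relative MSE anchors: perfect, zero and doubled estimates", {
  x <- matrix(rnorm(20), 4)
  expect_equal(relative_mse(x, x), 0)
  expect_equal(relative_mse(x, 0 * x), 1)
  expect_equal(relative_mse(x, 2 * x), 1)
  expect_error(relative_mse(0 * x, x), class = "laminpop_parameter_error")
})

test_that("exponential kernel: causality, closed form, normalization", {
  h <- exp_kernel(tau_ms = 5, delta_ms = 3, dt_ms = 1, n_bins = 100)
  expect_equal(h[1:3], c(0, 0, 0))          # t < delta
  expect_equal(h[4], 0.2)                   # t = 3: 1/tau
  expect_equal(h[9], 0.2 * exp(-1))         # t = 8
  h2 <- exp_kernel(10, 0, 1, 1000)
  expect_equal(sum(h2) * 1, 1, tolerance = 0.06)  # Riemann overshoot ~ dt/(2 tau)
  hint <- exp_kernel(10, 0, 1, 5000, integrated = TRUE)
  expect_equal(sum(hint) * 1, 1, tolerance = 1e-10)  # bin-averaged: exact mass
  expect_error(exp_kernel(0, 1, 1, 10), class = "laminpop_parameter_error")
  expect_error(exp_kernel(5, -1, 1, 10), class = "laminpop_parameter_error")
})

test_that("postsynaptic convolution equals the naive O(B^2) oracle", {
  set.seed(5)
  b <- 120; dt <- 0.5
  r <- rate_matrix(matrix(abs(rnorm(2 * b)), 2), dt,
                   populations = c("x", "y"))
  k <- kernel_params(c(7, 13.3), c(2.6, 0), populations = c("x", "y"))
  out <- unclass(postsynaptic_profiles(r, k))
  for (n in 1:2) {
    h <- exp_kernel(k$tau_ms[n], k$delta_ms[n], dt, b, integrated = TRUE)
    naive <- sapply(seq_len(b), function(j) {
      sum(h[seq_len(j)] * unclass(r)[n, j - seq_len(j) + 1]) * dt
    })
    expect_equal(out[n, ], naive, tolerance = 1e-10)
  }
})

test_that("postsynaptic profiles: impulse response, steady state, causality", {
  b <- 300
  imp <- matrix(0, 1, b); imp[1, 50] <- 1
  r <- rate_matrix(imp, 1)
  k <- kernel_params(8, 4)
  out <- unclass(postsynaptic_profiles(r, k))[1, ]
  h <- exp_kernel(8, 4, 1, b, integrated = TRUE)
  expect_equal(out[50:b], h[1:(b - 49)] * 1, tolerance = 1e-10)
  expect_equal(out[1:49], rep(0, 49))       # nothing before the impulse
  # constant rate converges to the same constant (kernel mass 1)
  const <- rate_matrix(matrix(3, 1, 500), 1)
  out2 <- unclass(postsynaptic_profiles(const, kernel_params(10, 5)))[1, ]
  expect_equal(out2[200:500], rep(3, 301), tolerance = 1e-3)
})

test_that("spatial field inference recovers planted profiles and flags collinearity", {
  set.seed(6)
  r <- rate_matrix(rbind(sin(1:80 / 5) + 2, cos(1:80 / 7) + 2), 1,
                   populations = c("a", "b"))
  l0 <- matrix(rnorm(12 * 2), 12)
  field <- l0 %*% unclass(r)
  l_hat <- infer_spatial_field(field, r)
  expect_equal(unname(l_hat), l0, tolerance = 1e-10)
  # normal-equations oracle on a toy case
  oracle <- field %*% t(unclass(r)) %*% solve(unclass(r) %*% t(unclass(r)))
  expect_equal(unname(l_hat), unname(oracle), tolerance = 1e-8)
  # identical rows -> collinearity warning naming the pair
  r2 <- rate_matrix(rbind(sin(1:80 / 5) + 2, sin(1:80 / 5) + 2), 1,
                    populations = c("a", "b"))
  expect_warning(infer_spatial_field(field, r2), "near-collinear",
                 class = "laminpop_collinear")
  expect_silent(infer_spatial_field(field, r2, quiet = TRUE))
})

test_that("csd_cost reduces to relative MSE at lambda 0 and is affine in lambda", {
  set.seed(4)
  truth <- matrix(rnorm(40), 8)
  est <- truth + matrix(rnorm(40, sd = 0.2), 8)
  expect_identical(csd_cost(truth, est, 0), relative_mse(truth, est))
  dev <- channel_sum_deviation(toy_recording(est))
  lam <- c(0.5, 1, 2, 4)
  costs <- sapply(lam, function(l) csd_cost(truth, est, l))
  expect_equal(costs, relative_mse(truth, est) + lam * dev, tolerance = 1e-12)
  # perfect dipole estimate incurs no penalty at any lambda
  dip <- matrix(c(1, -1), 2, 10) * matrix(rnorm(10), 2, 10, byrow = TRUE)
  truth2 <- matrix(rnorm(20), 2)
  expect_equal(csd_cost(truth2, dip, 5), csd_cost(truth2, dip, 0))
})

test_that("appending external rates stacks rows, checks time base, standardizes", {
  int <- rate_matrix(matrix(1:8, 2), 1, populations = c("L4", "L5"))
  ext <- rate_matrix(matrix(8:1, 2) * 10, 1, populations = c("LGN", "FB"),
                     source = "external")
  both <- append_external_rates(int, ext)
  expect_equal(rownames(both), c("L4", "L5", "LGN", "FB"))
  expect_equal(rate_source(both), c("internal", "internal", "external", "external"))
  expect_identical(unclass(append_external_rates(int, NULL)), unclass(int))
  bad <- rate_matrix(matrix(1:8, 2), 2, populations = c("LGN", "FB"))
  expect_error(append_external_rates(int, bad),
               class = "laminpop_dimension_error")
  std <- append_external_rates(int, ext, standardize = TRUE)
  expect_equal(unname(apply(abs(unclass(std)), 1, max)), rep(1, 4))
})

test_that("merging populations sums or weight-averages grouped rows", {
  r <- rate_matrix(rbind(a = c(1, 2), b = c(3, 4), c = c(5, 6), x = c(9, 9)), 1,
                   populations = c("a", "b", "c", "x"),
                   source = c("internal", "internal", "internal", "external"))
  m <- merge_populations(r, list(upper = c("a", "b"), deep = "c"))
  expect_equal(unclass(m)["upper", ], c(4, 6))
  expect_equal(unclass(m)["deep", ], c(5, 6))
  expect_equal(unclass(m)["x", ], c(9, 9))   # external carried through
  # singleton groups are the identity on values
  ident <- merge_populations(r, list(a = "a", b = "b", c = "c"))
  expect_equal(unclass(ident)[1:3, ], unclass(r)[1:3, ])
  # equal rows merged with weights stay unchanged
  r2 <- rate_matrix(rbind(p = c(2, 2), q = c(2, 2)), 1,
                    populations = c("p", "q"))
  mw <- merge_populations(r2, list(pq = c("p", "q")), weights = c(p = 10, q = 30))
  expect_equal(unclass(mw)["pq", ], c(2, 2))
  expect_error(merge_populations(r, list(g1 = c("a", "b"))),
               class = "laminpop_parameter_error")
})

test_that("rescaling the data rescales rates but leaves profiles fixed (height-1 convention)", {
  tt <- tiny_truth(seed = 4)
  r1 <- infer_rates(tt$m, tt$mua)
  scaled <- recording_matrix(5 * unclass(tt$mua), 1, 0, "mua")
  r2 <- infer_rates(tt$m, scaled)
  expect_equal(unclass(r2), 5 * unclass(r1), tolerance = 1e-10)
})
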