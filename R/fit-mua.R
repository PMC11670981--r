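# Step 1 of the decomposition: fit non-overlapping trapezoid profiles to the
# MUA envelope with differential evolution.

# --- feasible reparameterization --------------------------------------------
# The stochastic search runs in a unit box u in [0,1]^(4N+1): N+1 inter-support
# gaps, N plateau widths and N ramp widths (plus a small floor keeping ramps
# positive). Scaling the widths so they tile the (padded) probe span exactly
# makes every candidate a valid, depth-ordered, non-overlapping layout -- no
# rejection sampling inside the optimizer.
layout_from_unit <- function(u, span_lo, span_hi, n_pop, b_floor = 0.02) {
  g <- u[seq_len(n_pop + 1)]
  a <- u[n_pop + 1 + seq_len(n_pop)]
  b <- b_floor + u[2 * n_pop + 1 + seq_len(n_pop)]
  total <- sum(g) + sum(a) + 2 * sum(b)
  s <- (span_hi - span_lo) / total
  g <- g * s; a <- a * s; b <- b * s
  lo <- span_lo + cumsum(c(0, a + 2 * b)[seq_len(n_pop)]) +
    cumsum(g[seq_len(n_pop)])
  tibble(population = paste0("pop_", seq_len(n_pop)),
         z_um = lo + b + a / 2, a_um = a, b_um = b)
}

# padded probe span used by the fit: one median inter-channel spacing beyond
# the outermost contacts, so edge channels can lie on a plateau.
fit_span <- function(geom) {
  pad <- stats::median(diff(geom$depths_um))
  range(geom$depths_um) + c(-pad, pad)
}

# contiguous segmentation of channels into n groups by time-course similarity:
# dynamic programming minimizing within-segment squared distance of the
# unit-normalized channel time courses. Returns the first channel of each
# segment. Used only to seed the global search with plausible layouts.
segment_channels <- function(phi, n_seg) {
  n <- nrow(phi)
  nrm <- sqrt(rowSums(phi^2))
  x <- phi / ifelse(nrm > 0, nrm, 1)
  cs <- apply(x, 2, cumsum)                       # cumulative sums per column
  seg_cost <- function(i, j) {                    # channels i..j
    k <- j - i + 1
    s <- cs[j, ] - if (i > 1) cs[i - 1, ] else 0
    k - sum(s^2) / k                              # ||x_c||^2 = 1 each
  }
  costm <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in i:n) costm[i, j] <- seg_cost(i, j)
  dp <- matrix(Inf, n_seg, n)
  back <- matrix(0L, n_seg, n)
  dp[1, ] <- costm[1, ]
  if (n_seg > 1) {
    for (k in 2:n_seg) {
      for (j in k:n) {
        cand <- dp[k - 1, (k - 1):(j - 1)] + costm[k:j, j]
        b <- which.min(cand)
        dp[k, j] <- cand[b]
        back[k, j] <- (k - 1) + b                 # first channel of segment k
      }
    }
  }
  starts <- integer(n_seg)
  j <- n
  for (k in rev(seq_len(n_seg))[seq_len(max(0, n_seg - 1))]) {
    starts[k] <- back[k, j]
    j <- starts[k] - 1
  }
  starts[1] <- 1L
  starts
}

# convert a contiguous channel segmentation into unit-box DE coordinates:
# plateaus cover each segment's contacts, ramps split the gaps between
# segments. Inverts the layout_from_unit() scaling exactly.
layout_to_unit <- function(starts, geom, span, ramp_frac = 0.45,
                           b_floor = 0.02) {
  d <- geom$depths_um
  n_pop <- length(starts)
  ends <- c(starts[-1] - 1L, length(d))
  # support boundaries at midpoints between adjacent segments (and span ends)
  cuts <- c(span[1], (d[ends[-n_pop]] + d[starts[-1]]) / 2, span[2])
  lo <- cuts[seq_len(n_pop)]
  hi <- cuts[seq_len(n_pop) + 1]
  b <- pmax(1, ramp_frac * (hi - lo) / 2)
  a <- pmax(0, (hi - lo) - 2 * b)
  g <- rep(0, n_pop + 1)                          # supports tile the span
  scale <- 0.8 / max(c(g, a, b))
  u_b <- pmax(0, scale * b - b_floor)
  pmin(1, c(g * scale, a * scale, u_b))
}

#' Fit laminar population positions and firing rates to the MUA
#'
#' Runs a seeded global search (differential evolution) over the trapezoid
#' parameters `z`, `a`, `b` of `n_populations` non-overlapping populations.
#' For every candidate layout the temporal profiles come from the pseudoinverse
#' ([infer_rates()]) and the cost is the relative mean square error of the MUA
#' reconstruction; the search is followed by a local refinement when
#' `config$optimizer$polish` is `TRUE`. Candidates are generated in a
#' reparameterized gap/width space in which every point is a feasible,
#' depth-ordered, non-overlapping layout.
#'
#' @param mua MUA envelope (non-negative), a [recording_matrix()] of kind
#'   `"mua"`, trial-averaged.
#' @param geom a [probe_geometry()].
#' @param config an [analysis_config()]; uses `n_populations`, bounds,
#'   optimizer settings and `rng_seed`.
#' @return an `lpa_mua_fit`: populations (trapezoid table, depth-ordered, with
#'   layer labels when the geometry has layer boundaries), spatial matrix,
#'   rates, fitted MUA, `e_m`, correlation and convergence info. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_mua <- function(mua, geom, config) {
  stopifnot(inherits(mua, "recording_matrix"), inherits(geom, "probe_geometry"),
            inherits(config, "analysis_config"))
  if (rec_kind(mua) != "mua") {
    lp_abort("`fit_mua()` expects a MUA envelope recording.", "parameter_error")
  }
  check_channel_count(nrow(mua), geom)
  n_pop <- config$n_populations
  span <- fit_span(geom)
  min_width <- config$a_bounds_um[1] + 2 * config$b_bounds_um[1]
  if (n_pop * min_width > diff(span)) {
    lp_abort(sprintf(
      "cannot place %d non-overlapping trapezoids of minimal width %g um in a %g um span.",
      n_pop, min_width, diff(span)), "config_error")
  }

  phi <- unclass(mua)
  ss <- sum(phi^2)
  if (ss == 0) lp_abort("MUA envelope is all-zero.", "parameter_error")
  depths <- geom$depths_um

  cost <- function(u) {
    ly <- layout_from_unit(u, span[1], span[2], n_pop)
    m <- t(mapply(function(z, a, b) trapezoid_eval(depths, z, a, b),
                  ly$z_um, ly$a_um, ly$b_um))
    if (n_pop == 1) m <- matrix(m, nrow = 1)
    empty <- rowSums(m) == 0
    if (any(empty)) return(10 + sum(empty))  # infeasible: population off-grid
    r <- pseudoinverse(t(m)) %*% phi
    sum((phi - t(m) %*% r)^2) / ss
  }

  dim_u <- 3 * n_pop + 1   # N+1 gaps, N plateaus, N ramps
  # structured initial candidates seeded into the DE population:
  # (a) layouts derived from a contiguous segmentation of the channels by
  #     time-course similarity (plateaus on the segments, ramps in the gaps),
  # (b) evenly tiled layouts over a grid of gap/ramp ratios,
  # each with jittered copies; the rest of the population is uniform random.
  set.seed(config$rng_seed)
  jitter2 <- function(base) rbind(
    base,
    pmin(1, pmax(0, base + runif(dim_u, -0.08, 0.08))),
    pmin(1, pmax(0, base + runif(dim_u, -0.08, 0.08))))
  init <- NULL
  if (n_pop <= nrow(phi)) {
    starts <- segment_channels(phi, n_pop)
    init <- do.call(rbind, lapply(c(0.2, 0.45, 0.7), function(fr) {
      jitter2(layout_to_unit(starts, geom, span, ramp_frac = fr))
    }))
  }
  grid <- expand.grid(fg = c(0.03, 0.12, 0.3), fb = c(0.08, 0.2, 0.35))
  init <- rbind(init, do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    jitter2(c(rep(grid$fg[i], n_pop + 1), rep(0.5, n_pop),
              rep(grid$fb[i], n_pop)))
  })))
  opt <- run_de(cost, dim_u, config, init = init)

  ly <- layout_from_unit(opt$par, span[1], span[2], n_pop)
  pops <- population_model(ly, geom)
  if (!is.null(geom$layers)) pops <- assign_layers(pops, geom)
  m <- suppressWarnings(build_spatial_matrix(pops, geom))
  rates <- infer_rates(m, mua)
  fitted <- recording_matrix(t(m) %*% unclass(rates), rec_dt(mua), rec_t0(mua),
                             "mua", depths_um = depths)
  e_m <- relative_mse(phi, unclass(fitted))
  structure(
    list(populations = pops, spatial = m, rates = rates, fitted = fitted,
         data = mua, geometry = geom, e_m = e_m,
         correlation = stats::cor(as.numeric(phi), as.numeric(fitted)),
         convergence = opt$convergence, config = config),
    class = "lpa_mua_fit"
  )
}

#' @export
print.lpa_mua_fit <- function(x, ...) {
  cat(sprintf("<lpa_mua_fit> %d populations, e_M = %.4g, correlation = %.3f\n",
              nrow(x$populations), x$e_m, x$correlation))
  print(as_tibble(x$populations))
  invisible(x)
}

# --- differential-evolution driver ------------------------------------------
# Seeded global search in the unit box followed by an optional local polish.
run_de <- function(cost, dim_u, config, lower = rep(0, dim_u),
                   upper = rep(1, dim_u), init = NULL) {
  opt <- config$optimizer
  np <- opt$np %||% max(10 * dim_u, 40)
  set.seed(config$rng_seed)
  initialpop <- matrix(runif(np * dim_u, lower, upper), np, dim_u,
                       byrow = TRUE)
  if (!is.null(init)) {
    k <- min(nrow(init), floor(np / 3))
    initialpop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  de <- DEoptim::DEoptim(
    cost, lower = lower, upper = upper,
    control = DEoptim::DEoptim.control(
      NP = np, itermax = opt$maxiter, reltol = opt$reltol,
      CR = 0.9, F = 0.8, initialpop = initialpop,
      steptol = max(20, round(opt$maxiter / 5)), trace = FALSE)
  )
  par <- de$optim$bestmem
  val <- de$optim$bestval
  polished <- NA
  if (isTRUE(opt$polish)) {
    # staged local refinement with shrinking finite-difference steps: the
    # first pass crosses shallow ripples, the later ones resolve the narrow
    # quadratic basin around the optimum
    for (nd in c(1e-3, 1e-6, 1e-7, 1e-7)) {
      pol <- tryCatch(
        stats::optim(par, cost, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(maxit = 1000, factr = 10,
                                    ndeps = rep(nd, dim_u))),
        error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value)) {
        if (pol$value < val) { par <- pol$par; val <- pol$value }
        polished <- pol$convergence == 0
      }
    }
  }
  # converged: DE stopped early, its best cost had stalled, or the local
  # refinement reached a stationary point
  trace <- de$member$bestvalit
  tail_n <- max(2, round(length(trace) / 5))
  tail_tr <- trace[(length(trace) - tail_n + 1):length(trace)]
  stalled <- (max(tail_tr) - min(tail_tr)) <= 1e-3 * abs(min(tail_tr)) + 1e-12
  converged <- de$optim$iter < opt$maxiter || stalled || isTRUE(polished)
  if (!converged) {
    warn(sprintf("optimizer budget exhausted after %d iterations while still improving; returning best-so-far (cost %.4g).",
                 de$optim$iter, val), class = "laminpop_nonconvergence")
  }
  list(par = as.numeric(par), value = val,
       convergence = list(iterations = de$optim$iter, cost = val,
                          converged = converged, np = np))
}
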