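# Trapezoidal laminar population profiles and the spatial matrix M.

#' Evaluate a trapezoidal depth profile
#'
#' A laminar population's spatial profile is a trapezoid of height 1: weight 1
#' on the plateau `[z - a/2, z + a/2]`, a linear ramp down to 0 over width `b`
#' on each side, and 0 outside the support `[z - a/2 - b, z + a/2 + b]`.
#'
#' @param depth_um depth(s) at which to evaluate, um (vectorized).
#' @param z_um trapezoid centre depth, um.
#' @param a_um plateau width (>= 0), um.
#' @param b_um ramp width on each side (> 0), um.
#' @return weights in `[0, 1]`, same length as `depth_um`.
#' @examples
#' trapezoid_eval(c(0, 75, 200), z_um = 0, a_um = 100, b_um = 50)
#' @export
trapezoid_eval <- function(depth_um, z_um, a_um, b_um) {
  if (a_um < 0 || b_um <= 0) {
    lp_abort("need plateau a >= 0 and ramp b > 0.", "parameter_error")
  }
  d <- abs(depth_um - z_um) - a_um / 2
  pmin(1, pmax(0, 1 - d / b_um))
}

# support interval of one trapezoid
trapezoid_support <- function(z_um, a_um, b_um) {
  c(z_um - a_um / 2 - b_um, z_um + a_um / 2 + b_um)
}

#' Build a population model from trapezoid parameters
#'
#' Validates and orders a set of trapezoids: supports must be pairwise
#' non-overlapping and lie within the probe span, which keeps each population
#' spatially localized and makes the channel-to-population assignment unique.
#'
#' @param trapezoids data frame with columns `population`, `z_um`, `a_um`,
#'   `b_um` (one row per population; `population` defaults to `pop_<k>`).
#' @param geom optional [probe_geometry()]; when given, supports are checked
#'   against the probe span.
#' @return a `population_model` tibble ordered by depth, with a
#'   `support_lo_um`/`support_hi_um` pair added.
#' @export
population_model <- function(trapezoids, geom = NULL) {
  tz <- as_tibble(trapezoids)
  if (!all(c("z_um", "a_um", "b_um") %in% names(tz))) {
    lp_abort("`trapezoids` needs columns z_um, a_um, b_um.", "parameter_error")
  }
  if (!"population" %in% names(tz)) {
    tz$population <- paste0("pop_", seq_len(nrow(tz)))
  }
  if (any(tz$a_um < 0) || any(tz$b_um <= 0)) {
    lp_abort("need plateau a >= 0 and ramp b > 0 for every population.",
             "parameter_error")
  }
  sup <- t(mapply(trapezoid_support, tz$z_um, tz$a_um, tz$b_um))
  tz$support_lo_um <- sup[, 1]
  tz$support_hi_um <- sup[, 2]
  tz <- dplyr::arrange(tz, .data$z_um)
  if (nrow(tz) > 1 &&
      any(tz$support_lo_um[-1] < tz$support_hi_um[-nrow(tz)] - 1e-9)) {
    lp_abort("trapezoid supports overlap; populations must be non-overlapping.",
             "overlap_error")
  }
  if (!is.null(geom)) {
    # probe span padded by one inter-channel spacing: ramps may taper just
    # beyond the outermost contacts so edge channels can sit on a plateau
    pad <- stats::median(diff(geom$depths_um))
    span <- range(geom$depths_um) + c(-pad, pad)
    if (min(tz$support_lo_um) < span[1] - 1e-9 ||
        max(tz$support_hi_um) > span[2] + 1e-9) {
      lp_abort("trapezoid support extends beyond the probe span.", "overlap_error")
    }
  }
  class(tz) <- c("population_model", class(tz))
  tz
}

#' Spatial profile matrix M
#'
#' Evaluates every population's trapezoid at every channel depth, giving the
#' N_pop x N_ch matrix whose transpose maps population firing rates to MUA.
#' Because supports are non-overlapping, each channel has positive weight for
#' at most one population. Populations whose support covers no channel produce
#' an all-zero row and a warning.
#'
#' @param pops a [population_model()] (or data frame coercible to one).
#' @param geom a [probe_geometry()].
#' @return N_pop x N_ch numeric matrix with population row names.
#' @export
build_spatial_matrix <- function(pops, geom) {
  if (!inherits(pops, "population_model")) pops <- population_model(pops, geom)
  stopifnot(inherits(geom, "probe_geometry"))
  m <- t(mapply(function(z, a, b) trapezoid_eval(geom$depths_um, z, a, b),
                pops$z_um, pops$a_um, pops$b_um))
  rownames(m) <- pops$population
  empty <- rowSums(m > 0) == 0
  if (any(empty)) {
    warn(paste0("population(s) covering no channel: ",
                paste(pops$population[empty], collapse = ", ")),
         class = "laminpop_zero_support")
  }
  m
}

#' Assign channels to populations
#'
#' Each channel belongs to the unique population whose trapezoid weight at
#' that channel is positive (guaranteed unique by non-overlap). Channels with
#' zero weight everywhere are assigned to the population with the nearest
#' support and flagged in the `nearest` column.
#'
#' @param pops a [population_model()].
#' @param geom a [probe_geometry()].
#' @return tibble with columns `channel`, `depth_um`, `population`, `weight`,
#'   `nearest` (logical: assigned by proximity rather than positive weight).
#' @export
classify_channels <- function(pops, geom) {
  if (!inherits(pops, "population_model")) pops <- population_model(pops, geom)
  m <- suppressWarnings(build_spatial_matrix(pops, geom))
  idx <- apply(m, 2, which.max)
  w <- m[cbind(idx, seq_len(ncol(m)))]
  nearest <- w <= 0
  if (any(nearest)) {
    for (ch in which(nearest)) {
      z <- geom$depths_um[ch]
      dist <- pmax(pops$support_lo_um - z, z - pops$support_hi_um, 0)
      idx[ch] <- which.min(dist)
    }
  }
  tibble(channel = seq_along(idx),
         depth_um = geom$depths_um,
         population = pops$population[idx],
         weight = w,
         nearest = nearest)
}

#' Label populations with the cortical layer they overlap most
#'
#' A population is labelled with the layer its trapezoid support overlaps the
#' most with, overlap measured in micrometres against the geometry's layer
#' boundaries. Ties go to the shallower layer (and are messaged).
#'
#' @param pops a [population_model()].
#' @param geom a [probe_geometry()] with `layers`.
#' @return the population model with a `layer` column added.
#' @export
assign_layers <- function(pops, geom) {
  if (!inherits(pops, "population_model")) pops <- population_model(pops, geom)
  if (is.null(geom$layers)) {
    lp_abort("geometry has no layer boundaries.", "geometry_error")
  }
  ly <- geom$layers
  lab <- character(nrow(pops))
  for (k in seq_len(nrow(pops))) {
    ov <- pmax(0, pmin(pops$support_hi_um[k], ly$bottom_um) -
                  pmax(pops$support_lo_um[k], ly$top_um))
    best <- which(ov == max(ov))
    if (length(best) > 1) {
      rlang::inform(sprintf("layer-overlap tie for %s; shallower layer %s wins.",
                            pops$population[k], ly$layer[best[1]]))
    }
    lab[k] <- ly$layer[best[1]]  # layers sorted by depth: shallower wins ties
  }
  pops$layer <- lab
  pops
}

#' Predicted layer of every channel
#'
#' Combines [classify_channels()] (channel to population) with
#' [assign_layers()] (population to layer).
#'
#' @inheritParams assign_layers
#' @return tibble with `channel`, `depth_um`, `predicted_layer`.
#' @export
predict_channel_layers <- function(pops, geom) {
  pops <- assign_layers(pops, geom)
  cc <- classify_channels(pops, geom)
  tibble(channel = cc$channel, depth_um = cc$depth_um,
         predicted_layer = pops$layer[match(cc$population, pops$population)])
}
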