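#' Laminar probe geometry
#'
#' Describes the recording probe: ordered channel depths along the cortical
#' axis, extracellular conductivity, the disc radius used by the delta
#' inverse-CSD forward model, and (optionally) the depth interval of each
#' cortical layer. Depths increase from the cortical surface downward and
#' channel 1 is the most superficial contact.
#'
#' @param depths_um strictly increasing channel depths in micrometres.
#' @param sigma_s_per_m extracellular conductivity in S/m (default 0.3, a
#'   conventional cortical value).
#' @param disc_radius_um radius of the planar current discs assumed by the
#'   delta inverse-CSD method, in micrometres.
#' @param layers optional data frame with columns `layer`, `top_um`,
#'   `bottom_um` giving non-overlapping, ordered layer intervals.
#' @return a `probe_geometry` object.
#' @examples
#' geom <- probe_geometry(seq(20, 1020, by = 40))
#' n_channels(geom)
#' @export
probe_geometry <- function(depths_um,
                           sigma_s_per_m = 0.3,
                           disc_radius_um = 400,
                           layers = NULL) {
  depths_um <- as.numeric(depths_um)
  if (length(depths_um) < 2 || any(!is.finite(depths_um)) ||
      any(diff(depths_um) <= 0)) {
    lp_abort("`depths_um` must be a strictly increasing numeric vector (>= 2 channels).",
             "geometry_error")
  }
  if (!is_number(sigma_s_per_m) || sigma_s_per_m <= 0) {
    lp_abort("`sigma_s_per_m` must be a positive number.", "geometry_error")
  }
  if (!is_number(disc_radius_um) || disc_radius_um <= 0) {
    lp_abort("`disc_radius_um` must be a positive number.", "geometry_error")
  }
  if (!is.null(layers)) {
    layers <- as_tibble(layers)
    need <- c("layer", "top_um", "bottom_um")
    if (!all(need %in% names(layers))) {
      lp_abort("`layers` needs columns layer, top_um, bottom_um.", "geometry_error")
    }
    layers <- dplyr::arrange(layers, .data$top_um)
    if (any(layers$bottom_um <= layers$top_um) ||
        (nrow(layers) > 1 &&
         any(layers$top_um[-1] < layers$bottom_um[-nrow(layers)]))) {
      lp_abort("layer intervals must be non-degenerate, ordered and non-overlapping.",
               "geometry_error")
    }
  }
  structure(
    list(depths_um = depths_um,
         sigma_s_per_m = sigma_s_per_m,
         disc_radius_um = disc_radius_um,
         layers = layers),
    class = "probe_geometry"
  )
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("<probe_geometry> %d channels, %.0f-%.0f um", n_channels(x),
              min(x$depths_um), max(x$depths_um)))
  sp <- unique(round(diff(x$depths_um), 6))
  if (length(sp) == 1) cat(sprintf(", spacing %g um", sp))
  cat(sprintf("\n  sigma = %g S/m, disc radius = %g um\n",
              x$sigma_s_per_m, x$disc_radius_um))
  if (!is.null(x$layers)) {
    cat(sprintf("  layers: %s\n", paste(x$layers$layer, collapse = ", ")))
  }
  invisible(x)
}

#' Number of probe channels
#' @param geom a [probe_geometry()].
#' @return integer channel count.
#' @export
n_channels <- function(geom) {
  stopifnot(inherits(geom, "probe_geometry"))
  length(geom$depths_um)
}

#' True layer label of every channel
#'
#' Assigns each channel the layer whose `[top_um, bottom_um)` interval contains
#' its depth (the deepest layer is closed at the bottom).
#'
#' @param geom a [probe_geometry()] with `layers`.
#' @return character vector of layer labels, one per channel.
#' @export
channel_layers <- function(geom) {
  stopifnot(inherits(geom, "probe_geometry"))
  if (is.null(geom$layers)) {
    lp_abort("geometry has no layer boundaries.", "geometry_error")
  }
  ly <- geom$layers
  vapply(geom$depths_um, function(z) {
    hit <- which(z >= ly$top_um & (z < ly$bottom_um |
                   (z <= ly$bottom_um & ly$bottom_um == max(ly$bottom_um))))
    if (length(hit) == 0) NA_character_ else ly$layer[hit[1]]
  }, character(1))
}

#' Read / write probe geometry as YAML
#'
#' @param path file path.
#' @return `read_probe_geometry()` returns a [probe_geometry()];
#'   `write_probe_geometry()` returns `path` invisibly.
#' @export
read_probe_geometry <- function(path) {
  if (!file.exists(path)) lp_abort(paste0("no such file: ", path), "io_error")
  y <- yaml::read_yaml(path)
  if (is.null(y$depths_um)) {
    lp_abort("geometry file is missing `depths_um`.", "config_error")
  }
  layers <- NULL
  if (!is.null(y$layers)) {
    layers <- tibble(
      layer = vapply(y$layers, function(l) as.character(l$layer), character(1)),
      top_um = vapply(y$layers, function(l) as.numeric(l$top_um), numeric(1)),
      bottom_um = vapply(y$layers, function(l) as.numeric(l$bottom_um), numeric(1))
    )
  }
  probe_geometry(
    depths_um = as.numeric(y$depths_um),
    sigma_s_per_m = y$sigma_s_per_m %||% 0.3,
    disc_radius_um = y$disc_radius_um %||% 400,
    layers = layers
  )
}

#' @rdname read_probe_geometry
#' @param geom a [probe_geometry()].
#' @export
write_probe_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "probe_geometry"))
  y <- list(depths_um = geom$depths_um,
            sigma_s_per_m = geom$sigma_s_per_m,
            disc_radius_um = geom$disc_radius_um)
  if (!is.null(geom$layers)) {
    y$layers <- purrr::pmap(geom$layers, function(layer, top_um, bottom_um) {
      list(layer = layer, top_um = top_um, bottom_um = bottom_um)
    })
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
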