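# ggplot2 figures for the main result types.

#' Heatmap of a channels-by-time signal
#'
#' @param object a [recording_matrix()].
#' @param ... unused.
#' @return a ggplot: time on x, depth (or channel) on y (surface at the top),
#'   diverging fill.
#' @export
autoplot.recording_matrix <- function(object, ...) {
  tb <- tidy(object)
  yvar <- if ("depth_um" %in% names(tb)) "depth_um" else "channel"
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$time_ms, y = .data[[yvar]],
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac") +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = if (yvar == "depth_um") "depth (µm)" else "channel",
                  fill = rec_kind(object)) +
    ggplot2::theme_minimal()
}

#' Firing-rate time courses
#'
#' @param object a [rate_matrix()].
#' @param ... unused.
#' @return a ggplot of one line per population, faceted by source.
#' @export
autoplot.rate_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_ms, y = .data$rate,
                               colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~source, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time from stimulus onset (ms)", y = "rate",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Spatial profiles of an MUA population fit
#'
#' @param object an `lpa_mua_fit`.
#' @param ... unused.
#' @return a ggplot of trapezoid weight against depth per population, with
#'   layer boundaries when the geometry has them.
#' @export
autoplot.lpa_mua_fit <- function(object, ...) {
  m <- object$spatial
  tb <- tibble(
    population = rep(rownames(m), times = ncol(m)),
    depth_um = rep(object$geometry$depths_um, each = nrow(m)),
    weight = as.numeric(m)
  )
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$weight, y = .data$depth_um,
                                        colour = .data$population)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "trapezoid weight", y = "depth (µm)",
                  colour = "population") +
    ggplot2::theme_minimal()
  if (!is.null(object$geometry$layers)) {
    p <- p + ggplot2::geom_hline(
      data = object$geometry$layers,
      mapping = ggplot2::aes(yintercept = .data$top_um),
      linetype = "dotted", colour = "grey50")
  }
  p
}

#' Per-population field contributions of a kernel fit
#'
#' @param object an `lpa_csd_fit`.
#' @param ... unused.
#' @return a ggplot of contribution heatmaps, one facet per presynaptic
#'   population.
#' @export
autoplot.lpa_csd_fit <- function(object, ...) {
  depths <- attr(object$data, "depths_um") %||% seq_len(nrow(object$data))
  times <- rec_times(object$data)
  tb <- purrr::imap_dfr(object$contributions, function(mat, nm) {
    tibble(population = nm,
           depth_um = rep(depths, times = ncol(mat)),
           time_ms = rep(times, each = nrow(mat)),
           value = as.numeric(mat))
  })
  tb$population <- factor(tb$population, levels = names(object$contributions))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$time_ms, y = .data$depth_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac") +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "time from stimulus onset (ms)", y = "depth (µm)",
                  fill = "contribution") +
    ggplot2::theme_minimal()
}

#' Penalty-scan diagnostics
#'
#' @param object a `lambda_scan`.
#' @param ... unused.
#' @return a ggplot of channel-sum deviation against lambda, with the
#'   recorded data's deviation as a dashed reference line.
#' @export
autoplot.lambda_scan <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$lambda, y = .data$deviation)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$data_deviation,
                        linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(x = expression(lambda), y = "channel-sum deviation") +
    ggplot2::theme_minimal()
}
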