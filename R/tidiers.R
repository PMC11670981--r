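# broom-style tidiers for fitted objects.

#' Tidy an MUA population fit
#'
#' @param x an `lpa_mua_fit`.
#' @param ... unused.
#' @return tibble of trapezoid parameters (one row per population, with layer
#'   labels when available).
#' @export
tidy.lpa_mua_fit <- function(x, ...) {
  tb <- as_tibble(x$populations)
  class(tb) <- class(tibble())
  tb
}

#' @rdname tidy.lpa_mua_fit
#' @return `glance()`: one-row tibble with `n_populations`, `e_m`,
#'   `correlation`, `iterations`, `converged`.
#' @export
glance.lpa_mua_fit <- function(x, ...) {
  tibble(n_populations = nrow(x$populations), e_m = x$e_m,
         correlation = x$correlation,
         iterations = x$convergence$iterations,
         converged = x$convergence$converged)
}

#' Tidy a field (CSD/LFP) kernel fit
#'
#' @param x an `lpa_csd_fit`.
#' @param ... unused.
#' @return tibble of kernel parameters per presynaptic population, with the
#'   source (internal/external) of each.
#' @export
tidy.lpa_csd_fit <- function(x, ...) {
  dplyr::mutate(x$kernels, source = rate_source(x$rates))
}

#' @rdname tidy.lpa_csd_fit
#' @return `glance()`: one-row tibble with the total cost `e_c`, its
#'   `rel_mse` and `penalty_term` parts, `lambda`, `correlation`,
#'   `iterations`, `converged`.
#' @export
glance.lpa_csd_fit <- function(x, ...) {
  tibble(e_c = x$e_c, rel_mse = x$rel_mse, penalty_term = x$penalty_term,
         lambda = x$lambda, correlation = x$correlation,
         iterations = x$convergence$iterations,
         converged = x$convergence$converged)
}

#' Tidy a lambda scan
#'
#' @param x a `lambda_scan` from [select_lambda()].
#' @param ... unused.
#' @return the scan table (lambda, deviation, rel_mse, correlation).
#' @export
tidy.lambda_scan <- function(x, ...) x$table

#' Tidy a confusion matrix
#'
#' @param x a [confusion_matrix()].
#' @param ... unused.
#' @return long tibble with `predicted`, `truth`, `n`, `proportion`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(
    predicted = rep(x$layers, times = length(x$layers)),
    truth = rep(x$layers, each = length(x$layers)),
    n = as.integer(x$counts[cbind(rep(seq_along(x$layers), length(x$layers)),
                                  rep(seq_along(x$layers), each = length(x$layers)))]),
    proportion = as.numeric(x$proportions[cbind(
      rep(seq_along(x$layers), length(x$layers)),
      rep(seq_along(x$layers), each = length(x$layers)))])
  )
}

#' Tidy a baseline component set
#'
#' @param x a `component_set`.
#' @param ... unused.
#' @return long tibble with `component`, `channel`, `spatial` and, per time
#'   bin, `time_index`, `temporal` columns stacked long.
#' @export
tidy.component_set <- function(x, ...) {
  k <- ncol(x$spatial)
  dplyr::bind_rows(
    spatial = tibble(component = rep(colnames(x$spatial), each = nrow(x$spatial)),
                     index = rep(seq_len(nrow(x$spatial)), k),
                     value = as.numeric(x$spatial)),
    temporal = tibble(component = rep(rownames(x$temporal), times = ncol(x$temporal)),
                      index = rep(seq_len(ncol(x$temporal)), each = k),
                      value = as.numeric(x$temporal)),
    .id = "profile"
  )
}

#' @rdname tidy.component_set
#' @return `glance()`: one-row tibble with `method`, `k`, `converged` and the
#'   cumulative explained variance (PCA).
#' @export
glance.component_set <- function(x, ...) {
  tibble(method = x$method, k = ncol(x$spatial),
         cumulative_variance = if (is.null(x$explained_var)) NA_real_ else
           sum(x$explained_var),
         converged = x$converged)
}
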