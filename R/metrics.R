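# Validation metrics: confusion matrix, per-layer precision/recall/F1,
# Pearson correlation and contribution matching.

#' Confusion matrix for channel-layer classification
#'
#' Tallies predicted layer (rows) against true layer (columns): +1 is added at
#' (predicted row, true column) for every channel. The normalized form divides
#' each row by its sum, giving the proportion of correct and incorrect
#' classifications per predicted layer.
#'
#' @param predicted,truth equal-length vectors of layer labels per channel.
#' @param layers layer ordering; defaults to the union of labels in order of
#'   first appearance in `truth` then `predicted`.
#' @return a `confusion_matrix` with fields `counts` and `proportions`.
#' @export
confusion_matrix <- function(predicted, truth, layers = NULL) {
  if (length(predicted) == 0 || length(predicted) != length(truth)) {
    lp_abort("`predicted` and `truth` must be equal-length, non-empty.",
             "parameter_error")
  }
  layers <- layers %||% unique(c(as.character(truth), as.character(predicted)))
  unknown <- setdiff(unique(c(predicted, truth)), layers)
  if (length(unknown) > 0) {
    lp_abort(paste0("unknown layer label(s): ", paste(unknown, collapse = ", ")),
             "parameter_error")
  }
  counts <- table(factor(predicted, levels = layers),
                  factor(truth, levels = layers))
  counts <- matrix(as.integer(counts), nrow = length(layers),
                   dimnames = list(predicted = layers, truth = layers))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, proportions = props, layers = layers),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = predicted, columns = true)\n")
  print(x$counts)
  invisible(x)
}

check_layer <- function(cm, layer) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!layer %in% cm$layers) {
    lp_abort(paste0("layer not in confusion matrix: ", layer), "parameter_error")
  }
}

#' Per-layer precision, recall and F1
#'
#' Precision is TP / (TP + FP) (TP + FP = row sum of the predicted layer),
#' recall is TP / (TP + FN) (column sum of the true layer), and F1 is their
#' harmonic mean `2 * p * r / (p + r)`. A zero denominator yields a score of 0
#' with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @param layer layer label.
#' @return scalar in `[0, 1]`.
#' @export
precision <- function(cm, layer) {
  check_layer(cm, layer)
  tp <- cm$counts[layer, layer]
  denom <- sum(cm$counts[layer, ])
  if (denom == 0) {
    warn(paste0("no predictions for layer ", layer, "; precision set to 0."),
         class = "laminpop_zero_denominator")
    return(0)
  }
  tp / denom
}

#' @rdname precision
#' @export
recall <- function(cm, layer) {
  check_layer(cm, layer)
  tp <- cm$counts[layer, layer]
  denom <- sum(cm$counts[, layer])
  if (denom == 0) {
    warn(paste0("no true channels in layer ", layer, "; recall set to 0."),
         class = "laminpop_zero_denominator")
    return(0)
  }
  tp / denom
}

#' @rdname precision
#' @export
f1_score <- function(cm, layer) {
  f1_from_scores(precision(cm, layer), recall(cm, layer))
}

#' F1 from precision and recall
#'
#' @param precision,recall scores in `[0, 1]`.
#' @return the harmonic mean; 0 when both are 0.
#' @export
f1_from_scores <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Score table for every layer
#'
#' Per-layer precision, recall and F1 (as reported in the field), plus
#' unweighted macro averages and the micro-averaged accuracy as attributes
#' (`macro`, `accuracy`) -- the macro rows are a convenience addition, not a
#' standard report line.
#'
#' @param cm a [confusion_matrix()].
#' @return tibble with columns `layer`, `precision`, `recall`, `f1`.
#' @export
layer_scores <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tb <- tibble(
    layer = cm$layers,
    precision = vapply(cm$layers, function(l) suppressWarnings(precision(cm, l)),
                       numeric(1), USE.NAMES = FALSE),
    recall = vapply(cm$layers, function(l) suppressWarnings(recall(cm, l)),
                    numeric(1), USE.NAMES = FALSE)
  )
  tb$f1 <- f1_from_scores(tb$precision, tb$recall)
  attr(tb, "macro") <- c(precision = mean(tb$precision),
                         recall = mean(tb$recall), f1 = mean(tb$f1))
  attr(tb, "accuracy") <- sum(diag(cm$counts)) / sum(cm$counts)
  tb
}

#' Pearson correlation of two signals
#'
#' Standard Pearson r over the flattened values; errors on constant input.
#'
#' @param x,y same-shaped numeric vectors or matrices.
#' @return scalar in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(unclass(as.matrix(x))); y <- as.numeric(unclass(as.matrix(y)))
  if (length(x) != length(y)) {
    lp_abort("`x` and `y` must have the same shape.", "dimension_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    lp_abort("correlation is undefined for a constant input.", "parameter_error")
  }
  cor(x, y)
}

#' Score estimated per-population contributions against ground truth
#'
#' In labelled mode the lists are matched by name (or order) and each
#' population gets its Pearson correlation and relative MSE versus truth. In
#' unlabelled mode (statistical baselines, where components carry no
#' population identity) components are assigned to truth contributions by
#' exhaustive best-match: the one-to-one assignment maximizing the summed
#' correlation, optionally allowing sign flips for sign-indeterminate
#' components.
#'
#' @param estimated,truth named lists of channels x bins matrices.
#' @param labelled match by population label (`TRUE`) or by best correlation
#'   (`FALSE`)?
#' @param allow_sign_flip in unlabelled mode, also consider a component with
#'   its sign flipped (ICA components have arbitrary sign).
#' @return tibble with columns `population`, `component` (matched estimate
#'   name), `correlation`, `rel_mse`.
#' @export
match_contributions <- function(estimated, truth, labelled = TRUE,
                                allow_sign_flip = FALSE) {
  stopifnot(is.list(estimated), is.list(truth))
  if (labelled) {
    if (length(estimated) != length(truth)) {
      lp_abort("labelled mode needs equal population counts.", "dimension_error")
    }
    if (!is.null(names(estimated)) && !is.null(names(truth)) &&
        all(names(truth) %in% names(estimated))) {
      estimated <- estimated[names(truth)]
    }
    safe_cor <- function(x, y) {
      tryCatch(pearson_correlation(x, y), laminpop_parameter_error =
                 function(e) NA_real_)  # constant estimate: undefined, not fatal
    }
    return(tibble(
      population = names(truth) %||% paste0("pop_", seq_along(truth)),
      component = names(estimated) %||% paste0("est_", seq_along(estimated)),
      correlation = unname(purrr::map2_dbl(truth, estimated, safe_cor)),
      rel_mse = unname(purrr::map2_dbl(truth, estimated, relative_mse))
    ))
  }
  # unlabelled: exhaustive assignment over truth -> component injections
  n_t <- length(truth); n_e <- length(estimated)
  if (n_e < n_t) {
    lp_abort("need at least as many components as truth contributions.",
             "dimension_error")
  }
  cmat <- matrix(0, n_t, n_e)
  for (i in seq_len(n_t)) {
    for (j in seq_len(n_e)) {
      r <- pearson_correlation(truth[[i]], estimated[[j]])
      cmat[i, j] <- if (allow_sign_flip) abs(r) else r
    }
  }
  perms <- all_injections(n_t, n_e)
  scores <- vapply(perms, function(p) sum(cmat[cbind(seq_len(n_t), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  comp_names <- names(estimated) %||% paste0("comp_", seq_len(n_e))
  out <- tibble(
    population = names(truth) %||% paste0("pop_", seq_len(n_t)),
    component = comp_names[best],
    correlation = numeric(n_t), rel_mse = numeric(n_t)
  )
  for (i in seq_len(n_t)) {
    est <- estimated[[best[i]]]
    r <- pearson_correlation(truth[[i]], est)
    if (allow_sign_flip && r < 0) { est <- -est; r <- -r }
    out$correlation[i] <- r
    out$rel_mse[i] <- relative_mse(truth[[i]], est)
  }
  out
}

# all injective assignments of 1..k into 1..n (k <= n); k is small (<= 6)
all_injections <- function(k, n) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  recurse <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (j in remaining) recurse(c(prefix, j), setdiff(remaining, j))
  }
  recurse(integer(0), seq_len(n))
  out
}
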