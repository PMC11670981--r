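test_that("confusion matrix tallies predicted rows against true columns", {
  layers <- c("L1", "L2/3", "L4", "L5", "L6")
  cm <- confusion_matrix(c("L1", "L2/3"), c("L1", "L4"), layers)
  expect_equal(cm$counts["L1", "L1"], 1L)
  # predicted L2/3 but truly L4 -> row L2/3, column L4
  expect_equal(cm$counts["L2/3", "L4"], 1L)
  expect_equal(sum(cm$counts), 2L)
  # perfect prediction is diagonal, rows normalize to 1
  perfect <- confusion_matrix(layers, layers, layers)
  expect_equal(perfect$counts, diag(1L, 5),
               ignore_attr = TRUE)
  expect_equal(rowSums(perfect$proportions), rep(1, 5), ignore_attr = TRUE)
  expect_error(confusion_matrix(character(0), character(0)),
               class = "laminpop_parameter_error")
  expect_error(confusion_matrix("Lx", "L1", layers),
               class = "laminpop_parameter_error")
})

test_that("precision, recall and F1 follow their definitions with zero-denominator guards", {
  layers <- c("a", "b")
  # 3 channels: predicted a,a,b / truth a,b,b
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"), layers)
  expect_equal(precision(cm, "a"), 0.5)   # TP 1 of row sum 2
  expect_equal(recall(cm, "a"), 1)        # column a has only the TP
  expect_equal(f1_score(cm, "a"), 2 * 0.5 * 1 / 1.5)
  # a layer never predicted and never true
  cm2 <- confusion_matrix(c("a", "a"), c("a", "a"), c("a", "b"))
  expect_warning(pb <- precision(cm2, "b"), class = "laminpop_zero_denominator")
  expect_equal(pb, 0)
  expect_warning(rb <- recall(cm2, "b"), class = "laminpop_zero_denominator")
  expect_equal(rb, 0)
})

test_that("F1 is the harmonic mean, bounded by precision and recall", {
  expect_equal(round(f1_from_scores(0.5, 1), 2), 0.67)
  expect_equal(round(f1_from_scores(1, 0.8), 2), 0.89)
  expect_equal(f1_from_scores(1, 1), 1)
  expect_equal(f1_from_scores(0, 0), 0)
  set.seed(1)
  p <- runif(50); r <- runif(50)
  f <- f1_from_scores(p, r)
  expect_true(all(f <= pmax(p, r) + 1e-12))
  expect_true(all(f >= pmin(p, r) * 0 - 1e-12))
  expect_true(all((f == 1) == (p == 1 & r == 1)))
})

test_that("micro-averaged recall equals overall channel accuracy", {
  set.seed(9)
  layers <- c("L1", "L2/3", "L4", "L5", "L6")
  for (rep in 1:5) {
    truth <- sample(layers, 40, replace = TRUE)
    pred <- ifelse(runif(40) < 0.7, truth, sample(layers, 40, replace = TRUE))
    cm <- confusion_matrix(pred, truth, layers)
    scores <- layer_scores(cm)
    col_tot <- colSums(cm$counts)
    micro <- sum(scores$recall * col_tot) / sum(col_tot)
    expect_equal(micro, attr(scores, "accuracy"), tolerance = 1e-12)
  }
})

test_that("pearson correlation anchors and failure modes", {
  x <- matrix(rnorm(30), 5)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(x, x + 4), 1)
  expect_error(pearson_correlation(x, matrix(1, 5, 6)),
               class = "laminpop_parameter_error")
  expect_error(pearson_correlation(x, matrix(rnorm(10), 5)),
               class = "laminpop_dimension_error")
})

test_that("labelled contribution matching scores each population against truth", {
  set.seed(2)
  truth <- list(a = matrix(rnorm(40), 5), b = matrix(rnorm(40), 5))
  perfect <- match_contributions(truth, truth)
  expect_equal(perfect$correlation, c(1, 1))
  expect_equal(perfect$rel_mse, c(0, 0))
  zeros <- match_contributions(lapply(truth, function(m) 0 * m), truth)
  expect_equal(zeros$rel_mse, c(1, 1))
  expect_true(all(is.na(zeros$correlation)))  # constant estimate: undefined
  expect_error(match_contributions(truth[1], truth),
               class = "laminpop_dimension_error")
})

test_that("unlabelled matching recovers a planted permutation (exhaustive oracle)", {
  set.seed(4)
  truth <- setNames(lapply(1:4, function(i) matrix(rnorm(60), 6)),
                    c("p1", "p2", "p3", "p4"))
  shuffled <- truth[c(3, 1, 4, 2)]
  names(shuffled) <- paste0("comp_", 1:4)
  mc <- match_contributions(shuffled, truth, labelled = FALSE)
  expect_equal(mc$component, c("comp_2", "comp_4", "comp_1", "comp_3"))
  expect_equal(mc$correlation, rep(1, 4))
  # sign flips are tolerated when requested
  flipped <- lapply(shuffled, function(m) -m)
  mc2 <- match_contributions(flipped, truth, labelled = FALSE,
                             allow_sign_flip = TRUE)
  expect_equal(mc2$correlation, rep(1, 4))
  expect_equal(mc2$rel_mse, rep(0, 4), tolerance = 1e-12)
})
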