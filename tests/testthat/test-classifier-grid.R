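# Grid enumeration, confusion metrics, cross-validation mechanics, and the
# fitted one-vs-rest classifiers.

test_that("the default grid enumerates to the full Cartesian product", {
  cfg <- enumerate_configs(grid_spec())
  expect_equal(nrow(cfg), 80L)
  expect_equal(nrow(cfg), 2L * 2L * 2L * 5L * 2L)  # independent product
  expect_equal(cfg$config_id, seq_len(80L))
  one <- enumerate_configs(grid_spec(stem = FALSE, vectorizer = "count",
                                     penalty = "l1", C = 1,
                                     class_weight = "none"))
  expect_equal(nrow(one), 1L)
  expect_error(grid_spec(penalty = character(0)), "axis")
})

test_that("confusion metrics evaluate their defining formulas", {
  # TP=3, FP=1, FN=7, TN=89
  labels <- c(rep(TRUE, 10), rep(FALSE, 90))
  probs <- c(rep(0.9, 3), rep(0.1, 7), rep(0.9, 1), rep(0.1, 89))
  m <- confusion_metrics(labels, probs)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.30)
  expect_equal(m$f1, 2 * 0.75 * 0.3 / (0.75 + 0.3), tolerance = 1e-12)
  expect_equal(m$specificity, 89 / 90)
  expect_equal(m$npv, 89 / 96)

  perfect <- confusion_metrics(c(TRUE, FALSE), c(1, 0))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$brier, 0)

  none <- confusion_metrics(c(TRUE, FALSE, FALSE), c(0.1, 0.2, 0.3))
  expect_equal(none$precision, 0)
  expect_true(none$undefined["precision"])
  expect_equal(none$specificity, 1)

  expect_error(confusion_metrics(c(TRUE), c(0.5, 0.5)), "equal length")
})

test_that("cross-validation skips rare specialties and is seed-deterministic", {
  sep <- separable_corpus(40, keyword_rate = 1.0)
  config <- list(stem = FALSE, vectorizer = "count", penalty = "l2",
                 C = 1, class_weight = "none")
  rare <- sep$labeled
  rare$gold_specialty[rare$gold_specialty == "cardiology"] <- "dermatology"
  rare$gold_specialty[seq_len(4)] <- "cardiology"
  expect_true(cross_validate(rare, "cardiology", config, k = 5)$skipped)

  a <- cross_validate(sep$labeled, "cardiology", config, seed = 5L)
  b <- cross_validate(sep$labeled, "cardiology", config, seed = 5L)
  expect_equal(a$folds, b$folds)
  expect_false(a$skipped)
  # separable data: near-perfect cross-validated F1
  expect_gte(a$mean[["f1"]], 0.95)
  # fold-level F1 identity
  with(a$folds, expect_equal(f1, ifelse(precision + recall > 0,
                                        2 * precision * recall /
                                          (precision + recall), 0),
                             tolerance = 1e-12))
})

test_that("fold assignment partitions the corpus and stratifies positives", {
  y <- c(rep(TRUE, 20), rep(FALSE, 80))
  folds <- specwait:::make_stratified_folds(y, 5, seed = 3L)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 100L)
  expect_equal(as.vector(table(folds[y])), rep(4L, 5))  # 4 positives per fold
})

test_that("balanced class weights follow w_c = n_total / (2 n_c)", {
  y <- c(rep(TRUE, 10), rep(FALSE, 90))
  w <- specwait:::.balanced_weights(y)
  expect_equal(unique(w[y]), 100 / (2 * 10))
  expect_equal(unique(w[!y]), 100 / (2 * 90))
  expect_equal(unique(w[y]) / unique(w[!y]), 9)
})

test_that("stronger L1 penalties never increase the number of nonzero weights", {
  sep <- separable_corpus(50, keyword_rate = 0.6)
  nz <- vapply(c(10, 1, 0.1, 0.01, 0.001), function(C) {
    clf <- fit_specialty_classifier(
      sep$labeled, "cardiology",
      list(stem = FALSE, vectorizer = "count", penalty = "l1", C = C,
           class_weight = "none"))
    sum(clf$weights != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("prediction is the logistic of a linear score in the counts", {
  sep <- separable_corpus(50, keyword_rate = 1.0)
  clf <- fit_specialty_classifier(
    sep$labeled, "cardiology",
    list(stem = FALSE, vectorizer = "count", penalty = "l2", C = 1,
         class_weight = "none"))
  p <- predict(clf, sep$labeled$text)
  expect_true(all(p > 0 & p < 1))
  # no in-vocabulary tokens -> plogis(intercept)
  expect_equal(predict(clf, "zzzz qqqq"), plogis(clf$intercept))
  # doubling a note's text doubles its contribution to the log-odds
  txt <- sep$labeled$text[1]
  lo1 <- qlogis(predict(clf, txt)) - clf$intercept
  lo2 <- qlogis(predict(clf, paste(txt, txt))) - clf$intercept
  expect_equal(lo2, 2 * lo1, tolerance = 1e-6)
  expect_error(
    fit_specialty_classifier(
      transform(sep$labeled, gold_specialty = "cardiology"), "cardiology",
      list(stem = FALSE, vectorizer = "count", penalty = "l2", C = 1,
           class_weight = "none")),
    "single-class")
})

test_that("a refit on one fold's training set reproduces that fold's metrics", {
  sep <- separable_corpus(40, keyword_rate = 0.8)
  config <- list(stem = FALSE, vectorizer = "count", penalty = "l2",
                 C = 1, class_weight = "balanced")
  y <- sep$labeled$gold_specialty == "cardiology"
  folds <- specwait:::make_stratified_folds(y, 5, seed = 8L)
  cv <- cross_validate(sep$labeled, "cardiology", config, k = 5,
                       folds = folds)
  f <- 1L
  clf <- fit_specialty_classifier(sep$labeled[folds != f, ], "cardiology",
                                  config)
  m <- confusion_metrics(y[folds == f],
                         predict(clf, sep$labeled$text[folds == f]), 0.5)
  expect_equal(unlist(m[c("precision", "recall", "f1")]),
               unlist(cv$folds[f, c("precision", "recall", "f1")]),
               tolerance = 1e-6)
})
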