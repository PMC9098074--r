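# Diagnostic tables: F1 vs training size, accuracy by note length with
# small-cell suppression, and the confidence-threshold sweep.

make_best <- function(specialty, n, f1) {
  list(
    selections = data.frame(
      specialty = specialty, scheme = "best_f1",
      config_id = 1L, stem = FALSE, vectorizer = "count", penalty = "l2",
      C = 1, class_weight = "none", precision = f1, recall = f1, f1 = f1,
      fallback = FALSE, stringsAsFactors = FALSE),
    counts = data.frame(specialty = specialty, n = n,
                        stringsAsFactors = FALSE))
}

test_that("F1-vs-size table joins counts with best-F1 selections", {
  fx <- make_best(c("cardiology", "dermatology", "urology"),
                  n = c(100, 400, 900), f1 = c(0.5, 0.7, 0.9))
  tab <- f1_vs_training_size(fx$selections, fx$counts)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$n_notes, c(900, 400, 100))  # descending
  # constructed monotone signal-to-size design: positive rank correlation
  expect_gt(cor(tab$n_notes, tab$best_f1, method = "spearman"), 0)

  single <- make_best("cardiology", 10, 0.5)
  expect_equal(nrow(f1_vs_training_size(single$selections, single$counts)),
               1L)
  expect_error(f1_vs_training_size(fx$selections, single$counts),
               "different specialty sets")
})

test_that("length-accuracy rows suppress small cells and reward perfect models", {
  sep <- separable_corpus(60, keyword_rate = 1.0)
  clfs <- lapply(c("cardiology", "dermatology"), function(sp) {
    fit_specialty_classifier(
      sep$labeled, sp, list(stem = FALSE, vectorizer = "count",
                            penalty = "l2", C = 10, class_weight = "none"))
  })
  tab <- accuracy_by_note_length(clfs, sep$labeled)
  expect_true(all(tab$suppressed == (tab$n_notes < 5)))
  expect_true(all(is.na(tab$mean_accuracy[tab$suppressed])))
  # fully separable notes: accuracy 1.0 at every reported length
  expect_true(all(tab$mean_accuracy[!tab$suppressed] == 1))
  expect_equal(sum(tab$n_notes), nrow(sep$labeled))
})

test_that("uninformative short notes drag accuracy down at small lengths", {
  sep <- separable_corpus(80, keyword_rate = 0.9)
  vocabs <- specialty_vocabularies(sep$config)
  clfs <- lapply(c("cardiology", "dermatology"), function(sp) {
    fit_specialty_classifier(
      sep$labeled, sp, list(stem = FALSE, vectorizer = "count",
                            penalty = "l2", C = 10, class_weight = "none"))
  })
  # constructed gold set: short notes are filler-only, long notes keyworded
  set.seed(33)
  mk <- function(sp, len, keyworded, id) {
    pool <- if (keyworded) vocabs[[sp]] else vocabs$.shared
    data.frame(patient_id = id, note_id = id,
               date = as.Date("2015-06-01"),
               text = paste(sample(pool, len, TRUE), collapse = " "),
               gold_specialty = sp, stringsAsFactors = FALSE)
  }
  rows <- c(
    lapply(1:20, function(i) mk("cardiology", 7, FALSE, sprintf("s%03d", i))),
    lapply(1:20, function(i) mk("cardiology", 60, TRUE, sprintf("l%03d", i))),
    lapply(1:20, function(i) mk("dermatology", 7, FALSE, sprintf("t%03d", i))),
    lapply(1:20, function(i) mk("dermatology", 60, TRUE, sprintf("m%03d", i))))
  gold <- do.call(rbind, rows)
  tab <- accuracy_by_note_length(clfs, gold)
  acc_short <- tab$mean_accuracy[tab$tokens == 7]
  acc_long <- tab$mean_accuracy[tab$tokens == 60]
  expect_lt(acc_short, acc_long)
})

test_that("threshold sweep: sensitivity non-increasing, baseline constant", {
  ref <- reference_run()
  sweep <- threshold_sweep(ref$classifiers, ref$labeled, ref$notes,
                           ref$cohort$claims,
                           thresholds = seq(0.1, 0.9, by = 0.2),
                           study_year = 2015)
  expect_true(all(diff(sweep$mean_sensitivity) <= 1e-12))
  expect_equal(length(unique(sweep$baseline_median)), 1L)
  expect_gte(sweep$mean_sensitivity[1], 0.9)  # near-zero threshold
  expect_error(
    threshold_sweep(ref$classifiers, ref$labeled, ref$notes,
                    ref$cohort$claims, thresholds = c(0.5, 0.1),
                    study_year = 2015),
    "ascending")
})
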