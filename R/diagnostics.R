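## Diagnostic analyses: F1 against training-set size, accuracy by note
## length with small-cell suppression, and the confidence-threshold sweep
## with a gold-only baseline.

#' Best F1 against number of training notes
#'
#' Joins the per-specialty gold-note counts with each specialty's best-F1
#' selection, the table behind a performance-vs-dataset-size plot.
#'
#' @param selections best-F1 rows of [select_models()].
#' @param counts [specialty_tally()] output (true counts, not the suppressed
#'   display table).
#' @return data frame (`specialty`, `n_notes`, `best_f1`) ordered by
#'   `n_notes` descending.
#' @export
f1_vs_training_size <- function(selections, counts) {
  stopifnot(all(selections$scheme == "best_f1"))
  if (!setequal(selections$specialty, counts$specialty)) {
    stop("selections and counts cover different specialty sets",
         call. = FALSE)
  }
  m <- merge(counts, selections[, c("specialty", "f1")], by = "specialty")
  out <- data.frame(specialty = m$specialty, n_notes = m$n,
                    best_f1 = m$f1, stringsAsFactors = FALSE)
  out <- out[order(-out$n_notes, out$specialty), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classification accuracy by note length
#'
#' For every note length (token count) present in the gold set, computes each
#' classifier's binary accuracy (positive class = its specialty) over the
#' gold notes of that length, then averages unweighted across classifiers.
#' Lengths with fewer than `min_notes` notes are suppressed: the row is kept
#' with `suppressed = TRUE` and no accuracy value, mirroring the small-cell
#' rule of [specialty_counts()].
#'
#' @param classifiers named list of fitted classifiers (typically the
#'   best-F1 configuration per specialty).
#' @param labeled gold-labelled notes.
#' @param min_notes suppression threshold on notes per length.
#' @param threshold decision threshold.
#' @return data frame (`tokens`, `n_notes`, `mean_accuracy`, `suppressed`)
#'   ordered by `tokens`.
#' @export
accuracy_by_note_length <- function(classifiers, labeled, min_notes = 5,
                                    threshold = 0.5) {
  len <- count_tokens(labeled$text)
  correct <- vapply(classifiers, function(clf) {
    pred <- predict(clf, labeled$text) >= threshold
    pred == (labeled$gold_specialty == clf$specialty)
  }, logical(nrow(labeled)))
  correct <- matrix(correct, nrow = nrow(labeled))

  lens <- sort(unique(len))
  rows <- lapply(lens, function(L) {
    sel <- len == L
    n <- sum(sel)
    if (n < min_notes) {
      data.frame(tokens = L, n_notes = n, mean_accuracy = NA_real_,
                 suppressed = TRUE)
    } else {
      # per-classifier accuracy at this length, then unweighted mean
      acc <- colMeans(correct[sel, , drop = FALSE])
      data.frame(tokens = L, n_notes = n, mean_accuracy = mean(acc),
                 suppressed = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confidence-threshold sweep
#'
#' For each threshold: classification metrics on the gold set (per-specialty
#' one-vs-rest precision and sensitivity, averaged unweighted across
#' classifiers), and the deployed median wait from running
#' deploy-link-summarize on the full cohort at that threshold, pooled over
#' the classifiers' specialties. The gold-only baseline column is the median
#' wait computed from the gold-labelled pairs alone and is constant across
#' rows.
#'
#' @param classifiers named list of fitted classifiers.
#' @param labeled gold-labelled notes (the evaluation set).
#' @param notes full (short-note filtered) note stream.
#' @param claims claims data frame.
#' @param thresholds ascending thresholds in (0, 1).
#' @param study_year referral year.
#' @return data frame (`threshold`, `mean_ppv`, `mean_sensitivity`,
#'   `median_wait`, `n_obs`, `median_defined`, `baseline_median`).
#' @export
threshold_sweep <- function(classifiers, labeled, notes, claims,
                            thresholds = seq(0.05, 0.95, by = 0.05),
                            study_year) {
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must be strictly ascending and inside (0, 1)",
         call. = FALSE)
  }
  gold_probs <- lapply(classifiers, function(clf) predict(clf, labeled$text))
  full_probs <- lapply(classifiers, function(clf) predict(clf, notes$text))
  specialties <- unname(vapply(classifiers, `[[`, character(1L), "specialty"))

  # baseline: waits measurable from the gold pairs themselves
  gold_pos <- data.frame(
    patient_id = labeled$patient_id, note_id = labeled$note_id,
    date = labeled$date, specialty = labeled$gold_specialty,
    stringsAsFactors = FALSE
  )
  gold_pos <- gold_pos[gold_pos$specialty %in% specialties, , drop = FALSE]
  gold_waits <- link_wait_times(gold_pos, claims, study_year)
  baseline <- if (nrow(gold_waits)) stats::median(gold_waits$wait) else NA_real_

  rows <- lapply(thresholds, function(thr) {
    ppv <- sen <- numeric(length(classifiers))
    for (i in seq_along(classifiers)) {
      m <- confusion_metrics(
        labeled$gold_specialty == specialties[i], gold_probs[[i]], thr)
      ppv[i] <- m$precision
      sen[i] <- m$recall
    }
    pos <- do.call(rbind, lapply(seq_along(classifiers), function(i) {
      keep <- full_probs[[i]] >= thr
      data.frame(patient_id = notes$patient_id[keep],
                 note_id = notes$note_id[keep], date = notes$date[keep],
                 specialty = specialties[i], stringsAsFactors = FALSE)
    }))
    waits <- link_wait_times(pos, claims, study_year)
    data.frame(
      threshold = thr,
      mean_ppv = mean(ppv),
      mean_sensitivity = mean(sen),
      median_wait = if (nrow(waits)) stats::median(waits$wait) else NA_real_,
      n_obs = nrow(waits),
      median_defined = nrow(waits) > 0L,
      baseline_median = baseline
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
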