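## Deployment of the gated classifiers on the full note stream, linkage of
## predicted referrals to first consult claims, and wait-time quantiles with
## percentile-bootstrap confidence intervals.

#' Deploy classifiers on all notes
#'
#' Scores every note with every classifier independently; a note may be
#' positive for several specialties or none. Notes should already be
#' short-note filtered.
#'
#' @param classifiers named list of [fit_specialty_classifier()] objects
#'   (names are ignored; each carries its specialty).
#' @param notes notes data frame.
#' @param threshold predicted-probability cutoff (inclusive).
#' @return data frame of predicted positives: `patient_id`, `note_id`,
#'   `date`, `specialty`, `prob`.
#' @export
deploy_classifiers <- function(classifiers, notes, threshold = 0.5) {
  out <- lapply(classifiers, function(clf) {
    prob <- predict(clf, notes$text)
    keep <- prob >= threshold
    data.frame(
      patient_id = notes$patient_id[keep],
      note_id = notes$note_id[keep],
      date = notes$date[keep],
      specialty = rep(clf$specialty, sum(keep)),
      prob = prob[keep],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Link predicted referrals to first consult claims
#'
#' Per patient and specialty: the earliest positively-predicted note dated in
#' the study year is the first referral to that specialty (date ties break by
#' `note_id`); it links to the earliest claim of the same specialty dated on
#' or after the note and no later than the end of `study_year + 1` (referrals
#' late in the year may only be consulted the following year). Patients with
#' no qualifying claim contribute nothing. Linkage is independent across
#' specialties, so a patient can contribute one observation per specialty.
#'
#' @param positives output of [deploy_classifiers()] (or any data frame with
#'   `patient_id`, `note_id`, `date`, `specialty`).
#' @param claims claims data frame.
#' @param study_year referral calendar year.
#' @return data frame of wait observations: `patient_id`, `specialty`,
#'   `referral_date`, `consult_date`, `wait` (integer days >= 0).
#' @export
link_wait_times <- function(positives, claims, study_year) {
  if (nrow(positives) == 0L) {
    return(data.frame(patient_id = character(0L), specialty = character(0L),
                      referral_date = as.Date(character(0L)),
                      consult_date = as.Date(character(0L)),
                      wait = integer(0L)))
  }
  positives$date <- as_iso_date(positives$date)
  claims$date <- as_iso_date(claims$date)
  positives$specialty <- canon_specialty(positives$specialty)
  claims$specialty <- canon_specialty(claims$specialty)

  pos <- positives[date_year(positives$date) == study_year, , drop = FALSE]
  pos <- pos[order(pos$patient_id, pos$specialty, pos$date, pos$note_id), ,
             drop = FALSE]
  first <- !duplicated(pos[, c("patient_id", "specialty")])
  pos <- pos[first, , drop = FALSE]

  cl <- claims[claims$date <= year_end(study_year + 1L), , drop = FALSE]
  m <- merge(pos[, c("patient_id", "specialty", "date")],
             cl[, c("patient_id", "specialty", "date")],
             by = c("patient_id", "specialty"),
             suffixes = c("_ref", "_claim"))
  m <- m[m$date_claim >= m$date_ref, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(patient_id = character(0L), specialty = character(0L),
                      referral_date = as.Date(character(0L)),
                      consult_date = as.Date(character(0L)),
                      wait = integer(0L)))
  }
  m <- m[order(m$patient_id, m$specialty, m$date_claim), , drop = FALSE]
  m <- m[!duplicated(m[, c("patient_id", "specialty")]), , drop = FALSE]
  out <- data.frame(
    patient_id = m$patient_id,
    specialty = m$specialty,
    referral_date = m$date_ref,
    consult_date = m$date_claim,
    wait = as.integer(m$date_claim - m$date_ref),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Wait-time quantiles with bootstrap confidence intervals
#'
#' Point estimates are empirical quantiles of the observed waits; the 95%
#' interval per quantile is the 2.5th/97.5th percentile of that quantile over
#' `B` resamples of the observations with replacement (percentile bootstrap).
#'
#' @param waits integer vector of wait days for one specialty, or a
#'   [link_wait_times()] data frame restricted to one specialty.
#' @param quantile_levels quantile levels to estimate.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @param specialty optional label carried into the result.
#' @return object of class `wait_time_estimate`: `n`, named `point`
#'   estimates, `lower`/`upper` CI bounds, `B`, `seed`, `conf`.
#' @export
summarize_waits <- function(waits, quantile_levels = c(0.5, 0.75, 0.9),
                            B = 1000, seed = 1L, conf = 0.95,
                            specialty = NULL) {
  if (is.data.frame(waits)) {
    if (is.null(specialty) && length(unique(waits$specialty)) == 1L) {
      specialty <- waits$specialty[1L]
    }
    waits <- waits$wait
  }
  if (length(waits) == 0L) {
    stop("cannot summarize an empty set of wait observations", call. = FALSE)
  }
  stopifnot(B >= 1)
  qnames <- paste0("p", round(quantile_levels * 100))
  point <- stats::setNames(
    stats::quantile(waits, quantile_levels, names = FALSE), qnames)
  n <- length(waits)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      stats::quantile(waits[sample.int(n, n, replace = TRUE)],
                      quantile_levels, names = FALSE)
    }, numeric(length(quantile_levels)))
  })
  boot <- matrix(boot, nrow = length(quantile_levels))
  alpha <- (1 - conf) / 2
  lower <- stats::setNames(
    apply(boot, 1L, stats::quantile, probs = alpha, names = FALSE), qnames)
  upper <- stats::setNames(
    apply(boot, 1L, stats::quantile, probs = 1 - alpha, names = FALSE), qnames)
  structure(
    list(specialty = specialty, n = n, levels = quantile_levels,
         point = point, lower = pmin(lower, point),
         upper = pmax(upper, point), B = as.integer(B),
         seed = as.integer(seed), conf = conf),
    class = "wait_time_estimate"
  )
}

#' @method print wait_time_estimate
#' @export
print.wait_time_estimate <- function(x, ...) {
  cat("<wait_time_estimate>",
      if (!is.null(x$specialty)) x$specialty else "", sprintf(
        "n = %d, %d%% CI from %d bootstrap resamples (seed %d)\n",
        x$n, round(100 * x$conf), x$B, x$seed))
  for (q in names(x$point)) {
    cat(sprintf("  %-4s %6.1f days  [%.1f, %.1f]\n", q, x$point[q],
                x$lower[q], x$upper[q]))
  }
  invisible(x)
}

#' Compare a wait-time estimate against a prior-period value
#'
#' A change is substantial when the prior value lies outside the estimate's
#' confidence interval (bounds inclusive: a value exactly on a bound is
#' inside, hence non-substantial). The direction comes from the sign of
#' (current point estimate - prior value).
#'
#' @param estimate a [summarize_waits()] object.
#' @param prior_value the earlier period's point value, in days.
#' @param quantile which quantile to compare (name in `estimate$point`).
#' @return one of `"substantial increase"`, `"substantial decrease"`,
#'   `"non-substantial change"`.
#' @export
compare_periods <- function(estimate, prior_value, quantile = "p50") {
  stopifnot(inherits(estimate, "wait_time_estimate"),
            quantile %in% names(estimate$point))
  lo <- estimate$lower[quantile]
  hi <- estimate$upper[quantile]
  if (prior_value >= lo && prior_value <= hi) {
    return("non-substantial change")
  }
  if (estimate$point[quantile] > prior_value) {
    "substantial increase"
  } else {
    "substantial decrease"
  }
}
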