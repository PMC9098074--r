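## Gold-label derivation from the co-occurrence of referral notes and consult
## claims: short-note filter, single-pair rule, specialty exclusions, and the
## privacy-suppressed count table.

#' Count tokens in note text
#'
#' Token counts use the same normalization as the classifier features
#' (lowercase, punctuation and digits removed, whitespace split) but never
#' stemming, so a note's length is stable across pipeline configurations.
#'
#' @param text character vector.
#' @return integer vector of token counts.
#' @examples
#' count_tokens("Please see John for chest pain") # 6
#' @export
count_tokens <- function(text) {
  lengths(normalize_text(text, stem = FALSE))
}

#' Drop uninformative short notes
#'
#' Retains exactly the notes whose token count is at least `min_tokens`
#' (default 6: shorter notes are typically not true referral notes). The
#' number of removed notes is reported on the message stream.
#'
#' @param notes data frame with a `text` column.
#' @param min_tokens minimum token count (inclusive), at least 1.
#' @return the filtered notes data frame.
#' @export
filter_short_notes <- function(notes, min_tokens = 6) {
  stopifnot(min_tokens >= 1)
  if (nrow(notes) == 0L) return(notes)
  keep <- count_tokens(notes$text) >= min_tokens
  sw_log("short-note filter: removed %d of %d notes (fewer than %d tokens)",
         sum(!keep), length(keep), min_tokens)
  notes[keep, , drop = FALSE]
}

#' Derive gold specialty labels from single-pair patients
#'
#' A patient contributes a gold-labelled note exactly when they have one
#' referral note and one consult claim dated inside the study year: the
#' claim's specialty then labels the note. Patients with several notes or
#' several claims are excluded entirely (their pairing is ambiguous), as are
#' pairs whose claim specialty is on the exclusion list (by default
#' `"internal"`, whose consults overlap many organ-specific specialties).
#' Notes should already be short-note filtered; an uninformative stub removed
#' upstream does not disqualify its patient.
#'
#' @param notes data frame (`patient_id`, `note_id`, `date`, `text`).
#' @param claims data frame (`patient_id`, `specialty`, `date`).
#' @param study_year calendar year whose events are considered.
#' @param excluded_specialties specialty codes dropped after pairing
#'   (case-insensitive).
#' @return the labelled notes: the note columns plus `gold_specialty`,
#'   ordered by `note_id`.
#' @export
derive_gold_pairs <- function(notes, claims, study_year,
                              excluded_specialties = "internal") {
  stopifnot_cols(notes, c("patient_id", "note_id", "date", "text"), "notes")
  stopifnot_cols(claims, c("patient_id", "specialty", "date"), "claims")
  if (anyDuplicated(notes$note_id)) {
    stop("data error: duplicate note_id in notes", call. = FALSE)
  }
  notes$date <- as_iso_date(notes$date)
  claims$date <- as_iso_date(claims$date)

  ny <- notes[date_year(notes$date) == study_year, , drop = FALSE]
  cy <- claims[date_year(claims$date) == study_year, , drop = FALSE]
  one_note <- names(which(table(ny$patient_id) == 1L))
  one_claim <- names(which(table(cy$patient_id) == 1L))
  eligible <- intersect(one_note, one_claim)

  ny <- ny[ny$patient_id %in% eligible, , drop = FALSE]
  cy <- cy[cy$patient_id %in% eligible, , drop = FALSE]
  labeled <- merge(ny, cy[, c("patient_id", "specialty")], by = "patient_id")
  names(labeled)[names(labeled) == "specialty"] <- "gold_specialty"
  labeled$gold_specialty <- canon_specialty(labeled$gold_specialty)
  labeled <- labeled[!(labeled$gold_specialty %in%
                         canon_specialty(excluded_specialties)), ,
                     drop = FALSE]
  labeled <- labeled[order(labeled$note_id), , drop = FALSE]
  rownames(labeled) <- NULL
  labeled
}

#' Exact per-specialty tally of labelled notes
#'
#' Internal companion of [specialty_counts()] carrying the true counts; use
#' only where unsuppressed numbers are permitted (joins, validation).
#'
#' @param labeled output of [derive_gold_pairs()].
#' @return data frame (`specialty`, `n`), descending by count.
#' @export
specialty_tally <- function(labeled) {
  if (nrow(labeled) == 0L) {
    return(data.frame(specialty = character(0L), n = integer(0L)))
  }
  tab <- table(labeled$gold_specialty)
  out <- data.frame(specialty = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$specialty), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Privacy-suppressed per-specialty count table
#'
#' One row per specialty present in the labelled set, descending by true
#' count; counts below `suppression_threshold` are rendered as the string
#' `"<5"` (more generally `"<threshold>"`) and the true small value is never
#' emitted. Specialties with zero labelled notes are absent rather than
#' rendered.
#'
#' @inheritParams specialty_tally
#' @param suppression_threshold counts strictly below this are suppressed.
#' @return data frame (`specialty`, `count`) with `count` as character.
#' @export
specialty_counts <- function(labeled, suppression_threshold = 5) {
  tal <- specialty_tally(labeled)
  data.frame(
    specialty = tal$specialty,
    count = ifelse(tal$n < suppression_threshold,
                   paste0("<", suppression_threshold),
                   as.character(tal$n)),
    stringsAsFactors = FALSE
  )
}
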