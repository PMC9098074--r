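## Synthetic EMR + claims cohort generator. Emulates the statistical structure
## the labelling and wait-time stages assume: per-specialty keyword
## vocabularies embedded in shared clinical filler, variable note lengths
## (including uninformative stubs under 6 tokens), patients with one or
## several events per year, and per-specialty log-normal wait distributions
## with known medians.

#' Configuration for the synthetic cohort generator
#'
#' The defaults define the reference study conditions used throughout the
#' package's validation: three specialties with 500 notes each, keyword rate
#' 0.6 over disjoint vocabularies, wait medians of 30/60/90 days with
#' log-normal dispersion 0.6, and a 20% multi-event patient rate.
#'
#' @param specialties character vector of at least two specialty codes.
#' @param notes_per_specialty positive integer; single-event patients
#'   generated per specialty.
#' @param keyword_vocab_size keyword types per specialty vocabulary.
#' @param shared_vocab_size shared (filler) vocabulary size.
#' @param keyword_rate proportion in \[0,1\] of note tokens drawn from the
#'   note's specialty vocabulary; the rest come from the shared vocabulary.
#' @param note_length_distribution list with `lengths` (positive integers,
#'   support must be usable for lengths below 6 so the short-note filter is
#'   exercised) and `probs`. Default: 5% mass on 2-5 tokens, 95% on a
#'   discretized log-normal over 6-150 tokens peaked near 45.
#' @param wait_median_days positive numeric, recycled across specialties;
#'   median of each specialty's wait distribution in days.
#' @param wait_dispersion log-normal sigma of the wait distribution
#'   (0 collapses every draw to the rounded median).
#' @param multi_event_rate proportion of patients given extra (confounder)
#'   notes and/or claims in the year.
#' @param study_year calendar year of the simulated referrals.
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(specialties = c("cardiology", "dermatology",
                                             "gastroenterology"),
                             notes_per_specialty = 500,
                             keyword_vocab_size = 40,
                             shared_vocab_size = 200,
                             keyword_rate = 0.6,
                             note_length_distribution = NULL,
                             wait_median_days = c(30, 60, 90),
                             wait_dispersion = 0.6,
                             multi_event_rate = 0.2,
                             study_year = 2015,
                             seed = 1L) {
  specialties <- canon_specialty(specialties)
  if (length(specialties) < 2L || anyDuplicated(specialties)) {
    stop("configuration error: need at least 2 distinct specialties",
         call. = FALSE)
  }
  if (notes_per_specialty < 1) {
    stop("configuration error: notes_per_specialty must be >= 1",
         call. = FALSE)
  }
  if (keyword_rate < 0 || keyword_rate > 1) {
    stop("configuration error: keyword_rate must lie in [0,1]", call. = FALSE)
  }
  if (multi_event_rate < 0 || multi_event_rate > 1) {
    stop("configuration error: multi_event_rate must lie in [0,1]",
         call. = FALSE)
  }
  if (wait_dispersion < 0) {
    stop("configuration error: wait_dispersion must be non-negative",
         call. = FALSE)
  }
  if (any(wait_median_days <= 0)) {
    stop("configuration error: wait medians must be positive", call. = FALSE)
  }
  if (is.null(note_length_distribution)) {
    short <- 2:5
    long <- 6:150
    p_long <- stats::dlnorm(long, meanlog = log(45), sdlog = 0.45)
    note_length_distribution <- list(
      lengths = c(short, long),
      probs = c(rep(0.05 / length(short), length(short)),
                0.95 * p_long / sum(p_long))
    )
  }
  nld <- note_length_distribution
  if (!is.list(nld) || is.null(nld$lengths) || is.null(nld$probs) ||
      length(nld$lengths) != length(nld$probs) ||
      any(nld$lengths < 1) || any(nld$probs < 0)) {
    stop("configuration error: invalid note_length_distribution",
         call. = FALSE)
  }
  nld$probs <- nld$probs / sum(nld$probs)
  wait_median_days <- rep_len(wait_median_days, length(specialties))
  names(wait_median_days) <- specialties
  structure(
    list(specialties = specialties,
         notes_per_specialty = as.integer(notes_per_specialty),
         keyword_vocab_size = as.integer(keyword_vocab_size),
         shared_vocab_size = as.integer(shared_vocab_size),
         keyword_rate = keyword_rate,
         note_length_distribution = nld,
         wait_median_days = wait_median_days,
         wait_dispersion = wait_dispersion,
         multi_event_rate = multi_event_rate,
         study_year = as.integer(study_year),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# deterministic letter-only word lists; letter-only so the punctuation/digit
# normalization leaves synthetic tokens intact
.make_words <- function(prefix, n) {
  if (n > 26L * 26L) {
    stop("configuration error: vocabulary size above ", 26L * 26L,
         " is not supported", call. = FALSE)
  }
  i <- seq_len(n) - 1L
  paste0(prefix, "q", letters[i %/% 26L + 1L], letters[i %% 26L + 1L])
}

#' Specialty and shared vocabularies of a synthetic configuration
#'
#' Word lists are deterministic functions of the specialty codes, so two
#' configurations with the same specialties share them. Specialty
#' vocabularies must be pairwise disjoint (and disjoint from the shared
#' filler vocabulary); violations are a configuration error.
#'
#' @param config a `synthetic_config`.
#' @return list with one character vector per specialty plus `.shared`.
#' @export
specialty_vocabularies <- function(config) {
  prefixes <- gsub("[^a-z]", "", config$specialties)
  vocabs <- lapply(prefixes, .make_words, n = config$keyword_vocab_size)
  names(vocabs) <- config$specialties
  vocabs$.shared <- .make_words("common", config$shared_vocab_size)
  all <- unlist(vocabs, use.names = FALSE)
  if (anyDuplicated(all)) {
    stop("configuration error: specialty keyword vocabularies are not ",
         "disjoint", call. = FALSE)
  }
  vocabs
}

#' Draw one synthetic note text
#'
#' Each token is drawn from the specialty's keyword vocabulary with
#' probability `keyword_rate`, otherwise from the shared filler vocabulary.
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param specialty a specialty code configured in `config`.
#' @param length positive token count.
#' @param config a `synthetic_config`.
#' @param vocabs optional precomputed [specialty_vocabularies()] result.
#' @return a single string of `length` whitespace-joined tokens.
#' @export
sample_note_text <- function(specialty, length, config, vocabs = NULL) {
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  specialty <- canon_specialty(specialty)
  if (is.null(vocabs)) vocabs <- specialty_vocabularies(config)
  kw <- vocabs[[specialty]]
  if (is.null(kw)) stop("unknown specialty: ", specialty, call. = FALSE)
  use_kw <- stats::runif(length) < config$keyword_rate
  toks <- character(length)
  toks[use_kw] <- sample(kw, sum(use_kw), replace = TRUE)
  toks[!use_kw] <- sample(vocabs$.shared, sum(!use_kw), replace = TRUE)
  paste(toks, collapse = " ")
}

#' Draw synthetic waits in days
#'
#' Waits are log-normal with median `wait_median_days[specialty]` (scale
#' parameter `log(median)`) and sigma `wait_dispersion`, rounded to whole
#' days; strictly positive and right-skewed like observed referral waits.
#'
#' @param specialty configured specialty code.
#' @param config a `synthetic_config`.
#' @param n number of draws.
#' @return integer vector of non-negative day counts.
#' @export
sample_wait_days <- function(specialty, config, n = 1) {
  specialty <- canon_specialty(specialty)
  med <- config$wait_median_days[specialty]
  if (is.na(med)) stop("unknown specialty: ", specialty, call. = FALSE)
  if (config$wait_dispersion == 0) {
    return(rep.int(as.integer(round(med)), n))
  }
  draws <- stats::rlnorm(n, meanlog = log(med), sdlog = config$wait_dispersion)
  pmax(0L, as.integer(round(draws)))
}

#' Generate a synthetic cohort of referral notes and consult claims
#'
#' For every single-event patient the generator emits exactly one referral
#' note (date uniform over the study year) and one consult claim of the same
#' specialty dated `referral + wait`, with the wait drawn from that
#' specialty's log-normal distribution; consults may therefore spill into the
#' following calendar year. A `multi_event_rate` fraction of patients
#' additionally carries confounder events (an extra note, an extra claim, or
#' both) with uniformly drawn specialties and dates, which disqualifies them
#' from the downstream gold-pair rule.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `referral_cohort`: list with `notes`
#'   (patient_id, note_id, date, text), `claims` (patient_id, specialty,
#'   date), `truth` (note_id, specialty, wait_days; `NA` wait for confounder
#'   notes), `patients` (per-patient event counts within the study year and a
#'   `single_pair` flag), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  vocabs <- specialty_vocabularies(config)
  with_seed(config$seed, {
    sp <- config$specialties
    nps <- config$notes_per_specialty
    n <- length(sp) * nps
    start <- year_start(config$study_year)
    ndays <- as.integer(year_end(config$study_year) - start) + 1L

    patient_id <- sprintf("P%06d", seq_len(n))
    note_specialty <- rep(sp, each = nps)
    ref_date <- start + (sample.int(ndays, n, replace = TRUE) - 1L)
    wait <- unlist(lapply(sp, function(s) {
      sample_wait_days(s, config, nps)
    }), use.names = FALSE)
    lengths <- sample(config$note_length_distribution$lengths, n,
                      replace = TRUE,
                      prob = config$note_length_distribution$probs)
    text <- vapply(seq_len(n), function(i) {
      sample_note_text(note_specialty[i], lengths[i], config, vocabs)
    }, character(1L))

    notes <- data.frame(
      patient_id = patient_id,
      note_id = sprintf("N%06d-1", seq_len(n)),
      date = ref_date,
      text = text,
      stringsAsFactors = FALSE
    )
    claims <- data.frame(
      patient_id = patient_id,
      specialty = note_specialty,
      date = ref_date + wait,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      note_id = notes$note_id,
      specialty = note_specialty,
      wait_days = as.integer(wait),
      stringsAsFactors = FALSE
    )

    # confounder events: maximally uninformative (uniform specialty and date)
    is_multi <- stats::runif(n) < config$multi_event_rate
    idx <- which(is_multi)
    if (length(idx)) {
      kind <- sample(c("note", "claim", "both"), length(idx), replace = TRUE)
      nidx <- idx[kind != "claim"]
      if (length(nidx)) {
        xsp <- sample(sp, length(nidx), replace = TRUE)
        xdate <- start + (sample.int(ndays, length(nidx), replace = TRUE) - 1L)
        xlen <- sample(config$note_length_distribution$lengths, length(nidx),
                       replace = TRUE,
                       prob = config$note_length_distribution$probs)
        xtext <- vapply(seq_along(nidx), function(i) {
          sample_note_text(xsp[i], xlen[i], config, vocabs)
        }, character(1L))
        notes <- rbind(notes, data.frame(
          patient_id = patient_id[nidx],
          note_id = sprintf("N%06d-2", nidx),
          date = xdate,
          text = xtext,
          stringsAsFactors = FALSE
        ))
        truth <- rbind(truth, data.frame(
          note_id = sprintf("N%06d-2", nidx),
          specialty = xsp,
          wait_days = NA_integer_,
          stringsAsFactors = FALSE
        ))
      }
      cidx <- idx[kind != "note"]
      if (length(cidx)) {
        claims <- rbind(claims, data.frame(
          patient_id = patient_id[cidx],
          specialty = sample(sp, length(cidx), replace = TRUE),
          date = start + (sample.int(ndays, length(cidx), replace = TRUE) - 1L),
          stringsAsFactors = FALSE
        ))
      }
    }

    yr <- config$study_year
    n_notes_year <- table(factor(notes$patient_id[date_year(notes$date) == yr],
                                 levels = patient_id))
    n_claims_year <- table(factor(claims$patient_id[date_year(claims$date) == yr],
                                  levels = patient_id))
    patients <- data.frame(
      patient_id = patient_id,
      true_specialty = note_specialty,
      n_notes_year = as.integer(n_notes_year),
      n_claims_year = as.integer(n_claims_year),
      stringsAsFactors = FALSE
    )
    patients$single_pair <-
      patients$n_notes_year == 1L & patients$n_claims_year == 1L

    structure(
      list(notes = notes, claims = claims, truth = truth,
           patients = patients, config = config),
      class = "referral_cohort"
    )
  })
}

#' @method print referral_cohort
#' @export
print.referral_cohort <- function(x, ...) {
  cat("<referral_cohort>", nrow(x$notes), "notes,", nrow(x$claims),
      "claims,", length(x$config$specialties), "specialties, study year",
      x$config$study_year, "\n")
  cat("  single-pair patients:", sum(x$patients$single_pair), "of",
      nrow(x$patients), "\n")
  invisible(x)
}
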