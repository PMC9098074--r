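# Independent brute-force oracles and shared fixtures. The oracles never call
# the implementation paths they check.

# gold-pair oracle: loop over patients, count their in-year events directly
oracle_gold_pairs <- function(notes, claims, study_year,
                              excluded = "internal") {
  out <- list()
  for (p in unique(notes$patient_id)) {
    pn <- notes[notes$patient_id == p &
                  format(as.Date(notes$date), "%Y") == study_year, ,
                drop = FALSE]
    pc <- claims[claims$patient_id == p &
                   format(as.Date(claims$date), "%Y") == study_year, ,
                 drop = FALSE]
    if (nrow(pn) == 1L && nrow(pc) == 1L) {
      sp <- tolower(trimws(pc$specialty))
      if (!(sp %in% tolower(trimws(excluded)))) {
        out[[length(out) + 1L]] <- data.frame(
          note_id = pn$note_id, gold_specialty = sp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(note_id = character(0L),
                      gold_specialty = character(0L)))
  }
  res <- do.call(rbind, out)
  res[order(res$note_id), , drop = FALSE]
}

# linkage oracle: per patient x specialty scan over all note/claim pairs
oracle_link <- function(positives, claims, study_year) {
  positives$date <- as.Date(positives$date)
  claims$date <- as.Date(claims$date)
  end <- as.Date(sprintf("%d-12-31", study_year + 1L))
  out <- list()
  keys <- unique(positives[, c("patient_id", "specialty")])
  for (i in seq_len(nrow(keys))) {
    p <- keys$patient_id[i]; s <- keys$specialty[i]
    pn <- positives[positives$patient_id == p & positives$specialty == s &
                      format(positives$date, "%Y") == study_year, ,
                    drop = FALSE]
    if (nrow(pn) == 0L) next
    pn <- pn[order(pn$date, pn$note_id), , drop = FALSE]
    ref <- pn$date[1L]
    pc <- claims[claims$patient_id == p & claims$specialty == s &
                   claims$date >= ref & claims$date <= end, , drop = FALSE]
    if (nrow(pc) == 0L) next
    consult <- min(pc$date)
    out[[length(out) + 1L]] <- data.frame(
      patient_id = p, specialty = s, referral_date = ref,
      consult_date = consult, wait = as.integer(consult - ref),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(0L), specialty = character(0L),
                      wait = integer(0L)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id, res$specialty), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# model-selection oracle: exhaustive scan with the documented tie-breaks
oracle_select <- function(df, scheme, floor = 0.3) {
  avail <- df[!df$skipped, , drop = FALSE]
  pick <- function(sub, key) {
    sub <- sub[order(-sub[[key]], -sub$mean_precision, sub$config_id), ,
               drop = FALSE]
    sub[1L, ]
  }
  if (scheme == "best_f1") {
    return(list(row = pick(avail, "mean_f1"), fallback = FALSE))
  }
  if (scheme == "precision_floor") {
    ok <- avail[avail$mean_recall >= floor, , drop = FALSE]
    if (nrow(ok)) return(list(row = pick(ok, "mean_precision"),
                              fallback = FALSE))
    return(list(row = pick(avail, "mean_precision"), fallback = TRUE))
  }
  ok <- avail[avail$mean_precision >= floor, , drop = FALSE]
  if (nrow(ok)) return(list(row = pick(ok, "mean_recall"), fallback = FALSE))
  list(row = pick(avail, "mean_recall"), fallback = TRUE)
}

# random event-stream fixture for the pairing/linkage oracles
random_events <- function(n_patients, seed, year = 2015) {
  set.seed(seed)
  sps <- c("cardiology", "dermatology", "internal")
  notes <- list(); claims <- list(); nid <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (j in seq_len(sample(0:3, 1L))) {
      nid <- nid + 1L
      notes[[nid]] <- data.frame(
        patient_id = pid, note_id = sprintf("N%04d", nid),
        date = as.Date(sprintf("%d-01-01", year - 1L)) +
          sample(0:1000, 1L),
        text = "alpha beta gamma delta epsilon zeta eta",
        stringsAsFactors = FALSE)
    }
    for (j in seq_len(sample(0:3, 1L))) {
      claims[[length(claims) + 1L]] <- data.frame(
        patient_id = pid, specialty = sample(sps, 1L),
        date = as.Date(sprintf("%d-01-01", year - 1L)) +
          sample(0:1000, 1L),
        stringsAsFactors = FALSE)
    }
  }
  list(notes = do.call(rbind, notes), claims = do.call(rbind, claims))
}
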