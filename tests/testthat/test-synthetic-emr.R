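# The synthetic cohort generator: determinism, event structure, keyword
# mixture, wait distribution, and the file-format round trip.

test_that("identical seeds give identical cohorts", {
  cfg <- synthetic_config(notes_per_specialty = 40, seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$notes, b$notes)
  expect_identical(a$claims, b$claims)
  expect_identical(a$truth, b$truth)
})

test_that("without multi-event patients every patient has one note and one claim", {
  cfg <- synthetic_config(notes_per_specialty = 80, multi_event_rate = 0,
                          seed = 3L)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$notes), 240L)
  expect_equal(nrow(co$claims), 240L)
  expect_equal(as.vector(table(co$notes$patient_id)), rep(1L, 240L))
  expect_equal(as.vector(table(co$claims$patient_id)), rep(1L, 240L))
  # claim specialty equals the note's true specialty; visit = referral + wait
  m <- merge(merge(co$notes, co$truth, by = "note_id"), co$claims,
             by = "patient_id", suffixes = c("_note", "_claim"))
  expect_equal(m$specialty_note, m$specialty_claim)
  expect_equal(as.integer(m$date_claim - m$date_note), m$wait_days)
  # all referral dates inside the study year
  expect_true(all(format(co$notes$date, "%Y") == "2015"))
})

test_that("gold-pair count matches a brute-force recount of per-patient events", {
  cfg <- synthetic_config(notes_per_specialty = 200, multi_event_rate = 0.2,
                          seed = 11L)
  co <- generate_cohort(cfg)
  # independent recount from the emitted tables
  n_notes <- table(factor(
    co$notes$patient_id[format(co$notes$date, "%Y") == "2015"],
    levels = co$patients$patient_id))
  n_claims <- table(factor(
    co$claims$patient_id[format(co$claims$date, "%Y") == "2015"],
    levels = co$patients$patient_id))
  single <- sum(n_notes == 1L & n_claims == 1L)
  expect_equal(sum(co$patients$single_pair), single)
  labeled <- derive_gold_pairs(co$notes, co$claims, 2015,
                               excluded_specialties = character(0))
  expect_equal(nrow(labeled), single)
})

test_that("note text is a keyword/filler mixture at the configured rate", {
  cfg <- synthetic_config(seed = 5L)
  vocabs <- specialty_vocabularies(cfg)
  set.seed(21)
  txt1 <- sample_note_text("cardiology", 10,
                           modifyList(cfg, list(keyword_rate = 1.0)), vocabs)
  expect_true(all(strsplit(txt1, " ")[[1]] %in% vocabs$cardiology))
  txt0 <- sample_note_text("cardiology", 10,
                           modifyList(cfg, list(keyword_rate = 0.0)), vocabs)
  expect_true(all(strsplit(txt0, " ")[[1]] %in% vocabs$.shared))
  # law of large numbers at rate 0.5
  txt <- sample_note_text("cardiology", 10000,
                          modifyList(cfg, list(keyword_rate = 0.5)), vocabs)
  frac <- mean(strsplit(txt, " ")[[1]] %in% vocabs$cardiology)
  expect_lt(abs(frac - 0.5), 0.02)
  expect_error(sample_note_text("podiatry", 10, cfg, vocabs),
               "unknown specialty")
})

test_that("wait draws are non-negative with the configured median", {
  cfg0 <- synthetic_config(wait_dispersion = 0,
                           wait_median_days = c(40, 40, 40), seed = 1L)
  expect_equal(sample_wait_days("cardiology", cfg0, 50), rep(40L, 50))
  cfg <- synthetic_config(wait_median_days = c(40, 40, 40), seed = 1L)
  set.seed(31)
  draws <- sample_wait_days("dermatology", cfg, 10000)
  expect_true(all(draws >= 0))
  expect_lt(abs(stats::median(draws) - 40) / 40, 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(specialties = "cardiology"),
               "at least 2")
  expect_error(synthetic_config(notes_per_specialty = 0), "must be >= 1")
  expect_error(synthetic_config(keyword_rate = 1.2), "keyword_rate")
  # a specialty named like the shared filler prefix collides
  expect_error(
    specialty_vocabularies(synthetic_config(
      specialties = c("common", "dermatology"))),
    "not disjoint")
})

test_that("notes, claims and truth round-trip through both file formats", {
  co <- generate_cohort(synthetic_config(notes_per_specialty = 15, seed = 9L))
  for (ext in c("jsonl", "tsv")) {
    nf <- tempfile(fileext = paste0(".", ext))
    cf <- tempfile(fileext = paste0(".", ext))
    tf <- tempfile(fileext = paste0(".", ext))
    write_notes(co$notes, nf); write_claims(co$claims, cf)
    write_truth(co$truth, tf)
    n2 <- read_notes(nf); c2 <- read_claims(cf); t2 <- read_truth(tf)
    rownames(n2) <- rownames(c2) <- rownames(t2) <- NULL
    expect_equal(n2$text, co$notes$text)
    expect_equal(n2$date, co$notes$date)
    expect_equal(c2$specialty, co$claims$specialty)
    expect_equal(c2$date, co$claims$date)
    expect_equal(t2$wait_days, co$truth$wait_days)
  }
})
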