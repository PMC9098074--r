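# Reference study conditions shared by the slower integration and acceptance
# tests: the default synthetic cohort (3 specialties x 500 notes, keyword
# rate 0.6, wait medians 30/60/90) with the full 80-configuration grid.
# Computed once per test run and cached.

.sw_test_cache <- new.env(parent = emptyenv())

reference_run <- function() {
  if (!exists("ref", .sw_test_cache)) {
    cfg <- synthetic_config(seed = 1150L)
    cohort <- generate_cohort(cfg)
    notes <- suppressMessages(filter_short_notes(cohort$notes))
    labeled <- derive_gold_pairs(notes, cohort$claims, cfg$study_year)
    cv <- grid_search(labeled, seed = 2300L)
    pf <- select_models(cv, "precision_floor")
    best <- select_models(cv, "best_f1")
    eligible <- gate_specialties(pf)
    classifiers <- lapply(eligible, function(sp) {
      fit_specialty_classifier(labeled, sp,
                               pf[pf$specialty == sp, , drop = FALSE])
    })
    names(classifiers) <- eligible
    assign("ref", list(config = cfg, cohort = cohort, notes = notes,
                       labeled = labeled, cv = cv, pf = pf, best = best,
                       eligible = eligible, classifiers = classifiers),
           .sw_test_cache)
  }
  get("ref", .sw_test_cache)
}

# small separable corpus for fast classifier tests
separable_corpus <- function(n_per = 60, keyword_rate = 1.0, seed = 99L) {
  cfg <- synthetic_config(
    notes_per_specialty = n_per, keyword_rate = keyword_rate,
    multi_event_rate = 0, wait_median_days = c(20, 40, 60), seed = seed)
  cohort <- generate_cohort(cfg)
  notes <- suppressMessages(filter_short_notes(cohort$notes))
  list(cohort = cohort,
       labeled = derive_gold_pairs(notes, cohort$claims, cfg$study_year),
       config = cfg)
}
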