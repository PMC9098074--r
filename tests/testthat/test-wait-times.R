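# Deployment thresholds, referral-to-consult linkage (against a brute-force
# oracle and a calendar oracle), bootstrap quantiles, and period comparison.

test_that("degenerate thresholds give all-positive and no-positive sets", {
  sep <- separable_corpus(30, keyword_rate = 1.0)
  clf <- fit_specialty_classifier(
    sep$labeled, "cardiology",
    list(stem = FALSE, vectorizer = "count", penalty = "l2", C = 1,
         class_weight = "none"))
  all_pos <- deploy_classifiers(list(clf), sep$labeled, threshold = 0)
  expect_equal(nrow(all_pos), nrow(sep$labeled))
  expect_equal(nrow(deploy_classifiers(list(clf), sep$labeled,
                                       threshold = 1.01)), 0L)
  # positives at a higher threshold nest inside those at a lower one
  p5 <- deploy_classifiers(list(clf), sep$labeled, threshold = 0.5)
  p6 <- deploy_classifiers(list(clf), sep$labeled, threshold = 0.6)
  expect_true(all(p6$note_id %in% p5$note_id))
})

test_that("waits are calendar-exact across the leap February", {
  pos <- data.frame(patient_id = "p1", note_id = "n1",
                    date = as.Date("2015-11-01"), specialty = "cardiology",
                    stringsAsFactors = FALSE)
  claims <- data.frame(patient_id = "p1", specialty = "cardiology",
                       date = as.Date("2016-04-01"),
                       stringsAsFactors = FALSE)
  w <- link_wait_times(pos, claims, 2015)
  expect_equal(w$wait, 152L)
  # independent calendar oracle: enumerate the days
  expect_equal(
    length(seq(as.Date("2015-11-01"), as.Date("2016-04-01"), by = "day")) - 1L,
    152L)
})

test_that("linkage honours the forward-in-time and outer-year window rules", {
  pos <- data.frame(patient_id = "p1", note_id = "n1",
                    date = as.Date("2015-06-15"), specialty = "cardiology",
                    stringsAsFactors = FALSE)
  before <- data.frame(patient_id = "p1", specialty = "cardiology",
                       date = as.Date("2015-06-01"))
  expect_equal(nrow(link_wait_times(pos, before, 2015)), 0L)
  late <- data.frame(patient_id = "p1", specialty = "cardiology",
                     date = as.Date("2017-01-10"))
  expect_equal(nrow(link_wait_times(pos, late, 2015)), 0L)
  edge <- data.frame(patient_id = "p1", specialty = "cardiology",
                     date = as.Date("2016-12-31"))
  expect_equal(nrow(link_wait_times(pos, edge, 2015)), 1L)
  # same-date note ties break by note_id
  pos2 <- rbind(pos, data.frame(patient_id = "p1", note_id = "n0",
                                date = as.Date("2015-06-15"),
                                specialty = "cardiology"))
  w <- link_wait_times(pos2, edge, 2015)
  expect_equal(nrow(w), 1L)
  expect_equal(w$referral_date, as.Date("2015-06-15"))
})

test_that("linkage agrees with the brute-force per-patient oracle", {
  for (seed in c(404L, 505L)) {
    ev <- random_events(100, seed)
    pos <- data.frame(patient_id = ev$notes$patient_id,
                      note_id = ev$notes$note_id, date = ev$notes$date,
                      specialty = sample(c("cardiology", "dermatology"),
                                         nrow(ev$notes), replace = TRUE),
                      stringsAsFactors = FALSE)
    got <- link_wait_times(pos, ev$claims, 2015)
    got <- got[order(got$patient_id, got$specialty), ]
    rownames(got) <- NULL
    want <- oracle_link(pos, ev$claims, 2015)
    expect_equal(got$patient_id, want$patient_id)
    expect_equal(got$wait, want$wait)
    expect_true(all(got$wait >= 0))
  }
})

test_that("quantile estimates and bootstrap intervals behave", {
  e <- summarize_waits(c(10, 20, 30), B = 50, seed = 2L)
  expect_equal(unname(e$point["p50"]), 20)
  one <- summarize_waits(5L, B = 20, seed = 2L)
  expect_equal(unname(one$point), rep(5, 3))
  expect_equal(unname(one$lower), rep(5, 3))
  expect_equal(unname(one$upper), rep(5, 3))
  expect_error(summarize_waits(integer(0)), "empty")
  # monotone quantiles and CI ordering on random draws
  set.seed(12)
  for (i in 1:5) {
    w <- rpois(50, 40)
    est <- summarize_waits(w, B = 100, seed = i)
    expect_true(all(diff(est$point) >= 0))
    expect_true(all(est$lower <= est$point & est$point <= est$upper))
  }
})

test_that("bootstrap CIs cover a known log-normal median", {
  covered <- vapply(1:20, function(i) {
    set.seed(7000 + i)
    w <- round(rlnorm(1000, log(40), 0.6))
    est <- summarize_waits(w, quantile_levels = 0.5, B = 300, seed = i)
    est$lower["p50"] <= 40 && 40 <= est$upper["p50"]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("period comparison applies the closed-interval rule", {
  est <- summarize_waits(round(rlnorm(200, log(40), 0.3)), B = 200,
                         seed = 9L)
  below <- est$lower["p50"] - 5
  expect_equal(compare_periods(est, below), "substantial increase")
  above <- est$upper["p50"] + 5
  expect_equal(compare_periods(est, above), "substantial decrease")
  inside <- unname(est$point["p50"])
  expect_equal(compare_periods(est, inside), "non-substantial change")
  # exactly on a bound counts as inside
  expect_equal(compare_periods(est, unname(est$lower["p50"])),
               "non-substantial change")
})
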