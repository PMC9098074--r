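---
title: "Methods: weakly-supervised specialty labelling and wait-time estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly-supervised specialty labelling and wait-time estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

The quantity of interest is the distribution of waits, in calendar days,
between a family physician's referral and the patient's first consultation
with the targeted specialist. Consult visits are reliably recorded in
administrative claims, with a specialty code and a date; referral notes are
free text in the EMR with no trustworthy specialty label. The pipeline
therefore has two coupled parts: (i) learn to label the target specialty of
a referral note, using labels inferred from claims co-occurrence rather
than manual abstraction, and (ii) use the gated classifiers to link
referrals to consults and estimate per-specialty wait percentiles.

## Weak labels from claims co-occurrence

A patient with exactly one referral note and exactly one specialist claim
inside the study year yields an unambiguous pairing: the claim's specialty
labels the note (`derive_gold_pairs()`). Patients with several notes or
claims are excluded entirely — with *k* notes and *k* claims there are up
to *k*! pairings and no basis to choose among them. Two refinements:

* **Short-note filter.** Notes with fewer than 6 tokens (counted after the
  same lowercase/strip-punctuation-and-digits normalization the classifier
  uses, without stemming) are removed *before* the one-note count, so an
  uninformative stub — a name and a date — neither trains the model nor
  disqualifies its patient. Six tokens is the shortest note that can carry
  an actionable request ("please see X for chest pain").
* **Specialty exclusions.** The default exclusion list is `internal`:
  general internal-medicine consults overlap the organ-specific
  specialties, so its claims would mislabel notes that are really
  cardiology, gastroenterology, etc. The list is configurable.

The assumption being bought is that for single-pair patients the note and
the claim refer to the same clinical episode. That fails when the claim
falls in the following year (the pair is then not observed in-year and the
patient is simply not used), or when an unrelated self-referral happens to
be the year's only claim — a rare mislabelling the classifier's
regularization has to absorb. Labelled counts are reported through
`specialty_counts()`, which renders counts below 5 as `"<5"` — the
small-cell suppression convention of health-data custodians — and omits
zero rows.

## Features and classifiers

Text is normalized by lowercasing, replacing every punctuation character
and digit with a space, and splitting on whitespace; an optional Snowball
(English) stemming pass is one axis of the model grid. The stemmer is
implemented in the package (`snowball_stem()`) directly from the published
algorithm — regions R1/R2, consonant-`y` marking, steps 0–5 and the
exception lists — and validated against hand-traced cases.

Documents become unigram vectors over a vocabulary of tokens occurring at
least 5 times in the corpus they are built on (rarer types are mostly
misspellings). Two weightings are available: raw counts, and tf-idf with
the smoothed convention `idf(t) = ln((1+N)/(1+df(t))) + 1` followed by
Euclidean normalization of each document. The smoothing keeps idf strictly
positive and defined for unseen terms; count vectors are deliberately not
length-normalized, since occurrence counts are themselves informative.
Vocabulary and idf statistics are always computed on the training fold
only, never on held-out notes — building them globally would leak
document-frequency information across the cross-validation boundary.

Each specialty gets an independent binary (one-vs-rest) logistic
regression. The grid (`grid_spec()`) crosses stemming, vectorization,
penalty type (lasso/ridge), regularization and class weighting into 80
configurations. The regularization axis is interpreted as *inverse*
strength `C` (larger = weaker penalty), the convention of the toolkit
family these values are typically quoted from; the solver is `glmnet`, so
`C` maps to `lambda = 1/(C * n)`. Balanced class weights are
`w_c = n_total / (2 n_c)`. Numerical settings: convergence threshold 1e-8,
iteration cap 1e5, no predictor standardization (the features are already
homogeneous token weights).

Performance is measured by stratified 5-fold cross-validation — plain
k-folds would leave rare specialties with empty positive folds; specialties
with fewer positives than folds are skipped outright. The in-CV decision
threshold is fixed at 0.5; threshold effects are a separate diagnostic, not
a tuning axis. Metrics with zero denominators (e.g. precision with no
predicted positives) are reported as 0 with an explicit `undefined` flag
rather than NA, so aggregation stays total while the information is
preserved.

## Model selection and the deployment gate

Three selection schemes are reported per specialty: highest precision
subject to recall ≥ 0.3, highest recall subject to precision ≥ 0.3, and
highest F1. The floors exist because some grid corners buy a near-perfect
value of one metric at a useless value of the other. When a floor is
unsatisfiable the unconstrained optimum is returned with a `fallback` flag.
Ties break toward higher precision, then lower enumeration index — an
arbitrary but fixed rule, so reruns are bit-identical.

For wait-time estimation precision matters more than recall: a false
positive contaminates the wait distribution with a wrong-specialty episode,
while a false negative merely shrinks the sample. The deployed model is
therefore the *precision-floor* selection, and a specialty is eligible only
if that selection reaches precision ≥ 0.70 and recall ≥ 0.30 (inclusive)
without fallback — fallback selections have sub-floor recall by
construction and are never deployed regardless of their printed precision.

## Linkage and bootstrap estimation

Eligible classifiers score every (short-note-filtered) note independently;
a note may be positive for several specialties or none. Per patient and
specialty, the earliest positively-predicted note of the study year is the
first referral (date ties break by note id); it links to the earliest
same-specialty claim dated on or after it and no later than December 31 of
the following year. The one-year spill window keeps late-year referrals
from being censored out entirely; consults must follow referrals because a
negative wait is meaningless. All date arithmetic is calendar-exact
(leap-year aware), never 30-day months.

`summarize_waits()` reports empirical quantiles (default median, 75th and
90th percentiles) with percentile-bootstrap confidence intervals: `B = 1000`
resamples of the observations with replacement, interval = 2.5th/97.5th
percentile of each quantile's bootstrap distribution. The interval is
clamped to contain the point estimate, which can otherwise escape it at
very small *n*. Following the comparison rule used for period-over-period
reporting, a prior value is a *substantial* change only when it falls
strictly outside the (closed) interval; `compare_periods()` takes direction
from the sign of (current point − prior value).

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the analysis relies on:

* disjoint per-specialty keyword vocabularies embedded in a shared filler
  vocabulary, with each token drawn from the note's specialty vocabulary
  with probability `keyword_rate` (default 0.6 — enough signal that a
  6-token note is usually classifiable, far from the degenerate all-keyword
  case);
* note lengths from a discrete distribution whose default puts 5% of mass
  on 2–5 tokens (exercising the short-note filter) and the rest on a
  log-normal-shaped range over 6–150 tokens peaked near 45;
* referral dates uniform over the study year; each single-event patient's
  consult at `referral + wait`, with waits log-normal (scale = ln median,
  default medians 30/60/90 days across three specialties, sigma 0.6) —
  strictly positive and right-skewed, matching the large gaps between
  observed medians and 90th percentiles; consults may spill into the next
  calendar year;
* a `multi_event_rate` fraction of patients (default 0.2) carrying
  confounder events — an extra note, claim, or both, with uniformly drawn
  specialty and date — which removes them from the gold set and stresses
  the linkage stage.

Identical seeds give byte-identical cohorts, and generated tables
round-trip through the JSON-lines and TSV writers.

What the generator does *not* emulate: real clinical language (synthetic
tokens are arbitrary letter strings, so stemming is exercised mechanically
rather than linguistically), tick-box/custom-form referrals, EMR-vendor
heterogeneity, correlated referral and consult seasonality, or
specialty-dependent note style. Passing tests therefore demonstrate that
the pipeline's logic is correct and self-consistent under known ground
truth — not that any particular performance level transfers to real
referral notes, where class overlap is far heavier.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: pairing
and linkage against brute-force per-patient scans, selection against an
exhaustive scan with the same tie-breaks, metrics against hand-evaluated
confusion tables, the stemmer against hand-traced derivations, and calendar
arithmetic against day-by-day enumeration. Integration checks run the
reference conditions — three specialties × 500 notes, keyword rate 0.6,
wait medians 30/60/90 days — through the full 80-configuration grid,
requiring best-F1 ≥ 0.90 per specialty, deployed wait medians within 15% of
their configured values, and ≥ 80% bootstrap-CI coverage of the true median
across 20 regenerated replicates (each replicate re-trains the selected
configuration on its own cohort; repeating the full grid search per
replicate would only re-test selection, which has its own oracle). These
sizes give stable estimates (gold sets near 1,000 notes, several hundred
wait observations per specialty) while keeping the whole suite fast enough
to run routinely.

## Known limitations

* Recall at the deployed operating point is typically 0.3–0.5, so real-data
  estimates describe the *captured* subpopulation; non-random misses could
  skew them, and nothing in the pipeline corrects for that.
* Referrals never followed by a consult are not modelled (no censoring
  adjustment); the wait distribution is conditional on a consult occurring
  within the spill window.
* The single-pair rule trades sample size for label purity; specialties
  whose referrals arrive on custom forms may be under-represented in the
  gold set for reasons unrelated to their true volume.
* Probabilities are used as-is (logistic regression is reasonably
  calibrated); no recalibration step is included.
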