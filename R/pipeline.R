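## End-to-end driver: simulate (or read) -> label -> train -> select ->
## waits -> sweep, with every intermediate table written as a plain-text
## file whose header records the seeds in force.

#' Assemble a validated run configuration
#'
#' @param study_year referral calendar year.
#' @param synthetic a [synthetic_config()] to simulate inputs, or `NULL` to
#'   read `notes_path` / `claims_path`.
#' @param notes_path,claims_path input files (ignored when `synthetic` is
#'   given).
#' @param out_dir directory for intermediate and final tables; created if
#'   missing. `NULL` disables writing.
#' @param min_tokens short-note filter threshold.
#' @param excluded_specialties dropped from gold pairing.
#' @param grid a [grid_spec()].
#' @param k cross-validation folds.
#' @param min_precision,min_recall deployment gate floors in \[0,1\].
#' @param threshold deployment decision threshold.
#' @param bootstrap_B bootstrap replicates for wait-time CIs.
#' @param seed_cv,seed_bootstrap fold / bootstrap seeds (the synthetic seed
#'   lives inside `synthetic`).
#' @param sweep_thresholds thresholds for the diagnostic sweep.
#' @return list of class `run_config`.
#' @export
run_config <- function(study_year = 2015,
                       synthetic = synthetic_config(study_year = study_year),
                       notes_path = NULL, claims_path = NULL,
                       out_dir = NULL,
                       min_tokens = 6,
                       excluded_specialties = "internal",
                       grid = grid_spec(),
                       k = 5,
                       min_precision = 0.70, min_recall = 0.30,
                       threshold = 0.5,
                       bootstrap_B = 1000,
                       seed_cv = 1L, seed_bootstrap = 1L,
                       sweep_thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (min_precision < 0 || min_precision > 1 ||
      min_recall < 0 || min_recall > 1) {
    stop("configuration error: gate floors must lie in [0,1]", call. = FALSE)
  }
  if (is.null(synthetic) && (is.null(notes_path) || is.null(claims_path))) {
    stop("configuration error: need either a synthetic config or both ",
         "notes_path and claims_path", call. = FALSE)
  }
  structure(
    list(study_year = as.integer(study_year), synthetic = synthetic,
         notes_path = notes_path, claims_path = claims_path,
         out_dir = out_dir, min_tokens = min_tokens,
         excluded_specialties = excluded_specialties, grid = grid, k = k,
         min_precision = min_precision, min_recall = min_recall,
         threshold = threshold, bootstrap_B = as.integer(bootstrap_B),
         seed_cv = as.integer(seed_cv),
         seed_bootstrap = as.integer(seed_bootstrap),
         sweep_thresholds = sweep_thresholds),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Recognized top-level keys mirror the [run_config()] arguments; a
#' `synthetic:` mapping is passed to [synthetic_config()] and a `grid:`
#' mapping to [grid_spec()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  if (!is.null(raw$grid)) raw$grid <- do.call(grid_spec, raw$grid)
  do.call(run_config, raw)
}

.seed_header <- function(config) {
  sprintf("study_year=%d seed_synthetic=%s seed_cv=%d seed_bootstrap=%d",
          config$study_year,
          if (is.null(config$synthetic)) "NA" else config$synthetic$seed,
          config$seed_cv, config$seed_bootstrap)
}

.write_stage <- function(df, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  path <- file.path(config$out_dir, paste0(name, ".tsv"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .seed_header(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes every stage in order and, when `out_dir` is set, writes each
#' intermediate table (notes, claims, labelled notes, suppressed counts, CV
#' grid, selections, wait estimates, threshold sweep) with the seeds
#' recorded in a header line. Identical configuration and seeds give
#' identical outputs. With gate floors no specialty can meet, the wait-time
#' and sweep stages are skipped gracefully.
#'
#' @param config a [run_config()].
#' @return object of class `wait_pipeline_run`: per-stage row counts,
#'   selection tables, eligible specialties, per-specialty
#'   [summarize_waits()] estimates, and the sweep table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  stage <- function(fmt, ...) {
    sw_log("%s [%.1fs]", sprintf(fmt, ...),
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  # -- simulate / ingest ------------------------------------------------
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    notes <- cohort$notes
    claims <- cohort$claims
    .write_stage(cohort$truth, config, "truth")
  } else {
    notes <- read_notes(config$notes_path)
    claims <- read_claims(config$claims_path)
  }
  stage("ingest: %d notes, %d claims", nrow(notes), nrow(claims))
  .write_stage(transform(notes, date = format(date)), config, "notes")
  .write_stage(transform(claims, date = format(date)), config, "claims")

  # -- label ------------------------------------------------------------
  n_in <- nrow(notes)
  notes <- filter_short_notes(notes, config$min_tokens)
  stage("short-note filter: %d in = %d retained + %d removed",
        n_in, nrow(notes), n_in - nrow(notes))
  labeled <- derive_gold_pairs(notes, claims, config$study_year,
                               config$excluded_specialties)
  counts <- specialty_counts(labeled)
  stage("gold pairs: %d labelled notes across %d specialties",
        nrow(labeled), nrow(counts))
  .write_stage(transform(labeled, date = format(date)), config, "labeled")
  .write_stage(counts, config, "specialty_counts")

  # -- train ------------------------------------------------------------
  cv <- grid_search(labeled, config$grid, k = config$k,
                    threshold = config$threshold, seed = config$seed_cv)
  stage("grid search: %d specialty x config cells", nrow(cv))
  .write_stage(cv, config, "cv_metrics")

  # -- select + gate ----------------------------------------------------
  selections <- select_models(cv)
  pf <- selections[selections$scheme == "precision_floor", , drop = FALSE]
  eligible <- gate_specialties(pf, config$min_precision, config$min_recall)
  stage("selection: %d specialties, %d eligible for deployment",
        length(unique(selections$specialty)), length(eligible))
  .write_stage(selections, config, "selections")

  # -- waits ------------------------------------------------------------
  estimates <- list()
  wait_table <- NULL
  sweep <- NULL
  if (length(eligible)) {
    classifiers <- lapply(eligible, function(sp) {
      cfg <- pf[pf$specialty == sp, , drop = FALSE]
      fit_specialty_classifier(labeled, sp, cfg)
    })
    names(classifiers) <- eligible
    positives <- deploy_classifiers(classifiers, notes, config$threshold)
    waits <- link_wait_times(positives, claims, config$study_year)
    estimates <- lapply(eligible, function(sp) {
      w <- waits[waits$specialty == sp, , drop = FALSE]
      if (nrow(w) == 0L) return(NULL)
      summarize_waits(w, B = config$bootstrap_B,
                      seed = config$seed_bootstrap, specialty = sp)
    })
    names(estimates) <- eligible
    estimates <- Filter(Negate(is.null), estimates)
    wait_table <- do.call(rbind, lapply(estimates, function(e) {
      data.frame(specialty = e$specialty, n = e$n,
                 median = unname(e$point["p50"]), p75 = unname(e$point["p75"]),
                 p90 = unname(e$point["p90"]),
                 median_lo = unname(e$lower["p50"]),
                 median_hi = unname(e$upper["p50"]),
                 p75_lo = unname(e$lower["p75"]),
                 p75_hi = unname(e$upper["p75"]),
                 p90_lo = unname(e$lower["p90"]),
                 p90_hi = unname(e$upper["p90"]),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    stage("wait times: %d observations, %d specialties estimated",
          nrow(waits), length(estimates))
    .write_stage(wait_table, config, "wait_times")

    # -- sweep ----------------------------------------------------------
    sweep <- threshold_sweep(classifiers, labeled, notes, claims,
                             config$sweep_thresholds, config$study_year)
    stage("threshold sweep: %d thresholds", nrow(sweep))
    .write_stage(sweep, config, "threshold_sweep")
  } else {
    stage("no eligible specialty; wait-time and sweep stages skipped")
  }

  structure(
    list(config = config,
         counts = list(notes_in = n_in, notes_retained = nrow(notes),
                       notes_removed = n_in - nrow(notes),
                       labeled = nrow(labeled), claims = nrow(claims)),
         specialty_counts = counts,
         cv = cv,
         selections = selections,
         eligible = eligible,
         estimates = estimates,
         wait_table = wait_table,
         sweep = sweep),
    class = "wait_pipeline_run"
  )
}

#' @method print wait_pipeline_run
#' @export
print.wait_pipeline_run <- function(x, ...) {
  cat("<wait_pipeline_run> study year", x$config$study_year, "\n")
  cat(sprintf("  notes: %d in = %d retained + %d short-note filtered\n",
              x$counts$notes_in, x$counts$notes_retained,
              x$counts$notes_removed))
  cat(sprintf("  gold-labelled notes: %d across %d specialties\n",
              x$counts$labeled, nrow(x$specialty_counts)))
  cat("  eligible for deployment:",
      if (length(x$eligible)) paste(x$eligible, collapse = ", ") else "none",
      "\n")
  if (!is.null(x$wait_table)) {
    cat("  wait-time estimates (days):\n")
    print(x$wait_table, row.names = FALSE)
  }
  invisible(x)
}
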