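## Constrained model selection: per specialty, pick one configuration under
## each of three optimization schemes, then gate specialties for wait-time
## estimation on the precision-floor selection.

.sw_schemes <- c("precision_floor", "recall_floor", "best_f1")

# argmax over `primary` with ties broken by higher precision, then lower
# enumeration index
.pick <- function(df, primary) {
  df[order(-df[[primary]], -df$mean_precision, df$config_id), ][1L, ]
}

#' Select a configuration for one specialty under one scheme
#'
#' `precision_floor`: highest mean precision among configurations with mean
#' recall >= `floor`; if none qualifies, the globally most precise
#' configuration is returned with `fallback = TRUE`. `recall_floor` is the
#' mirror image (highest recall subject to precision >= `floor`). `best_f1`:
#' highest mean F1. The floors exist because some hyperparameters buy a
#' near-perfect value of one metric at the extreme cost of the other, which
#' is clinically useless. Ties break toward higher precision, then lower
#' `config_id`.
#'
#' @param cv_results rows of [grid_search()] for a single specialty.
#' @param scheme one of `"precision_floor"`, `"recall_floor"`, `"best_f1"`.
#' @param floor the constraint level for the floored schemes.
#' @return one-row data frame: specialty, scheme, the chosen `config_id` and
#'   configuration fields, its mean precision/recall/F1, and a `fallback`
#'   flag.
#' @export
select_model <- function(cv_results, scheme = .sw_schemes, floor = 0.3) {
  scheme <- match.arg(scheme)
  if (length(unique(cv_results$specialty)) > 1L) {
    stop("select_model expects cv results for a single specialty",
         call. = FALSE)
  }
  avail <- cv_results[!cv_results$skipped, , drop = FALSE]
  if (nrow(avail) == 0L) {
    stop("all configurations were skipped for specialty '",
         cv_results$specialty[1L], "'", call. = FALSE)
  }
  fallback <- FALSE
  chosen <- switch(
    scheme,
    precision_floor = {
      ok <- avail[avail$mean_recall >= floor, , drop = FALSE]
      if (nrow(ok) == 0L) { fallback <- TRUE; ok <- avail }
      .pick(ok, "mean_precision")
    },
    recall_floor = {
      ok <- avail[avail$mean_precision >= floor, , drop = FALSE]
      if (nrow(ok) == 0L) { fallback <- TRUE; ok <- avail }
      .pick(ok, "mean_recall")
    },
    best_f1 = .pick(avail, "mean_f1")
  )
  data.frame(
    specialty = chosen$specialty, scheme = scheme,
    config_id = chosen$config_id, stem = chosen$stem,
    vectorizer = chosen$vectorizer, penalty = chosen$penalty, C = chosen$C,
    class_weight = chosen$class_weight,
    precision = chosen$mean_precision, recall = chosen$mean_recall,
    f1 = chosen$mean_f1, fallback = fallback,
    stringsAsFactors = FALSE
  )
}

#' Select configurations for every specialty under one or all schemes
#'
#' @param cv_results full [grid_search()] output.
#' @param scheme scheme(s) to apply (default: all three).
#' @param floor constraint level for the floored schemes.
#' @return data frame with one row per specialty x scheme; specialties whose
#'   configurations were all skipped are omitted.
#' @export
select_models <- function(cv_results, scheme = .sw_schemes, floor = 0.3) {
  scheme <- match.arg(scheme, several.ok = TRUE)
  specialties <- unique(cv_results$specialty)
  rows <- list()
  for (sp in specialties) {
    sub <- cv_results[cv_results$specialty == sp, , drop = FALSE]
    if (all(sub$skipped)) next
    for (sch in scheme) rows[[length(rows) + 1L]] <- select_model(sub, sch, floor)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gate specialties for wait-time estimation
#'
#' A specialty is eligible for deployment when its precision-floor selection
#' reaches mean precision >= `min_precision` and mean recall >= `min_recall`
#' (both inclusive) without having fallen back: fallback selections have
#' recall below the floor by construction and are never deployed, whatever
#' their printed precision.
#'
#' @param selections precision-floor rows of [select_models()].
#' @param min_precision,min_recall the gate floors.
#' @return character vector of eligible specialties.
#' @export
gate_specialties <- function(selections, min_precision = 0.70,
                             min_recall = 0.30) {
  stopifnot(all(selections$scheme == "precision_floor"))
  ok <- selections$precision >= min_precision &
    selections$recall >= min_recall &
    !selections$fallback
  selections$specialty[ok]
}
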