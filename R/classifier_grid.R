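## One-vs-rest regularized logistic regression over the hyperparameter grid,
## scored by stratified 5-fold cross-validation. glmnet is the solver; the
## grid's "regularization" axis is inverse strength C (larger = weaker
## penalty), mapped to the glmnet scale as lambda = 1/(C * n).

#' The hyperparameter grid
#'
#' Five axes: preprocessing (stemming on/off), vectorization (count /
#' tf-idf), penalty (ridge / lasso), inverse regularization strength C, and
#' class weighting (none / balanced). The default grid enumerates to
#' 2 x 2 x 2 x 5 x 2 = 80 pipeline configurations per specialty.
#'
#' @param stem logical options for Snowball stemming.
#' @param vectorizer subset of `c("count", "tfidf")`.
#' @param penalty subset of `c("l2", "l1")` (ridge / lasso).
#' @param C positive inverse regularization strengths.
#' @param class_weight subset of `c("none", "balanced")`.
#' @return list of class `sw_grid`.
#' @export
grid_spec <- function(stem = c(FALSE, TRUE),
                      vectorizer = c("count", "tfidf"),
                      penalty = c("l2", "l1"),
                      C = c(0.001, 0.01, 0.1, 1, 10),
                      class_weight = c("none", "balanced")) {
  axes <- list(stem = stem, vectorizer = vectorizer, penalty = penalty,
               C = C, class_weight = class_weight)
  if (any(lengths(axes) == 0L)) {
    stop("configuration error: every grid axis needs at least one option",
         call. = FALSE)
  }
  structure(axes, class = "sw_grid")
}

#' Enumerate all pipeline configurations of a grid
#'
#' Cartesian product of the grid axes in a fixed order; `config_id` is the
#' enumeration index used for deterministic tie-breaking everywhere
#' downstream.
#'
#' @param grid an [grid_spec()] object.
#' @return data frame with one row per configuration.
#' @export
enumerate_configs <- function(grid = grid_spec()) {
  stopifnot(inherits(grid, "sw_grid"))
  cfg <- expand.grid(stem = grid$stem, vectorizer = grid$vectorizer,
                     penalty = grid$penalty, C = grid$C,
                     class_weight = grid$class_weight,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cfg$config_id <- seq_len(nrow(cfg))
  cfg[, c("config_id", "stem", "vectorizer", "penalty", "C", "class_weight")]
}

.metric_names <- c("precision", "recall", "f1", "specificity", "npv", "brier")

#' Confusion-matrix metrics at a decision threshold
#'
#' Predicts positive wherever `probabilities >= threshold` and reports
#' precision (PPV), recall (sensitivity), F1, specificity, NPV and the Brier
#' score (mean squared difference between probability and outcome). Any
#' metric with a zero denominator is reported as 0 with its flag set in
#' `undefined`.
#'
#' @param labels logical (or 0/1) true class per observation.
#' @param probabilities predicted probabilities in \[0,1\].
#' @param threshold decision threshold.
#' @return list with the six metrics, the confusion counts, and an
#'   `undefined` logical vector.
#' @export
confusion_metrics <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities must have equal length", call. = FALSE)
  }
  y <- as.logical(labels)
  pred <- probabilities >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  undefined <- c(precision = FALSE, recall = FALSE, f1 = FALSE,
                 specificity = FALSE, npv = FALSE, brier = FALSE)
  div <- function(num, den, metric) {
    if (den == 0) {
      undefined[metric] <<- TRUE
      0
    } else {
      num / den
    }
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  specificity <- div(tn, tn + fp, "specificity")
  npv <- div(tn, tn + fn, "npv")
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    undefined["f1"] <- TRUE
    0
  }
  brier <- if (length(y)) mean((probabilities - as.numeric(y))^2) else {
    undefined["brier"] <- TRUE
    0
  }
  list(precision = precision, recall = recall, f1 = f1,
       specificity = specificity, npv = npv, brier = brier,
       tp = tp, fp = fp, fn = fn, tn = tn, undefined = undefined)
}

# stratified fold assignment: positives and negatives are shuffled and dealt
# round-robin so each fold keeps the corpus positive rate
make_stratified_folds <- function(y, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

.balanced_weights <- function(y) {
  n <- length(y)
  w <- numeric(n)
  w[y] <- n / (2 * sum(y))
  w[!y] <- n / (2 * sum(!y))
  w
}

# glmnet fit for one configuration; returns intercept + dense coefficients
.fit_logistic <- function(x, y, config) {
  n <- nrow(x)
  p0 <- ncol(x)
  pad <- p0 < 2L
  if (pad) x <- cbind(x, Matrix::Matrix(0, n, 2L - p0, sparse = TRUE))
  w <- if (config$class_weight == "balanced") .balanced_weights(y) else NULL
  fit <- glmnet::glmnet(
    x, factor(y, levels = c(FALSE, TRUE)),
    family = "binomial",
    alpha = if (config$penalty == "l1") 1 else 0,
    lambda = 1 / (config$C * n),
    weights = w,
    standardize = FALSE,
    thresh = 1e-8,
    maxit = 100000
  )
  beta <- as.numeric(fit$beta[, 1L])
  if (pad) beta <- beta[seq_len(p0)]  # drop padding columns
  list(intercept = as.numeric(fit$a0[1L]), beta = beta)
}

.linear_probs <- function(x, model) {
  eta <- as.numeric(x %*% model$beta) + model$intercept
  stats::plogis(eta)
}

#' Cross-validate one pipeline configuration for one specialty
#'
#' Stratified k-fold split seeded by `seed`. Within each fold the vocabulary
#' is built on the training fold only (no information leaks from held-out
#' notes), the one-vs-rest classifier is fitted (positive = gold label equals
#' `specialty`), and held-out notes are scored with [confusion_metrics()].
#' Specialties with fewer positive examples than folds are skipped rather
#' than scored.
#'
#' @param labeled labelled notes from [derive_gold_pairs()].
#' @param specialty the positive class.
#' @param config one row of [enumerate_configs()] (or a list with the same
#'   fields).
#' @param k number of folds.
#' @param threshold decision threshold inside CV (fixed at 0.5; threshold
#'   sweeps are a separate diagnostic).
#' @param seed integer fold-assignment seed.
#' @param min_count vocabulary frequency threshold.
#' @param tokens optional pre-normalized token lists matching `config$stem`,
#'   to avoid re-normalizing across grid cells.
#' @param folds optional precomputed fold assignment.
#' @return list of class `sw_cv`: per-fold metric rows, their means and
#'   standard deviations, and a `skipped` flag.
#' @export
cross_validate <- function(labeled, specialty, config, k = 5, threshold = 0.5,
                           seed = 1L, min_count = 5, tokens = NULL,
                           folds = NULL) {
  if (nrow(labeled) == 0L) stop("empty labelled corpus", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  y <- labeled$gold_specialty == canon_specialty(specialty)
  if (sum(y) < k) {
    return(structure(list(specialty = specialty, config = config,
                          skipped = TRUE, folds = NULL,
                          mean = NULL, sd = NULL),
                     class = "sw_cv"))
  }
  if (is.null(tokens)) tokens <- normalize_text(labeled$text, stem = config$stem)
  if (is.null(folds)) folds <- make_stratified_folds(y, k, seed)

  fold_rows <- vector("list", k)
  flags <- matrix(FALSE, k, length(.metric_names),
                  dimnames = list(NULL, .metric_names))
  for (f in seq_len(k)) {
    tr <- folds != f
    vocab <- build_vocabulary(tokens[tr], min_count = min_count)
    xtr <- vectorize_corpus(tokens[tr], vocab, config$vectorizer)
    xte <- vectorize_corpus(tokens[!tr], vocab, config$vectorizer)
    model <- .fit_logistic(xtr, y[tr], config)
    m <- confusion_metrics(y[!tr], .linear_probs(xte, model), threshold)
    fold_rows[[f]] <- unlist(m[.metric_names])
    flags[f, ] <- m$undefined
  }
  per_fold <- do.call(rbind, fold_rows)
  structure(
    list(specialty = specialty, config = config, skipped = FALSE,
         folds = as.data.frame(per_fold),
         undefined = flags,
         mean = colMeans(per_fold),
         sd = apply(per_fold, 2L, stats::sd)),
    class = "sw_cv"
  )
}

#' @method print sw_cv
#' @export
print.sw_cv <- function(x, ...) {
  if (x$skipped) {
    cat("<sw_cv>", x$specialty, "- skipped (fewer positives than folds)\n")
  } else {
    cat("<sw_cv>", x$specialty, sprintf(
      "- P %.3f (%.3f), R %.3f (%.3f), F1 %.3f (%.3f)\n",
      x$mean["precision"], x$sd["precision"], x$mean["recall"],
      x$sd["recall"], x$mean["f1"], x$sd["f1"]))
  }
  invisible(x)
}

#' Cross-validate the full grid for several specialties
#'
#' Runs [cross_validate()] for every configuration of the grid and every
#' specialty, sharing tokenizations, fold assignments, per-fold vocabularies
#' and document matrices across the grid cells they are common to. Fold
#' assignment is stratified per specialty and seeded by `seed`.
#'
#' @param labeled labelled notes from [derive_gold_pairs()].
#' @param grid an [grid_spec()].
#' @param specialties specialties to score (default: all gold labels
#'   present).
#' @param k folds.
#' @param threshold in-CV decision threshold.
#' @param seed fold seed.
#' @param min_count vocabulary frequency threshold.
#' @return long data frame: one row per specialty x configuration with the
#'   configuration fields, a `skipped` flag, and `mean_*` / `sd_*` columns
#'   for the six metrics.
#' @export
grid_search <- function(labeled, grid = grid_spec(), specialties = NULL,
                        k = 5, threshold = 0.5, seed = 1L, min_count = 5) {
  configs <- enumerate_configs(grid)
  if (is.null(specialties)) specialties <- sort(unique(labeled$gold_specialty))
  toks <- list(
    `FALSE` = normalize_text(labeled$text, stem = FALSE),
    `TRUE` = normalize_text(labeled$text, stem = TRUE)
  )
  out <- vector("list", length(specialties) * nrow(configs))
  pos <- 0L
  for (sp in specialties) {
    y <- labeled$gold_specialty == canon_specialty(sp)
    folds <- if (sum(y) >= k) make_stratified_folds(y, k, seed) else NULL

    # fold-level feature matrices shared by all configs with the same
    # stem x vectorizer choice
    cache <- new.env(parent = emptyenv())
    fold_xs <- function(stem, vectorizer, f) {
      key <- paste(stem, vectorizer, f, sep = "|")
      if (!exists(key, cache)) {
        tk <- toks[[as.character(stem)]]
        tr <- folds != f
        vocab <- build_vocabulary(tk[tr], min_count = min_count)
        assign(key, list(
          xtr = vectorize_corpus(tk[tr], vocab, vectorizer),
          xte = vectorize_corpus(tk[!tr], vocab, vectorizer)
        ), cache)
      }
      get(key, cache)
    }

    for (ci in seq_len(nrow(configs))) {
      config <- configs[ci, ]
      pos <- pos + 1L
      if (is.null(folds)) {
        out[[pos]] <- data.frame(specialty = sp, config, skipped = TRUE,
                                 stringsAsFactors = FALSE)
        next
      }
      rows <- matrix(NA_real_, k, length(.metric_names),
                     dimnames = list(NULL, .metric_names))
      for (f in seq_len(k)) {
        xs <- fold_xs(config$stem, config$vectorizer, f)
        model <- .fit_logistic(xs$xtr, y[folds != f], config)
        m <- confusion_metrics(y[folds == f], .linear_probs(xs$xte, model),
                               threshold)
        rows[f, ] <- unlist(m[.metric_names])
      }
      stats_row <- c(
        stats::setNames(colMeans(rows), paste0("mean_", .metric_names)),
        stats::setNames(apply(rows, 2L, stats::sd), paste0("sd_", .metric_names))
      )
      out[[pos]] <- data.frame(specialty = sp, config, skipped = FALSE,
                               as.list(stats_row), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the final one-vs-rest classifier for one specialty
#'
#' Fits on the full gold corpus with the configuration's preprocessing,
#' vectorization, penalty, inverse regularization strength and class
#' weighting (balanced weights are `w_c = n_total / (2 n_c)`). The returned
#' object carries its own vocabulary and weights, so prediction needs only
#' raw note text.
#'
#' @inheritParams cross_validate
#' @return object of class `specialty_classifier`.
#' @export
fit_specialty_classifier <- function(labeled, specialty, config,
                                     min_count = 5) {
  y <- labeled$gold_specialty == canon_specialty(specialty)
  if (sum(y) == 0L || sum(!y) == 0L) {
    stop("cannot fit a one-vs-rest classifier on a single-class corpus",
         call. = FALSE)
  }
  tokens <- normalize_text(labeled$text, stem = config$stem)
  vocab <- build_vocabulary(tokens, min_count = min_count)
  x <- vectorize_corpus(tokens, vocab, config$vectorizer)
  model <- .fit_logistic(x, y, config)
  structure(
    list(specialty = canon_specialty(specialty),
         config = config,
         vocab = vocab,
         weights = stats::setNames(model$beta, vocab$tokens),
         intercept = model$intercept,
         n_train = length(y), n_positive = sum(y)),
    class = "specialty_classifier"
  )
}

#' Predicted probability that notes target the classifier's specialty
#'
#' Normalizes and vectorizes `text` with the classifier's stored stemming
#' flag, vocabulary and vectorization mode, then applies the logistic link.
#'
#' @param object a `specialty_classifier`.
#' @param text character vector of raw note texts.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1); notes with no
#'   in-vocabulary token score `plogis(intercept)`.
#' @export
predict.specialty_classifier <- function(object, text, ...) {
  tokens <- normalize_text(text, stem = object$config$stem)
  x <- vectorize_corpus(tokens, object$vocab, object$config$vectorizer)
  .linear_probs(x, list(beta = unname(object$weights),
                        intercept = object$intercept))
}

#' @rdname predict.specialty_classifier
#' @param classifier a `specialty_classifier`.
#' @export
predict_proba <- function(classifier, text) {
  predict(classifier, text)
}

#' @export
coef.specialty_classifier <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @method print specialty_classifier
#' @export
print.specialty_classifier <- function(x, ...) {
  cat("<specialty_classifier>", x$specialty, "\n")
  cat(sprintf(
    "  config: stem=%s, %s vectors, %s penalty, C=%g, class_weight=%s\n",
    x$config$stem, x$config$vectorizer, x$config$penalty, x$config$C,
    x$config$class_weight))
  cat(sprintf("  trained on %d notes (%d positive), %d features, %d nonzero\n",
              x$n_train, x$n_positive, length(x$weights),
              sum(x$weights != 0)))
  invisible(x)
}
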