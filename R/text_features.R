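## Text normalization, vocabulary construction, and count / tf-idf document
## vectors. Vectors are rows of a sparse Matrix::dgCMatrix so the downstream
## glmnet fits stay sparse.

#' Normalize clinical note text into tokens
#'
#' Lowercases the text, replaces every punctuation character and digit with a
#' space, splits on whitespace, and optionally stems each token with the
#' English Snowball stemmer. This is the single normalization used everywhere
#' in the pipeline (token counting, vocabulary building, vectorization).
#'
#' @param text character vector of raw note texts.
#' @param stem logical; stem tokens with [snowball_stem()]?
#' @return a list of character vectors, one per input text (empty vector for
#'   texts with no alphabetic content).
#' @examples
#' normalize_text("Chest pain, r/o MI 2015.")
#' @export
normalize_text <- function(text, stem = FALSE) {
  text <- tolower(as.character(text))
  text <- gsub("[^a-z]+", " ", text)
  toks <- strsplit(trimws(text), "[ \t\r\n]+")
  toks <- lapply(toks, function(x) x[nzchar(x)])
  if (stem) {
    # stem the corpus-wide unique tokens once, then map back
    all <- unlist(toks, use.names = FALSE)
    if (length(all)) {
      uniq <- unique(all)
      stemmed <- snowball_stem(uniq)
      toks <- lapply(toks, function(x) stemmed[match(x, uniq)])
    }
  }
  toks
}

#' Build a frequency-thresholded unigram vocabulary
#'
#' Collects every unigram whose total frequency across the corpus is at least
#' `min_count`, in lexicographic order. Document frequencies are stored for
#' tf-idf weighting.
#'
#' @param token_lists list of token vectors as returned by [normalize_text()].
#' @param min_count minimum total corpus frequency for a token to enter the
#'   vocabulary (default 5; rarer tokens are typically misspellings).
#' @return an object of class `sw_vocabulary`: list with `tokens` (ordered
#'   types), `df` (document frequency per token) and `n_docs`.
#' @export
build_vocabulary <- function(token_lists, min_count = 5) {
  if (length(token_lists) == 0L) {
    stop("cannot build a vocabulary from an empty corpus", call. = FALSE)
  }
  all <- unlist(token_lists, use.names = FALSE)
  tf <- table(all)
  keep <- names(tf)[as.vector(tf) >= min_count]
  keep <- sort(keep, method = "radix")
  per_doc <- lapply(token_lists, unique)
  df_tab <- table(factor(unlist(per_doc, use.names = FALSE), levels = keep))
  structure(
    list(tokens = keep,
         df = as.integer(df_tab),
         n_docs = length(token_lists),
         min_count = min_count),
    class = "sw_vocabulary"
  )
}

#' @method print sw_vocabulary
#' @export
print.sw_vocabulary <- function(x, ...) {
  cat("<sw_vocabulary>", length(x$tokens), "token types over", x$n_docs,
      "documents (min_count =", paste0(x$min_count, ")\n"))
  invisible(x)
}

# smoothed idf; df = N gives idf = 1 so ubiquitous terms keep their counts
idf_weights <- function(vocab) {
  log((1 + vocab$n_docs) / (1 + vocab$df)) + 1
}

#' Vectorize token lists over a vocabulary
#'
#' Produces one sparse row per document. In `"count"` mode entries are raw
#' occurrence counts of in-vocabulary tokens; out-of-vocabulary tokens are
#' ignored. In `"tfidf"` mode counts are multiplied by the smoothed inverse
#' document frequency `idf(t) = ln((1+N)/(1+df(t))) + 1` and each row is
#' Euclidean-normalized (all-zero rows stay zero).
#'
#' @param token_lists list of token vectors.
#' @param vocab an `sw_vocabulary`.
#' @param mode `"count"` or `"tfidf"`.
#' @return a `dgCMatrix` with one row per document and one column per
#'   vocabulary token.
#' @export
vectorize_corpus <- function(token_lists, vocab, mode = c("count", "tfidf")) {
  if (!inherits(vocab, "sw_vocabulary") || length(vocab$tokens) == 0L) {
    stop("vocab must be a non-empty sw_vocabulary", call. = FALSE)
  }
  mode <- match.arg(mode)
  n <- length(token_lists)
  lens <- lengths(token_lists)
  doc <- rep.int(seq_len(n), lens)
  idx <- match(unlist(token_lists, use.names = FALSE), vocab$tokens)
  ok <- !is.na(idx)
  x <- Matrix::sparseMatrix(
    i = doc[ok], j = idx[ok], x = 1,
    dims = c(n, length(vocab$tokens)),
    dimnames = list(NULL, vocab$tokens)
  )
  if (mode == "tfidf") {
    x <- x %*% Matrix::Diagonal(x = idf_weights(vocab))
    nrm <- sqrt(Matrix::rowSums(x^2))
    nrm[nrm == 0] <- 1
    x <- Matrix::Diagonal(x = 1 / nrm) %*% x
    colnames(x) <- vocab$tokens
  }
  methods::as(x, "CsparseMatrix")
}

#' Vectorize a single token list
#'
#' Convenience wrapper around [vectorize_corpus()] returning a named sparse
#' one-row vector for one document.
#'
#' @inheritParams vectorize_corpus
#' @param tokens a single token vector.
#' @export
vectorize <- function(tokens, vocab, mode = c("count", "tfidf")) {
  vectorize_corpus(list(tokens), vocab, mode)[1L, , drop = FALSE]
}

#' Write / read a vocabulary as a two-column delimited file
#'
#' Columns are `token` and `df` (document frequency); `n_docs` and
#' `min_count` travel in a comment header line.
#'
#' @param vocab an `sw_vocabulary`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_docs=%d min_count=%d", vocab$n_docs,
                     vocab$min_count), con)
  utils::write.table(
    data.frame(token = vocab$tokens, df = vocab$df),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- as.integer(regmatches(header, gregexpr("[0-9]+", header))[[1L]])
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(
    list(tokens = as.character(tab$token), df = as.integer(tab$df),
         n_docs = meta[1L], min_count = meta[2L]),
    class = "sw_vocabulary"
  )
}
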