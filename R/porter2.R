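## English Snowball ("Porter2") stemmer, implemented from the published
## algorithm definition: R1/R2 regions, consonant-y marking, exception lists,
## and steps 0-5. Operates on single lowercase words; normalize_text() is the
## intended caller.

.p2_vowels <- c("a", "e", "i", "o", "u", "y")
.p2_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.p2_li_valid <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.p2_exceptions <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.p2_exceptions_1a <- c(
  "inning", "outing", "canning", "herring", "earring",
  "proceed", "exceed", "succeed"
)

.sw_ends <- function(w, s) {
  n <- nchar(w); m <- nchar(s)
  n >= m && substr(w, n - m + 1L, n) == s
}

.sw_chop <- function(w, k) substr(w, 1L, nchar(w) - k)

# start of the region after the first non-vowel that follows a vowel,
# scanning from position `from`; n+1 when no such region exists
.p2_after_vnv <- function(ch, from) {
  n <- length(ch)
  i <- from
  while (i <= n && !(ch[i] %in% .p2_vowels)) i <- i + 1L
  while (i <= n && (ch[i] %in% .p2_vowels)) i <- i + 1L
  if (i >= n) n + 1L else i + 1L
}

# TRUE when the word ends in a short syllable: vowel + non-vowel (not w/x/Y)
# preceded by a non-vowel, or word-initial vowel + non-vowel
.p2_ends_short_syll <- function(ch) {
  n <- length(ch)
  if (n == 2L && (ch[1L] %in% .p2_vowels) && !(ch[2L] %in% .p2_vowels)) {
    return(TRUE)
  }
  if (n >= 3L &&
      (ch[n - 1L] %in% .p2_vowels) &&
      !(ch[n] %in% c(.p2_vowels, "w", "x", "Y")) &&
      !(ch[n - 2L] %in% .p2_vowels)) {
    return(TRUE)
  }
  FALSE
}

.p2_step2 <- list(
  c("ization", "ize"), c("ational", "ate"), c("fulness", "ful"),
  c("ousness", "ous"), c("iveness", "ive"),
  c("tional", "tion"), c("biliti", "ble"), c("lessli", "less"),
  c("entli", "ent"), c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
  c("ousli", "ous"), c("iviti", "ive"), c("fulli", "ful"),
  c("enci", "ence"), c("anci", "ance"), c("abli", "able"),
  c("izer", "ize"), c("ator", "ate"), c("alli", "al"),
  c("bli", "ble"), c("ogi", "og"), c("li", "")
)

.p2_step3 <- list(
  c("ational", "ate"), c("tional", "tion"), c("alize", "al"),
  c("icate", "ic"), c("iciti", "ic"), c("ative", ""), c("ical", "ic"),
  c("ness", ""), c("ful", "")
)

.p2_step4 <- c(
  "ement",
  "ance", "ence", "able", "ible", "ment",
  "ant", "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
  "al", "er", "ic"
)

.p2_stem_word <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # step 0: apostrophe forms (normalize_text removes them, but direct calls
  # may not)
  word <- sub("^'", "", word)
  if (.sw_ends(word, "'s'")) {
    word <- .sw_chop(word, 3L)
  } else if (.sw_ends(word, "'s")) {
    word <- .sw_chop(word, 2L)
  } else if (.sw_ends(word, "'")) {
    word <- .sw_chop(word, 1L)
  }

  exc <- .p2_exceptions[word]
  if (!is.na(exc)) return(unname(exc))
  if (nchar(word) <= 2L) return(word)

  # mark y that functions as a consonant
  ch <- strsplit(word, "", fixed = TRUE)[[1L]]
  if (ch[1L] == "y") ch[1L] <- "Y"
  if (length(ch) >= 2L) {
    for (i in 2:length(ch)) {
      if (ch[i] == "y" && (ch[i - 1L] %in% .p2_vowels)) ch[i] <- "Y"
    }
  }
  word <- paste(ch, collapse = "")

  r1 <- if (grepl("^commun", word)) {
    7L
  } else if (grepl("^(gener|arsen)", word)) {
    6L
  } else {
    .p2_after_vnv(ch, 1L)
  }
  r2 <- .p2_after_vnv(ch, r1)

  # step 1a
  if (.sw_ends(word, "sses")) {
    word <- paste0(.sw_chop(word, 4L), "ss")
  } else if (.sw_ends(word, "ied") || .sw_ends(word, "ies")) {
    word <- paste0(.sw_chop(word, 3L), if (nchar(word) > 4L) "i" else "ie")
  } else if (.sw_ends(word, "us") || .sw_ends(word, "ss")) {
    # no change
  } else if (.sw_ends(word, "s")) {
    stem <- .sw_chop(word, 1L)
    if (nchar(stem) >= 2L &&
        grepl("[aeiouy]", substr(stem, 1L, nchar(stem) - 1L))) {
      word <- stem
    }
  }

  if (word %in% .p2_exceptions_1a) return(word)

  # step 1b
  if (.sw_ends(word, "eedly")) {
    if (nchar(word) - 4L >= r1) word <- paste0(.sw_chop(word, 5L), "ee")
  } else if (.sw_ends(word, "eed")) {
    if (nchar(word) - 2L >= r1) word <- paste0(.sw_chop(word, 3L), "ee")
  } else {
    suf <- NULL
    for (s in c("ingly", "edly", "ing", "ed")) {
      if (.sw_ends(word, s)) { suf <- s; break }
    }
    if (!is.null(suf)) {
      stem <- .sw_chop(word, nchar(suf))
      if (grepl("[aeiouy]", stem)) {
        word <- stem
        n <- nchar(word)
        if (.sw_ends(word, "at") || .sw_ends(word, "bl") ||
            .sw_ends(word, "iz")) {
          word <- paste0(word, "e")
        } else if (n >= 2L && substr(word, n - 1L, n) %in% .p2_doubles) {
          word <- .sw_chop(word, 1L)
        } else if (r1 > n &&
                   .p2_ends_short_syll(strsplit(word, "", fixed = TRUE)[[1L]])) {
          word <- paste0(word, "e")
        }
      }
    }
  }

  # step 1c: final y/Y -> i after a non-vowel that is not the first letter
  n <- nchar(word)
  if (n >= 3L) {
    last <- substr(word, n, n)
    prev <- substr(word, n - 1L, n - 1L)
    if ((last == "y" || last == "Y") && !(prev %in% .p2_vowels)) {
      word <- paste0(.sw_chop(word, 1L), "i")
    }
  }

  # step 2 (longest suffix; act only when it lies in R1)
  for (pair in .p2_step2) {
    s <- pair[1L]
    if (.sw_ends(word, s)) {
      pos <- nchar(word) - nchar(s) + 1L
      if (pos >= r1) {
        before <- if (pos > 1L) substr(word, pos - 1L, pos - 1L) else ""
        if (s == "ogi") {
          if (before == "l") word <- paste0(.sw_chop(word, 3L), "og")
        } else if (s == "li") {
          if (before %in% .p2_li_valid) word <- .sw_chop(word, 2L)
        } else {
          word <- paste0(.sw_chop(word, nchar(s)), pair[2L])
        }
      }
      break
    }
  }

  # step 3
  for (pair in .p2_step3) {
    s <- pair[1L]
    if (.sw_ends(word, s)) {
      pos <- nchar(word) - nchar(s) + 1L
      if (pos >= r1) {
        if (s == "ative") {
          if (pos >= r2) word <- .sw_chop(word, 5L)
        } else {
          word <- paste0(.sw_chop(word, nchar(s)), pair[2L])
        }
      }
      break
    }
  }

  # step 4 (delete in R2; "ion" only after s/t)
  for (s in .p2_step4) {
    if (.sw_ends(word, s)) {
      pos <- nchar(word) - nchar(s) + 1L
      if (pos >= r2) {
        if (s == "ion") {
          before <- if (pos > 1L) substr(word, pos - 1L, pos - 1L) else ""
          if (before %in% c("s", "t")) word <- .sw_chop(word, 3L)
        } else {
          word <- .sw_chop(word, nchar(s))
        }
      }
      break
    }
  }

  # step 5
  n <- nchar(word)
  if (.sw_ends(word, "e")) {
    if (n >= r2) {
      word <- .sw_chop(word, 1L)
    } else if (n >= r1) {
      stem <- .sw_chop(word, 1L)
      if (!.p2_ends_short_syll(strsplit(stem, "", fixed = TRUE)[[1L]])) {
        word <- stem
      }
    }
  } else if (.sw_ends(word, "ll") && n >= r2) {
    word <- .sw_chop(word, 1L)
  }

  gsub("Y", "y", word, fixed = TRUE)
}

#' Stem English words with the Snowball (Porter2) algorithm
#'
#' Applies the English Snowball stemming algorithm to each element of a
#' character vector. Words are expected to be lowercase; uppercase input is
#' lowercased first. Repeated words are stemmed once and recycled, so large
#' token streams with modest vocabularies stem quickly.
#'
#' @param words character vector of words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' snowball_stem(c("running", "ties", "relational", "happy"))
#' @export
snowball_stem <- function(words) {
  if (length(words) == 0L) return(character(0L))
  words <- tolower(words)
  uniq <- unique(words)
  stems <- vapply(uniq, .p2_stem_word, character(1L), USE.NAMES = FALSE)
  stems[match(words, uniq)]
}
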