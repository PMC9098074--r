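## Shared internal helpers: seeded evaluation, specialty-code canonicalization,
## date utilities, stage logging.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Specialty codes are free strings matched case-insensitively after trimming.
canon_specialty <- function(x) tolower(trimws(as.character(x)))

as_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(out) && !anyNA(x)) {
    bad <- which(is.na(out))[1L]
    stop("unparseable date: '", as.character(x)[bad], "' (expected ISO-8601)",
         call. = FALSE)
  }
  out
}

date_year <- function(d) as.integer(format(d, "%Y"))

year_start <- function(year) as.Date(sprintf("%d-01-01", year))
year_end <- function(year) as.Date(sprintf("%d-12-31", year))

sw_log <- function(...) message("[specwait] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
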