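## Readers and writers for the pipeline's event streams. Two plain-text
## encodings are supported so any stage can be rerun in isolation: JSON-lines
## (one object per line) and tab-delimited tables. Dates are ISO-8601.

.sw_format_from_path <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("jsonl", "tsv")))
  if (grepl("\\.jsonl$", path)) "jsonl" else "tsv"
}

.sw_write_table <- function(df, path, format, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (format == "jsonl") {
    jsonlite::stream_out(df, con, verbose = FALSE)
  } else {
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.sw_read_table <- function(path, format) {
  if (format == "jsonl") {
    con <- file(path, "r")
    on.exit(close(con))
    jsonlite::stream_in(con, verbose = FALSE)
  } else {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character")
  }
}

#' Read and write referral notes, consult claims, and truth tables
#'
#' Notes carry `patient_id`, `note_id`, `date`, `text`; claims carry
#' `patient_id`, `specialty`, `date`; truth tables carry `note_id`,
#' `specialty`, `wait_days`. The on-disk format is JSON-lines when the path
#' ends in `.jsonl`, tab-delimited otherwise (or force it via `format`).
#' Writing then reading a table is value-exact.
#'
#' @param notes,claims,truth data frames as produced by [generate_cohort()].
#' @param path file path.
#' @param format `"jsonl"`, `"tsv"`, or `NULL` to infer from the extension.
#' @param header optional comment line (without the leading `#`) recorded at
#'   the top of the file; ignored for reading.
#' @return the read data frame, or (invisibly) the path when writing.
#' @export
write_notes <- function(notes, path, format = NULL, header = NULL) {
  stopifnot_cols(notes, c("patient_id", "note_id", "date", "text"), "notes")
  out <- notes[, c("patient_id", "note_id", "date", "text")]
  out$date <- format(as_iso_date(out$date), "%Y-%m-%d")
  .sw_write_table(out, path, .sw_format_from_path(path, format), header)
}

#' @rdname write_notes
#' @export
read_notes <- function(path, format = NULL) {
  df <- .sw_read_table(path, .sw_format_from_path(path, format))
  stopifnot_cols(df, c("patient_id", "note_id", "date", "text"), "notes file")
  df$date <- as_iso_date(df$date)
  df$text <- as.character(df$text)
  df
}

#' @rdname write_notes
#' @export
write_claims <- function(claims, path, format = NULL, header = NULL) {
  stopifnot_cols(claims, c("patient_id", "specialty", "date"), "claims")
  out <- claims[, c("patient_id", "specialty", "date")]
  out$date <- format(as_iso_date(out$date), "%Y-%m-%d")
  .sw_write_table(out, path, .sw_format_from_path(path, format), header)
}

#' @rdname write_notes
#' @export
read_claims <- function(path, format = NULL) {
  df <- .sw_read_table(path, .sw_format_from_path(path, format))
  stopifnot_cols(df, c("patient_id", "specialty", "date"), "claims file")
  df$date <- as_iso_date(df$date)
  df
}

#' @rdname write_notes
#' @export
write_truth <- function(truth, path, format = NULL, header = NULL) {
  stopifnot_cols(truth, c("note_id", "specialty", "wait_days"), "truth")
  .sw_write_table(truth[, c("note_id", "specialty", "wait_days")], path,
                  .sw_format_from_path(path, format), header)
}

#' @rdname write_notes
#' @export
read_truth <- function(path, format = NULL) {
  df <- .sw_read_table(path, .sw_format_from_path(path, format))
  stopifnot_cols(df, c("note_id", "specialty", "wait_days"), "truth file")
  df$wait_days <- suppressWarnings(as.integer(df$wait_days))
  df
}
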