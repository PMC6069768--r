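#' @title Clinical-note and coded-encounter tables
#' @description The package represents a note corpus as a plain data frame
#'   with columns `patient_id`, `encounter_id`, `note_date` (class `Date`) and
#'   `text`, and an encounter/diagnosis table as a data frame with columns
#'   `patient_id`, `encounter_id`, `date` (class `Date`), `code` and
#'   `description`. [clinical_notes()] and [coded_encounters()] build validated
#'   instances of these tables.
#'
#' The `(patient_id, encounter_id, note_date)` triple need not be unique: a
#' patient can have several notes attached to one encounter. `text` and
#' `description` may be empty; `code` must be non-empty.
#' @param patient_id,encounter_id character identifiers.
#' @param note_date,date calendar dates (`Date` or ISO-8601 strings).
#' @param text free note text (may be empty).
#' @param code diagnosis code text (ICD-9, ICD-10 or local custom); non-empty.
#' @param description free-text code label (may be empty).
#' @return A validated data frame.
#' @examples
#' clinical_notes("p1", "e1", "2015-03-02", "NYHA class II today.")
#' @export
clinical_notes <- function(patient_id, encounter_id, note_date, text) {
  notes <- data.frame(
    patient_id = as.character(patient_id),
    encounter_id = as.character(encounter_id),
    note_date = as.Date(note_date),
    text = as.character(text),
    stringsAsFactors = FALSE
  )
  validate_notes(notes)
}

#' @rdname clinical_notes
#' @export
coded_encounters <- function(patient_id, encounter_id, date, code, description = "") {
  enc <- data.frame(
    patient_id = as.character(patient_id),
    encounter_id = as.character(encounter_id),
    date = as.Date(date),
    code = as.character(code),
    description = as.character(description),
    stringsAsFactors = FALSE
  )
  validate_encounters(enc)
}

NOTE_FIELDS <- c("patient_id", "encounter_id", "note_date", "text")
ENCOUNTER_FIELDS <- c("patient_id", "encounter_id", "date", "code", "description")

validate_notes <- function(notes) {
  miss <- setdiff(NOTE_FIELDS, names(notes))
  if (length(miss)) .stop_contract("note table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(notes) && anyNA(notes$note_date)) .stop_contract("note table contains unparseable note_date values")
  notes[NOTE_FIELDS]
}

validate_encounters <- function(enc) {
  miss <- setdiff(ENCOUNTER_FIELDS, names(enc))
  if (length(miss)) .stop_contract("encounter table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(enc)) {
    if (anyNA(enc$date)) .stop_contract("encounter table contains unparseable date values")
    if (any(is.na(enc$code) | !nzchar(enc$code))) .stop_contract("encounter table contains empty codes")
  }
  enc[ENCOUNTER_FIELDS]
}

# shared JSONL/CSV record reader; `fields` defines schema, `date_fields` are
# parsed as ISO-8601.  Errors cite the 0-based record index and field name.
.read_records <- function(path, format, fields, date_fields) {
  if (!file.exists(path)) .stop_contract("input file not found: %s", path)
  format <- match.arg(format, c("jsonl", "csv"))
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
        .stop_contract("record %d: invalid JSON (%s)", i - 1L, conditionMessage(e))
      })
      for (f in fields) {
        if (is.null(rec[[f]])) .stop_contract("record %d: missing field '%s'", i - 1L, f)
      }
      recs[[i]] <- lapply(rec[fields], as.character)
    }
    out <- as.data.frame(do.call(rbind, lapply(recs, function(r) unlist(r, use.names = TRUE))),
                         stringsAsFactors = FALSE)
    if (!length(recs)) {
      out <- as.data.frame(stats::setNames(rep(list(character()), length(fields)), fields),
                           stringsAsFactors = FALSE)
    }
    names(out) <- fields
  } else {
    out <- utils::read.csv(path, colClasses = "character", na.strings = character(),
                           check.names = FALSE)
    miss <- setdiff(fields, names(out))
    if (length(miss)) .stop_contract("file %s is missing required column(s): %s",
                                     path, paste(miss, collapse = ", "))
    out <- out[fields]
  }
  for (f in date_fields) {
    parsed <- as.Date(out[[f]], format = "%Y-%m-%d")
    bad <- which(is.na(parsed) | !nzchar(out[[f]]))
    if (length(bad)) .stop_contract("record %d: unparseable date '%s' in field '%s'",
                                    bad[1] - 1L, out[[f]][bad[1]], f)
    out[[f]] <- parsed
  }
  rownames(out) <- NULL
  out
}

.write_records <- function(x, path, format, date_fields) {
  format <- match.arg(format, c("jsonl", "csv"))
  y <- x
  for (f in date_fields) y[[f]] <- format(y[[f]], "%Y-%m-%d")
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(y)), function(i) {
      as.character(jsonlite::toJSON(as.list(y[i, , drop = FALSE]), auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(y, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write note corpora
#'
#' Notes are serialized as JSONL (one UTF-8 JSON object per line; the
#' canonical format, robust to embedded commas and newlines) or as CSV with a
#' header row. Fields are `patient_id`, `encounter_id`, `note_date`
#' (ISO-8601) and `text`. `read_notes()` preserves record order; a record
#' missing a required field or carrying an unparseable date raises an error
#' naming the 0-based record index and the field.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`.
#' @param notes a note table as returned by [clinical_notes()].
#' @return `read_notes()` returns a note data frame; `write_notes()` returns
#'   `path` invisibly. Round-tripping a corpus through either format is the
#'   identity.
#' @export
read_notes <- function(path, format = c("jsonl", "csv")) {
  validate_notes(.read_records(path, match.arg(format), NOTE_FIELDS, "note_date"))
}

#' @rdname read_notes
#' @export
write_notes <- function(notes, path, format = c("jsonl", "csv")) {
  .write_records(validate_notes(notes), path, match.arg(format), "note_date")
}

#' @rdname read_notes
#' @export
read_encounters <- function(path, format = c("jsonl", "csv")) {
  validate_encounters(.read_records(path, match.arg(format), ENCOUNTER_FIELDS, "date"))
}

#' @rdname read_notes
#' @param encounters an encounter table as returned by [coded_encounters()].
#' @export
write_encounters <- function(encounters, path, format = c("jsonl", "csv")) {
  .write_records(validate_encounters(encounters), path, match.arg(format), "date")
}
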