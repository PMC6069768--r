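#' Map a diagnosis-code description to an NYHA class
#'
#' Custom (local) diagnosis codes often carry free-text labels such as
#' "Congestive heart failure with left ventricular diastolic dysfunction,
#' NYHA class 3 (H)". `map_description()` applies the same trigger lexicon
#' and token grammar as the note extractor, but with the window spanning the
#' whole description (code labels are short curated strings, so the
#' 40-character bound for notes does not apply). A description maps to a
#' class only when its NYHA statement is unambiguous: a class pair, or
#' several conflicting statements, yield `NA` — code-derived labels feed the
#' reference standard and must be single classes.
#'
#' @param description free-text code label (scalar).
#' @param lexicon an [nyha_lexicon()].
#' @param config a [rule_config()]; its `window_chars` is ignored here.
#' @return an integer NYHA class in 1..4, or `NA`.
#' @examples
#' map_description("CHF (NYHA class III, ACC/AHA stage C) (H)")
#' map_description("Congestive heart failure, unspecified")
#' @export
map_description <- function(description, lexicon = nyha_lexicon(), config = rule_config()) {
  .map_description_full(description, lexicon, config)$nyha
}

.map_description_full <- function(description, lexicon, config) {
  if (length(description) != 1L || is.na(description) || !nzchar(description)) {
    return(list(nyha = NA_integer_, token = NA_character_))
  }
  cfg <- config
  cfg$window_chars <- nchar(description) + 1L
  m <- extract_mentions(description, lexicon, cfg)
  if (!nrow(m) || any(!is.na(m$class_hi))) {
    return(list(nyha = NA_integer_, token = NA_character_))
  }
  u <- unique(m$class_lo)
  if (length(u) != 1L) return(list(nyha = NA_integer_, token = NA_character_))
  list(nyha = u, token = m$raw[1])
}

#' Build an NYHA code-mapping table from coded encounters
#'
#' Deduplicates `(code, description)` pairs in first-appearance order and maps
#' each description with [map_description()]. The counts of mapped and
#' unmapped descriptions are attached as attributes `n_mapped` / `n_unmapped`
#' and shown by the print method.
#'
#' @param encounters an encounter table (see [coded_encounters()]).
#' @inheritParams map_description
#' @return a data frame of class `nyha_code_table` with columns `code`,
#'   `description`, `nyha` (integer or `NA`), `matched_token`.
#' @export
build_code_table <- function(encounters, lexicon = nyha_lexicon(), config = rule_config()) {
  encounters <- validate_encounters(encounters)
  key <- paste(encounters$code, encounters$description, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(code = encounters$code[first],
                    description = encounters$description[first],
                    stringsAsFactors = FALSE)
  mapped <- lapply(out$description, .map_description_full, lexicon = lexicon, config = config)
  out$nyha <- vapply(mapped, `[[`, integer(1), "nyha")
  out$matched_token <- vapply(mapped, `[[`, character(1), "token")
  rownames(out) <- NULL
  structure(out,
            n_mapped = sum(!is.na(out$nyha)),
            n_unmapped = sum(is.na(out$nyha)),
            class = c("nyha_code_table", "data.frame"))
}

#' @export
print.nyha_code_table <- function(x, ...) {
  cat(sprintf("NYHA code table: %d distinct codes (%d mapped, %d unmapped)\n",
              nrow(x), attr(x, "n_mapped"), attr(x, "n_unmapped")))
  print.data.frame(x, ...)
  invisible(x)
}
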