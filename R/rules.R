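#' Trigger lexicon and rule configuration
#'
#' The rule-based extractor anchors on case-insensitive occurrences of an
#' NYHA trigger phrase and parses the character window that follows it for a
#' class token. `nyha_lexicon()` builds the trigger list (default: the five
#' lexical variants "new york heart association", "new york heart
#' classification", "nyha", "ny classification", "ny class");
#' `rule_config()` collects the pattern-grammar knobs.
#'
#' @param triggers character vector of trigger phrases (matched
#'   case-insensitively at word boundaries; longest match wins at a position).
#' @param window_chars number of characters after a trigger within which the
#'   class token must lie entirely (default 40).
#' @param allow_pairs recognize contiguous two-class patterns such as
#'   "II/III" (default `TRUE`). When disabled, separator-joined class tokens
#'   are treated as ambiguous and yield no mention rather than a spurious
#'   single class.
#' @param pair_separators characters accepted between the two members of a
#'   pair; optional spaces around the separator are allowed. Default
#'   hyphen, slash and en-dash.
#' @param roman_case `"any"` (default) matches Roman numerals
#'   case-insensitively at letter boundaries; `"upper"` requires upper case.
#' @param pair_policy how a two-class mention contributes a single label:
#'   `"higher"` (default) or `"lower"`.
#' @param mention_policy how several mentions reduce to one note label:
#'   `"majority"` (default; ties broken in favour of the tied class mentioned
#'   last in document order), `"first"`, or `"last"`.
#' @return An object of class `nyha_lexicon` / `nyha_rule_config`.
#' @export
nyha_lexicon <- function(triggers = c(
                           "new york heart association",
                           "new york heart classification",
                           "nyha", "ny classification", "ny class")) {
  triggers <- tolower(trimws(as.character(triggers)))
  if (!length(triggers) || any(!nzchar(triggers))) {
    .stop_contract("trigger lexicon must contain at least one non-empty phrase")
  }
  structure(list(triggers = unique(triggers)), class = "nyha_lexicon")
}

#' @rdname nyha_lexicon
#' @export
rule_config <- function(window_chars = 40L,
                        allow_pairs = TRUE,
                        pair_separators = c("-", "/", "\u2013"),
                        roman_case = c("any", "upper"),
                        pair_policy = c("higher", "lower"),
                        mention_policy = c("majority", "first", "last")) {
  window_chars <- as.integer(window_chars)
  if (is.na(window_chars) || window_chars <= 0L) .stop_contract("window_chars must be a positive integer")
  structure(list(
    window_chars = window_chars,
    allow_pairs = isTRUE(allow_pairs),
    pair_separators = as.character(pair_separators),
    roman_case = match.arg(roman_case),
    pair_policy = match.arg(pair_policy),
    mention_policy = match.arg(mention_policy)
  ), class = "nyha_rule_config")
}

.empty_mentions <- function() {
  data.frame(span_start = integer(), span_end = integer(),
             trigger = character(), raw = character(),
             class_lo = integer(), class_hi = integer(),
             stringsAsFactors = FALSE)
}

#' Locate NYHA trigger phrases in text
#'
#' Finds all case-insensitive, non-overlapping occurrences of a lexicon
#' trigger, preferring the longest trigger at any position. "nyha" and the
#' other triggers match only at word boundaries, so a trigger embedded inside
#' a longer word is not found. Offsets are 0-based, half-open.
#'
#' @param text a single character string.
#' @param lexicon an [nyha_lexicon()].
#' @return data frame with columns `span_start`, `span_end` (0-based,
#'   half-open) and `trigger` (the matched surface text), ordered by position.
#' @examples
#' find_triggers("Pt is NYHA class II today", nyha_lexicon())
#' @export
find_triggers <- function(text, lexicon = nyha_lexicon()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(span_start = integer(), span_end = integer(),
                      trigger = character(), stringsAsFactors = FALSE))
  }
  trigs <- lexicon$triggers[order(-nchar(lexicon$triggers), lexicon$triggers)]
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", trigs)
  rx <- paste0("\\b(?:", paste(esc, collapse = "|"), ")\\b")
  m <- gregexpr(rx, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(span_start = integer(), span_end = integer(),
                      trigger = character(), stringsAsFactors = FALSE))
  }
  st <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(span_start = st - 1L, span_end = st - 1L + len,
             trigger = substring(text, st, st + len - 1L),
             stringsAsFactors = FALSE)
}

# --- token grammar -----------------------------------------------------------
# A digit class token is 1-4 at non-alphanumeric boundaries, never preceded
# by a dot nor followed by a decimal part (so the "1" of "428.1", "14" or
# "1.5" never matches, while sentence-final "2." does).  A Roman token is I/II/III/IV at
# letter boundaries (so "IVF" never matches).

.digit_core <- "[1-4]"
.digit_guard_l <- "(?<![A-Za-z0-9.])"
.digit_guard_r <- "(?![A-Za-z0-9]|\\.[0-9])"  # allow sentence-final "2."; block decimals "2.5"
.roman_core <- "(?:IV|III|II|I)"
.roman_guard_l <- "(?<![A-Za-z])"
.roman_guard_r <- "(?![A-Za-z])"

.sep_class <- function(config) {
  paste0("[", gsub("([]^\\\\-])", "\\\\\\1", paste(config$pair_separators, collapse = "")), "]")
}

.rule_patterns <- function(config) {
  ci <- if (config$roman_case == "any") "(?i)" else ""
  sep <- paste0("[ ]*", .sep_class(config), "[ ]*")
  list(
    pair_digit = paste0(.digit_guard_l, "(", .digit_core, ")", sep, "(", .digit_core, ")", .digit_guard_r),
    pair_roman = paste0(ci, .roman_guard_l, "(", .roman_core, ")", sep, "(", .roman_core, ")", .roman_guard_r),
    single_digit = paste0(.digit_guard_l, .digit_core, .digit_guard_r),
    single_roman = paste0(ci, .roman_guard_l, .roman_core, .roman_guard_r)
  )
}

.token_value <- function(tok) {
  if (grepl("^[1-4]$", tok)) as.integer(tok) else .roman_to_class(tok)
}

# all non-overlapping matches of `rx` in `window` as a (start, end) table,
# 1-based inclusive; boundary lookarounds see the full window context
.all_matches <- function(window, rx) {
  m <- gregexpr(rx, window, perl = TRUE)[[1]]
  if (m[1] == -1L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

# blocker after a single token: "or"/"to" plus a second class token (the
# ambiguous "NYHA 1 or 2" family), or a pair separator plus a class token
# that did not already form a valid pair (mixed "II-3", and any leftover
# separator-joined combination).  Returns 1-based end of the blocked stretch
# or NULL.
.single_blocker_end <- function(window, tok_end, config) {
  rest_start <- tok_end + 1L
  if (rest_start > nchar(window)) return(NULL)
  rest <- substring(window, rest_start)
  any_tok <- paste0("(?:", .digit_core, .digit_guard_r, "|(?i:", .roman_core, ")", .roman_guard_r, ")")
  rx_or <- paste0("^[ ]*(?i:or|to)[ ]+", any_tok)
  rx_sep <- paste0("^[ ]*", .sep_class(config), "[ ]*", any_tok)
  for (rx in c(rx_or, rx_sep)) {
    m <- regexpr(rx, rest, perl = TRUE)
    if (m != -1L) return(rest_start + attr(m, "match.length") - 1L)
  }
  NULL
}

#' Parse the window following a trigger for a class token
#'
#' Scans `window` left to right and returns the first decisive match: a
#' single class token (digit 1-4 or Roman numeral I-IV) or, preferred when it
#' starts at the same position, a contiguous two-class pattern separated by
#' `-`, `/` or an en-dash with optional surrounding spaces. Any characters may
#' precede the first class token inside the window. The matched token must lie
#' entirely within the first `window_chars` characters.
#'
#' Ambiguous constructions yield no mention and the scan continues past them:
#' a token followed by "or"/"to" and another class token ("1 or 2"), a
#' non-contiguous pair ("2/4"), and a mixed digit/Roman pair ("II-3").
#' Descending contiguous pairs ("III/II") are accepted and normalized to
#' ascending order.
#'
#' @param window the text following a trigger. Characters beyond
#'   `window_chars` are used only as boundary context (so a token starting
#'   near the edge is not mistakenly truncated); a mention must end within
#'   the window.
#' @param config a [rule_config()].
#' @return `NULL` if no mention, else a list with `classes` (1 or 2 ascending
#'   integers), `raw` (matched token text), and 0-based half-open `start`,
#'   `end` offsets relative to the window.
#' @examples
#' parse_window(" class II today", rule_config())
#' parse_window(" II/III symptoms", rule_config())
#' parse_window(" 1 or 2", rule_config())
#' @export
parse_window <- function(window, config = rule_config()) {
  stopifnot(is.character(window), length(window) == 1L)
  if (is.na(window) || !nzchar(window)) return(NULL)
  pats <- .rule_patterns(config)
  wc <- config$window_chars
  pairs <- if (config$allow_pairs) {
    rbind(.all_matches(window, pats$pair_digit), .all_matches(window, pats$pair_roman))
  } else cbind(start = integer(0), end = integer(0))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  singles <- rbind(.all_matches(window, pats$single_digit),
                   .all_matches(window, pats$single_roman))
  singles <- singles[order(singles[, 1]), , drop = FALSE]

  pos <- 1L
  repeat {
    p <- pairs[pairs[, 1] >= pos, , drop = FALSE]
    s <- singles[singles[, 1] >= pos, , drop = FALSE]
    if (!nrow(p) && !nrow(s)) return(NULL)

    use_pair <- nrow(p) > 0L && (!nrow(s) || p[1, 1] <= s[1, 1])
    if (use_pair) {
      if (p[1, 2] > wc) return(NULL)  # token must lie entirely within the window
      raw <- substring(window, p[1, 1], p[1, 2])
      toks <- regmatches(raw, gregexpr(paste0("(?i)", .roman_core, "|", .digit_core),
                                       raw, perl = TRUE))[[1]]
      vals <- vapply(toks, .token_value, integer(1), USE.NAMES = FALSE)
      if (abs(vals[1] - vals[2]) == 1L) {
        return(list(classes = sort(vals), raw = raw,
                    start = p[1, 1] - 1L, end = p[1, 2]))
      }
      pos <- p[1, 2] + 1L  # non-contiguous pair: ambiguous, consume and move on
      next
    }

    if (s[1, 2] > wc) return(NULL)
    blk <- .single_blocker_end(window, s[1, 2], config)
    if (!is.null(blk)) {
      pos <- blk + 1L
      next
    }
    raw <- substring(window, s[1, 1], s[1, 2])
    return(list(classes = .token_value(raw), raw = raw,
                start = s[1, 1] - 1L, end = s[1, 2]))
  }
}

#' Extract NYHA mentions from a clinical note
#'
#' Runs [find_triggers()] and [parse_window()] over a note: one mention is
#' produced per trigger whose following window parses. The mention span covers
#' the trigger start through the end of the matched class token (0-based,
#' half-open offsets into the note text). Text before a trigger is never
#' scanned.
#'
#' @param note a single-row note table, a list with a `text` element, or a
#'   character string.
#' @param lexicon an [nyha_lexicon()].
#' @param config a [rule_config()].
#' @return data frame of mentions ordered by `span_start` with columns
#'   `span_start`, `span_end`, `trigger`, `raw`, `class_lo`, `class_hi`
#'   (`class_hi` is `NA` for single-class mentions, else `class_lo + 1`).
#' @examples
#' extract_mentions("NYHA II. Previously NYHA III.")
#' @export
extract_mentions <- function(note, lexicon = nyha_lexicon(), config = rule_config()) {
  text <- if (is.character(note)) note else note$text
  if (length(text) != 1L) .stop_contract("extract_mentions() handles one note at a time")
  trg <- find_triggers(text, lexicon)
  if (!nrow(trg)) return(.empty_mentions())
  rows <- vector("list", nrow(trg))
  slack <- 24L  # boundary/blocker context beyond the window proper
  for (i in seq_len(nrow(trg))) {
    wstart <- trg$span_end[i]  # 0-based offset of first window character
    win <- substring(text, wstart + 1L, wstart + config$window_chars + slack)
    res <- parse_window(win, config)
    if (is.null(res)) next
    cls <- res$classes
    rows[[i]] <- data.frame(
      span_start = trg$span_start[i],
      span_end = wstart + res$end,
      trigger = trg$trigger[i],
      raw = res$raw,
      class_lo = cls[1],
      class_hi = if (length(cls) == 2L) cls[2] else NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.empty_mentions())
  out <- do.call(rbind, rows)
  out <- out[order(out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# resolve each mention to one class under the pair policy
.resolve_mentions <- function(mentions, config) {
  if (!nrow(mentions)) return(integer())
  hi <- mentions$class_hi
  lo <- mentions$class_lo
  if (config$pair_policy == "higher") ifelse(is.na(hi), lo, hi) else lo
}

.reduce_classes <- function(resolved, policy) {
  if (!length(resolved)) return(NA_integer_)
  switch(policy,
    first = resolved[1L],
    last = resolved[length(resolved)],
    majority = {
      tab <- table(resolved)
      top <- as.integer(names(tab)[tab == max(tab)])
      if (length(top) == 1L) top
      else {
        last_pos <- vapply(top, function(k) max(which(resolved == k)), integer(1))
        top[which.max(last_pos)]
      }
    }
  )
}

#' Reduce rule-based mentions to a note- or encounter-level class
#'
#' `classify_note_rule()` extracts mentions from one note and reduces them to
#' a single class: each two-class mention is first resolved by the pair
#' policy (default: the higher class), then multiple mentions are reduced by
#' the mention policy (default: majority vote, ties going to the tied class
#' mentioned last in document order). `classify_encounter_rule()` pools the
#' mentions of all notes belonging to one encounter, in the order given, and
#' applies the same reduction.
#'
#' @inheritParams extract_mentions
#' @param notes a note table whose rows all share `(patient_id, encounter_id)`.
#' @return an integer NYHA class in 1..4, or `NA` when no mention is found.
#' @examples
#' classify_note_rule("NYHA II. Previously NYHA III. NYHA II again.")
#' @export
classify_note_rule <- function(note, lexicon = nyha_lexicon(), config = rule_config()) {
  m <- extract_mentions(note, lexicon, config)
  .reduce_classes(.resolve_mentions(m, config), config$mention_policy)
}

#' @rdname classify_note_rule
#' @export
classify_encounter_rule <- function(notes, lexicon = nyha_lexicon(), config = rule_config()) {
  notes <- validate_notes(notes)
  if (!nrow(notes)) return(NA_integer_)
  key <- unique(paste(notes$patient_id, notes$encounter_id, sep = "\r"))
  if (length(key) != 1L) {
    .stop_contract("classify_encounter_rule(): notes span multiple encounters (%d distinct patient/encounter pairs)",
                   length(key))
  }
  pooled <- lapply(seq_len(nrow(notes)), function(i) extract_mentions(notes$text[i], lexicon, config))
  pooled <- do.call(rbind, c(pooled, list(.empty_mentions())))
  .reduce_classes(.resolve_mentions(pooled, config), config$mention_policy)
}
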