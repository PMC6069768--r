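# Independent brute-force oracles for the rule engine and the evaluation
# report.  Everything here is written as plain character-position loops (no
# shared regex machinery with the package) so the two routes can disagree.

.o_char <- function(s, i) if (i >= 1 && i <= nchar(s)) substr(s, i, i) else ""
.o_word_char <- function(ch) grepl("^[A-Za-z0-9_]$", ch)

oracle_find_triggers <- function(text, triggers = c(
  "new york heart association", "new york heart classification",
  "nyha", "ny classification", "ny class")) {
  trigs <- triggers[order(-nchar(triggers), triggers)]
  tl <- tolower(text)
  out <- list()
  i <- 1L
  n <- nchar(tl)
  while (i <= n) {
    hit <- FALSE
    for (tr in trigs) {
      L <- nchar(tr)
      if (i + L - 1L <= n && substr(tl, i, i + L - 1L) == tr &&
          !.o_word_char(.o_char(tl, i - 1L)) &&
          !.o_word_char(.o_char(tl, i + L))) {
        out[[length(out) + 1L]] <- data.frame(
          span_start = i - 1L, span_end = i - 1L + L,
          trigger = substr(text, i, i + L - 1L), stringsAsFactors = FALSE)
        i <- i + L
        hit <- TRUE
        break
      }
    }
    if (!hit) i <- i + 1L
  }
  if (!length(out)) {
    return(data.frame(span_start = integer(), span_end = integer(),
                      trigger = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# class token starting exactly at position i, or NULL
oracle_token_at <- function(s, i) {
  ch <- .o_char(s, i)
  if (ch %in% c("1", "2", "3", "4")) {
    prev <- .o_char(s, i - 1L); nxt <- .o_char(s, i + 1L)
    if (grepl("^[A-Za-z0-9.]$", prev)) return(NULL)
    if (grepl("^[A-Za-z0-9]$", nxt)) return(NULL)
    if (nxt == "." && grepl("^[0-9]$", .o_char(s, i + 2L))) return(NULL)
    return(list(len = 1L, val = as.integer(ch), kind = "digit"))
  }
  if (grepl("^[A-Za-z]$", .o_char(s, i - 1L))) return(NULL)
  for (cand in c("iv", "iii", "ii", "i")) {  # alternation order of the grammar
    L <- nchar(cand)
    if (tolower(substr(s, i, i + L - 1L)) == cand &&
        !grepl("^[A-Za-z]$", .o_char(s, i + L))) {
      return(list(len = L, val = match(cand, c("i", "ii", "iii", "iv")),
                  kind = "roman"))
    }
  }
  NULL
}

# first decisive match in a trigger window under the default grammar
oracle_parse_window <- function(s, wc = 40L) {
  seps <- c("-", "/", "–")
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    t1 <- oracle_token_at(s, pos)
    if (is.null(t1)) { pos <- pos + 1L; next }
    t1_end <- pos + t1$len - 1L

    # separator-joined second token?
    k <- t1_end + 1L
    while (.o_char(s, k) == " ") k <- k + 1L
    t2 <- NULL; t2_end <- NA_integer_
    if (.o_char(s, k) %in% seps) {
      k2 <- k + 1L
      while (.o_char(s, k2) == " ") k2 <- k2 + 1L
      t2 <- oracle_token_at(s, k2)
      if (!is.null(t2)) t2_end <- k2 + t2$len - 1L
    }

    if (!is.null(t2) && t2$kind == t1$kind) {   # homogeneous pair pattern
      if (t2_end > wc) return(NULL)
      if (abs(t1$val - t2$val) == 1L) {
        return(list(classes = sort(c(t1$val, t2$val)),
                    raw = substr(s, pos, t2_end),
                    start = pos - 1L, end = t2_end))
      }
      pos <- t2_end + 1L                        # non-contiguous: consumed
      next
    }

    if (t1_end > wc) return(NULL)
    if (!is.null(t2)) { pos <- t2_end + 1L; next }  # mixed pair: blocked

    # "or"/"to" ambiguity blocker
    k <- t1_end + 1L
    while (.o_char(s, k) == " ") k <- k + 1L
    w2 <- tolower(substr(s, k, k + 1L))
    if (w2 %in% c("or", "to")) {
      k2 <- k + 2L; nsp <- 0L
      while (.o_char(s, k2) == " ") { k2 <- k2 + 1L; nsp <- nsp + 1L }
      if (nsp >= 1L) {
        tb <- oracle_token_at(s, k2)
        if (!is.null(tb)) { pos <- k2 + tb$len; next }
      }
    }
    return(list(classes = t1$val, raw = substr(s, pos, t1_end),
                start = pos - 1L, end = t1_end))
  }
  NULL
}

oracle_extract_mentions <- function(text, wc = 40L) {
  trg <- oracle_find_triggers(text)
  rows <- list()
  for (i in seq_len(nrow(trg))) {
    wstart <- trg$span_end[i]
    win <- substring(text, wstart + 1L, wstart + wc + 24L)
    res <- oracle_parse_window(win, wc)
    if (is.null(res)) next
    cls <- res$classes
    rows[[length(rows) + 1L]] <- data.frame(
      span_start = trg$span_start[i], span_end = wstart + res$end,
      trigger = trg$trigger[i], raw = res$raw,
      class_lo = cls[1], class_hi = if (length(cls) == 2L) cls[2] else NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(span_start = integer(), span_end = integer(),
                      trigger = character(), raw = character(),
                      class_lo = integer(), class_hi = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$span_start), , drop = FALSE]
}

# random text assembled from grammar-relevant fragments (uses current RNG)
fuzz_text <- function() {
  triggers <- c("NYHA", "nyha", "Nyha", "NY class", "NY classification",
                "New York Heart Association", "New York Heart Classification")
  classish <- c("1", "2", "3", "4", "I", "II", "III", "IV", "iv", "iii", "ii", "i")
  seps <- c("-", "/", "–")
  words <- c("class", "Class", "functional", "status", "pt", "stable", "history",
             "of", "IVF", "fluids", "grade", "428.1", "x14", "today", "polynyhapse",
             "or", "to", "scale", "dyspnea")
  n <- sample(4:14, 1)
  pieces <- character(n)
  for (i in seq_len(n)) {
    r <- stats::runif(1)
    pieces[i] <- if (r < 0.25) sample(triggers, 1)
    else if (r < 0.55) sample(classish, 1)
    else if (r < 0.65) sample(seps, 1)
    else sample(words, 1)
  }
  joiners <- sample(c(" ", " ", " ", "", "  ", ", ", ". ", ": "), n - 1, replace = TRUE)
  paste0(paste0(pieces[-n], joiners, collapse = ""), pieces[n])
}

# brute-force evaluation report
oracle_evaluate <- function(pred, gold) {
  conf <- matrix(0L, 4, 4)
  abst <- integer(4)
  for (i in seq_along(gold)) {
    if (is.na(pred[i])) abst[gold[i]] <- abst[gold[i]] + 1L
    else conf[gold[i], pred[i]] <- conf[gold[i], pred[i]] + 1L
  }
  prec <- rec <- f <- rep(NA_real_, 4)
  for (k in 1:4) {
    tp <- conf[k, k]
    npred <- sum(conf[, k])
    ngold <- sum(conf[k, ]) + abst[k]
    if (npred > 0) prec[k] <- tp / npred
    if (ngold > 0) rec[k] <- tp / ngold
    if (!is.na(prec[k]) && !is.na(rec[k])) {
      f[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    }
  }
  list(confusion = conf, abstained = abst, precision = prec, recall = rec,
       f = f, macro_p = mean(prec, na.rm = TRUE), macro_r = mean(rec, na.rm = TRUE),
       f_macro = mean(f, na.rm = TRUE))
}

# small labelled corpus builder for reference-builder tests
make_labeled <- function(gold, text = "x") {
  n <- length(gold)
  data.frame(patient_id = sprintf("p%04d", seq_len(n)),
             encounter_id = sprintf("e%04d", seq_len(n)),
             note_date = as.Date("2015-01-01") + seq_len(n),
             text = rep_len(text, n), gold = as.integer(gold),
             source_code = rep_len("FV30", n), stringsAsFactors = FALSE)
}
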