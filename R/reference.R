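#' Build the labelled reference corpus by patient/date matching
#'
#' A note receives a gold NYHA label when at least one NYHA-mapped diagnosis
#' code exists for the same patient on the same calendar date (the reference-
#' standard assumption: a note should mention the same NYHA class as the
#' custom diagnosis code attached to its encounter). If all matching mapped
#' codes agree, the note is labelled with that class; if they conflict, the
#' note is excluded by default (`conflict = "exclude"`) and logged, or given
#' the modal class under `conflict = "majority"` (modal ties still exclude).
#' Notes without any matching mapped code are dropped.
#'
#' @param notes a note table (see [clinical_notes()]).
#' @param code_table an [build_code_table()] result (or any data frame with
#'   `code`, `description`, `nyha`).
#' @param encounters an encounter table (see [coded_encounters()]).
#' @param conflict policy for conflicting same-date code labels.
#' @param match_on `"date"` (default; same patient, same calendar date) or
#'   `"encounter"` (strict: same patient and encounter id).
#' @return a labelled-note data frame: the note columns plus `gold` (integer
#'   1..4) and `source_code`. Attributes: `conflicts` (excluded notes with the
#'   conflicting class sets), `n_unmatched` (notes without a mapped code).
#' @export
match_notes_to_codes <- function(notes, code_table, encounters,
                                 conflict = c("exclude", "majority"),
                                 match_on = c("date", "encounter")) {
  notes <- validate_notes(notes)
  encounters <- validate_encounters(encounters)
  conflict <- match.arg(conflict)
  match_on <- match.arg(match_on)

  ct <- as.data.frame(code_table)[, c("code", "description", "nyha")]
  ct <- ct[!is.na(ct$nyha), , drop = FALSE]
  enc <- merge(encounters, ct, by = c("code", "description"))

  enc_key <- if (match_on == "date") {
    paste(enc$patient_id, format(enc$date, "%Y-%m-%d"))
  } else {
    paste(enc$patient_id, enc$encounter_id)
  }
  note_key <- if (match_on == "date") {
    paste(notes$patient_id, format(notes$note_date, "%Y-%m-%d"))
  } else {
    paste(notes$patient_id, notes$encounter_id)
  }

  by_key_class <- split(enc$nyha, enc_key)
  by_key_code <- split(enc$code, enc_key)

  gold <- rep(NA_integer_, nrow(notes))
  src <- rep(NA_character_, nrow(notes))
  conflict_rows <- integer(0)
  conflict_sets <- character(0)
  for (i in seq_len(nrow(notes))) {
    cls <- by_key_class[[note_key[i]]]
    if (is.null(cls)) next
    u <- sort(unique(cls))
    pick <- NA_integer_
    if (length(u) == 1L) {
      pick <- u
    } else if (conflict == "majority") {
      tab <- table(cls)
      top <- as.integer(names(tab)[tab == max(tab)])
      if (length(top) == 1L) pick <- top
    }
    if (is.na(pick)) {
      conflict_rows <- c(conflict_rows, i)
      conflict_sets <- c(conflict_sets, paste(u, collapse = "/"))
      next
    }
    gold[i] <- pick
    src[i] <- by_key_code[[note_key[i]]][match(pick, cls)]
  }

  keep <- !is.na(gold)
  out <- notes[keep, , drop = FALSE]
  out$gold <- gold[keep]
  out$source_code <- src[keep]
  rownames(out) <- NULL
  conflicts <- cbind(notes[conflict_rows, , drop = FALSE],
                     data.frame(classes = conflict_sets, stringsAsFactors = FALSE))
  rownames(conflicts) <- NULL
  structure(out,
            conflicts = conflicts,
            n_unmatched = sum(!keep) - length(conflict_rows),
            class = c("nyha_labeled", "data.frame"))
}

#' Split a labelled corpus into training and testing sets
#'
#' Seeded random split. With `stratify = TRUE` the test set is allocated per
#' class by largest-remainder rounding, so per-class train/test proportions
#' differ from the overall proportion by at most one note per class.
#'
#' @param labeled a labelled-note data frame (see [match_notes_to_codes()]).
#' @param test_fraction proportion of notes held out for testing (0 < f < 1).
#' @param seed integer seed; the split is reproducible given the seed.
#' @param stratify stratify the split by gold class.
#' @return an object of class `nyha_split`: list with `train`, `test`
#'   (disjoint data frames covering the corpus) and `seed`.
#' @examples
#' lab <- data.frame(patient_id = paste0("p", 1:10), encounter_id = paste0("e", 1:10),
#'                   note_date = as.Date("2015-01-01") + 1:10, text = "x",
#'                   gold = rep(1:2, 5), source_code = "FV")
#' s <- split_corpus(lab, 0.3, seed = 7, stratify = TRUE)
#' nrow(s$test)
#' @export
split_corpus <- function(labeled, test_fraction, seed, stratify = FALSE) {
  n <- nrow(labeled)
  if (is.null(n) || n == 0L) .stop_contract("split_corpus(): the corpus is empty")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    .stop_contract("test_fraction must lie strictly between 0 and 1")
  }
  n_test <- max(1L, min(n - 1L, as.integer(round(n * test_fraction))))
  idx <- if (!stratify) {
    withr::with_seed(seed, sample.int(n, n_test))
  } else {
    cls_idx <- split(seq_len(n), labeled$gold)
    sizes <- lengths(cls_idx)
    quota <- sizes * n_test / n
    take <- floor(quota)
    rem <- n_test - sum(take)
    if (rem > 0) {
      ord <- order(-(quota - take), seq_along(take))  # largest remainder, ties by class order
      bump <- ord[seq_len(rem)]
      take[bump] <- take[bump] + 1L
    }
    take <- pmin(take, sizes)
    withr::with_seed(seed, {
      unlist(lapply(seq_along(cls_idx), function(k) {
        if (take[k] == 0L) integer(0) else sample(cls_idx[[k]], take[k])
      }), use.names = FALSE)
    })
  }
  idx <- sort(idx)
  train <- labeled[-idx, , drop = FALSE]
  test <- labeled[idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  structure(list(train = train, test = test, seed = as.integer(seed)),
            class = "nyha_split")
}

#' Per-class counts of a labelled corpus or split
#'
#' Tabulates gold NYHA classes. For an `nyha_split` the result has the shape
#' of the usual corpus-description table: one row per class plus a total row,
#' with training, testing and combined counts and the combined proportions.
#'
#' @param x a labelled-note data frame or an `nyha_split`.
#' @return a data frame of class `nyha_corpus_summary` with columns `nyha`,
#'   (`train`, `test` for splits,) `total` and `proportion`.
#' @export
corpus_summary <- function(x) {
  count4 <- function(df) tabulate(factor(df$gold, levels = 1:4), nbins = 4L)
  if (inherits(x, "nyha_split")) {
    tr <- count4(x$train); te <- count4(x$test); tot <- tr + te
    out <- data.frame(nyha = c(.ROMAN, "Total"),
                      train = c(tr, sum(tr)),
                      test = c(te, sum(te)),
                      total = c(tot, sum(tot)),
                      stringsAsFactors = FALSE)
  } else {
    tot <- count4(x)
    out <- data.frame(nyha = c(.ROMAN, "Total"),
                      total = c(tot, sum(tot)),
                      stringsAsFactors = FALSE)
  }
  grand <- out$total[5]
  out$proportion <- if (grand > 0) out$total / grand else rep(0, 5)
  structure(out, class = c("nyha_corpus_summary", "data.frame"))
}

#' @export
print.nyha_corpus_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$proportion <- sprintf("%.1f%%", 100 * y$proportion)
  cat("Notes per NYHA class\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
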