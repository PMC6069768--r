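#' Synthetic EHR generator configuration
#'
#' Controls the seeded generator of synthetic clinical notes, coded
#' encounters and custom NYHA diagnosis codes. The default class
#' distribution follows the reference corpus the package emulates
#' (1367 : 2502 : 1790 : 515 over classes I-IV, i.e. roughly 22/41/29/8
#' percent), so the scarcity of class IV — the known hard case — is
#' reproduced. Styles: `digit` ("NYHA class 3"), `roman` ("NYHA class III"),
#' `pair` ("NYHA II/III"; the planted class is the pair's higher member, to
#' match the extractor's default pair policy), `none` (no trigger at all),
#' `ambiguous_or` ("NYHA 1 or 2", which the rules must reject) and
#' `distractor_iv` ("IV fluids" plus a trigger with no class in its window).
#'
#' @param n_patients number of synthetic patients.
#' @param notes_per_patient integer range `c(lo, hi)`; each patient receives
#'   a uniform draw of notes, one encounter per note, on distinct dates.
#' @param class_distribution named proportions over classes 1..4 (sum 1).
#' @param mention_style_mix named proportions over the six styles.
#' @param trigger_mix proportions over the lexicon triggers used in mention
#'   sentences.
#' @param label_noise proportion of labelled notes whose diagnosis-code class
#'   is flipped to a different class than the planted mention.
#' @param seed integer seed; generation is byte-identical given the seed.
#' @return an object of class `nyha_generator_config`.
#' @export
generator_config <- function(n_patients = 500L,
                             notes_per_patient = c(1L, 3L),
                             class_distribution = c(`1` = 1367, `2` = 2502,
                                                    `3` = 1790, `4` = 515) / 6174,
                             mention_style_mix = c(digit = 0.30, roman = 0.40,
                                                   pair = 0.15, none = 0.05,
                                                   ambiguous_or = 0.05,
                                                   distractor_iv = 0.05),
                             trigger_mix = c("nyha" = 0.60,
                                             "new york heart association" = 0.15,
                                             "ny class" = 0.15,
                                             "new york heart classification" = 0.05,
                                             "ny classification" = 0.05),
                             label_noise = 0,
                             seed = 1L) {
  class_distribution <- as.numeric(class_distribution)
  if (length(class_distribution) != 4L || any(class_distribution < 0) ||
      abs(sum(class_distribution) - 1) > 1e-9) {
    .stop_contract("class_distribution must be 4 non-negative proportions summing to 1")
  }
  styles <- c("digit", "roman", "pair", "none", "ambiguous_or", "distractor_iv")
  mix <- rep(0, 6); names(mix) <- styles
  mix[names(mention_style_mix)] <- as.numeric(mention_style_mix)
  if (any(mix < 0) || sum(mix) <= 0) .stop_contract("mention_style_mix must be non-negative with positive sum")
  if (!(label_noise >= 0 && label_noise <= 1)) .stop_contract("label_noise must lie in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 notes_per_patient = as.integer(notes_per_patient),
                 class_distribution = class_distribution,
                 mention_style_mix = mix / sum(mix),
                 trigger_mix = trigger_mix,
                 label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "nyha_generator_config")
}

# surface form used in note text for each canonical trigger
.trigger_surface <- c(
  "nyha" = "NYHA",
  "new york heart association" = "New York Heart Association",
  "new york heart classification" = "New York Heart Classification",
  "ny classification" = "NY classification",
  "ny class" = "NY class"
)

# filler sentences: no triggers, no standalone class tokens
.filler_pool <- c(
  "Patient seen in cardiology clinic for routine follow up.",
  "Blood pressure stable on current medications.",
  "Denies chest pain at rest or with exertion.",
  "Echocardiogram reviewed and discussed with the patient.",
  "Continue furosemide at the current dose.",
  "Weight stable since the last visit.",
  "No lower extremity edema on examination today.",
  "Plan to repeat basic labs in six weeks."
)

# distractor fillers: class-like tokens in non-NYHA contexts (no triggers),
# deliberately polluting unigram features
.distractor_pool <- c(
  "Received IV fluids during the observation stay.",
  "Grade II/VI systolic murmur noted on auscultation.",
  "Patient walked 3 laps in the hallway without rest.",
  "Pain rated 4 out of 10 at its worst."
)

.mention_sentence <- function(style, k, trig_surface) {
  roman <- .ROMAN
  switch(style,
    digit = sprintf(sample(c("%s class %d at today's visit.",
                             "Functional status %s %d.",
                             "%s class %d with stable symptoms."), 1L),
                    trig_surface, k),
    roman = sprintf(sample(c("%s class %s on examination.",
                             "%s %s, unchanged on current therapy.",
                             "Assessed today as %s class %s."), 1L),
                    trig_surface, roman[k]),
    pair = {
      sep <- sample(c("/", "-", "\u2013"), 1L)
      if (stats::runif(1) < 0.5) {
        sprintf("%s class %d%s%d symptoms.", trig_surface, k - 1L, sep, k)
      } else {
        sprintf("%s %s%s%s on exertion.", trig_surface, roman[k - 1L], sep, roman[k])
      }
    },
    ambiguous_or = sprintf("%s %d or %d, difficult to grade today.",
                           trig_surface, k, k + 1L),
    distractor_iv = sprintf("%s class not documented at this visit.", trig_surface),
    none = "Functional status not formally assessed today."
  )
}

# custom NYHA diagnosis-code catalogue: deterministic code/description per
# (class, variant), emulating local codes whose labels embed the class
.custom_code <- function(label, variant) {
  code <- sprintf("FV%02d", label * 10L + variant)
  description <- if (variant == 0L) {
    sprintf("CHF (NYHA class %d, ACC/AHA stage C) (H)", label)
  } else {
    sprintf("Congestive heart failure with left ventricular systolic dysfunction, NYHA class %s (H)",
            .ROMAN[label])
  }
  list(code = code, description = description)
}

#' Generate a synthetic EHR corpus
#'
#' Builds synthetic clinical notes, one encounter per note, together with a
#' coded-encounter table: every patient carries a heart-failure ICD code, and
#' every note with a planted unambiguous mention gets a same-patient,
#' same-date custom diagnosis code whose description encodes the planted
#' class (flipped to a different class with probability `label_noise`).
#' Note text is assembled from clinical sentence templates: a few filler or
#' distractor sentences followed by at most one NYHA mention sentence, so
#' notes with style `digit`, `roman` or `pair` contain exactly one mention.
#'
#' @param config a [generator_config()].
#' @param lexicon the [nyha_lexicon()] whose triggers the mention sentences
#'   draw from.
#' @return an object of class `nyha_corpus`: list with `notes`,
#'   `encounters`, and `truth` (row-aligned with `notes`: `planted_class`,
#'   `planted_style`, `label_class`) plus the `config`.
#' @examples
#' corp <- generate_corpus(generator_config(n_patients = 5, seed = 42))
#' corp$notes$text[1]
#' @export
generate_corpus <- function(config = generator_config(), lexicon = nyha_lexicon()) {
  stopifnot(inherits(config, "nyha_generator_config"))
  trig_mix <- config$trigger_mix
  trig_names <- names(trig_mix) %||% lexicon$triggers[seq_along(trig_mix)]
  dates <- seq(as.Date("2012-01-01"), as.Date("2015-12-31"), by = "day")

  withr::with_seed(config$seed, {
    notes <- list(); encs <- list(); truth <- list()
    enc_counter <- 0L
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%05d", p)
      lo <- config$notes_per_patient[1]; hi <- config$notes_per_patient[2]
      n_notes <- if (hi > lo) sample(lo:hi, 1L) else lo
      pdates <- sort(sample(dates, n_notes))
      for (j in seq_len(n_notes)) {
        enc_counter <- enc_counter + 1L
        eid <- sprintf("E%06d", enc_counter)
        style <- sample(names(config$mention_style_mix), 1L,
                        prob = config$mention_style_mix)
        k <- sample(1:4, 1L, prob = config$class_distribution)
        if (style == "pair" && k == 1L) style <- "roman"  # pairs resolve upward; class-1 pairs cannot exist
        if (style == "ambiguous_or" && k == 4L) k <- 3L
        trig <- sample(trig_names, 1L, prob = trig_mix)
        n_fill <- sample(2:4, 1L)
        fillers <- sample(c(.filler_pool, .distractor_pool), n_fill)
        body <- .mention_sentence(style, k, .trigger_surface[[trig]])
        text <- paste(c(fillers, body), collapse = " ")

        planted <- if (style %in% c("digit", "roman", "pair")) k else NA_integer_
        label <- NA_integer_
        if (!is.na(planted)) {
          label <- planted
          if (config$label_noise > 0 && stats::runif(1) < config$label_noise) {
            label <- sample(setdiff(1:4, planted), 1L)
          }
          cc <- .custom_code(label, sample(0:1, 1L))
          encs[[length(encs) + 1L]] <- data.frame(
            patient_id = pid, encounter_id = eid, date = pdates[j],
            code = cc$code, description = cc$description,
            stringsAsFactors = FALSE)
        } else {
          encs[[length(encs) + 1L]] <- data.frame(
            patient_id = pid, encounter_id = eid, date = pdates[j],
            code = "428.9", description = "Congestive heart failure, unspecified",
            stringsAsFactors = FALSE)
        }
        if (j == 1L) {  # every patient carries an HF ICD diagnosis
          encs[[length(encs) + 1L]] <- data.frame(
            patient_id = pid, encounter_id = eid, date = pdates[j],
            code = sample(c("428.0", "428.22", "I50.9", "I11.0"), 1L),
            description = "Heart failure", stringsAsFactors = FALSE)
        }
        notes[[length(notes) + 1L]] <- data.frame(
          patient_id = pid, encounter_id = eid, note_date = pdates[j],
          text = text, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          patient_id = pid, encounter_id = eid, note_date = pdates[j],
          planted_style = style, planted_class = planted, label_class = label,
          stringsAsFactors = FALSE)
      }
    }
    structure(list(notes = validate_notes(do.call(rbind, notes)),
                   encounters = validate_encounters(do.call(rbind, encs)),
                   truth = do.call(rbind, truth),
                   config = config),
              class = "nyha_corpus")
  })
}

#' @export
print.nyha_corpus <- function(x, ...) {
  cat(sprintf("Synthetic EHR corpus: %d notes, %d patients, %d coded encounter rows\n",
              nrow(x$notes), length(unique(x$notes$patient_id)), nrow(x$encounters)))
  print(table(style = x$truth$planted_style))
  invisible(x)
}

#' Frozen worked examples for the rule grammar
#'
#' A fixed fixture set covering every pattern rule and the known failure
#' categories: single digits and Roman numerals, contiguous pairs with all
#' three separators, the "1 or 2" ambiguity rejection, non-contiguous and
#' mixed pairs, the 40-character window boundary, the "IV fluids" / "IVF"
#' distractors, word-boundary behaviour, and multi-mention notes. Used as
#' the golden test suite for the extractor.
#'
#' @return list of records, each with `text`, `expected` (data frame of
#'   `class_lo`, `class_hi` per expected mention, zero rows when no mention
#'   must be found) and a short `note`.
#' @export
generate_worked_examples <- function() {
  rec <- function(text, lo, hi, note) {
    list(text = text,
         expected = data.frame(class_lo = as.integer(lo), class_hi = as.integer(hi)),
         note = note)
  }
  list(
    rec("NYHA class II today.", 2, NA, "single Roman numeral"),
    rec("Pt is NYHA class 3 at rest.", 3, NA, "single digit"),
    rec("NYHA 1.", 1, NA, "digit class 1"),
    rec("nyha class iv confirmed.", 4, NA, "lower-case Roman numeral"),
    rec("New York Heart Association class III documented.", 3, NA,
        "full-phrase trigger, no nested NY trigger"),
    rec("NY class 2 per cardiology.", 2, NA, "short trigger variant"),
    rec("NYHA II/III symptoms on exertion.", 2, 3, "contiguous Roman pair, slash"),
    rec("NYHA 1–2 on exertion.", 1, 2, "contiguous digit pair, en-dash"),
    rec("NYHA II - III with spaces.", 2, 3, "pair with spaces around separator"),
    rec("NYHA III/II noted.", 2, 3, "descending pair normalized ascending"),
    rec("NYHA 1 or 2, difficult to assess.", integer(0), integer(0),
        "ambiguous 'or' link rejected"),
    rec("NYHA 2 to 3 by history.", integer(0), integer(0),
        "ambiguous 'to' link rejected"),
    rec("NYHA 2/4 dyspnea scale.", integer(0), integer(0),
        "non-contiguous pair rejected"),
    rec("NYHA II-3 mixed notation.", integer(0), integer(0),
        "mixed digit/Roman pair rejected"),
    rec("Gave IV fluids; no NYHA documented this visit.", integer(0), integer(0),
        "IV before the trigger is never scanned"),
    rec("Patient on IVF support. NYHA class IV.", 4, NA,
        "IV followed by a letter never matches"),
    rec(paste0("NYHA ", strrep("x", 38), " III"), integer(0), integer(0),
        "class token beyond the 40-character window"),
    rec(paste0("NYHA ", strrep("x", 34), " III"), 3, NA,
        "class token ending exactly at the window edge"),
    rec("polynyhapse noted.", integer(0), integer(0),
        "trigger inside a word does not match"),
    rec("NYHA 2. Previously NYHA 3.", c(2, 3), c(NA, NA), "two mentions in order"),
    rec("No NYHA class documented.", integer(0), integer(0),
        "trigger without a class token")
  )
}
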