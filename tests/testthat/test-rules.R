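test_that("triggers are found case-insensitively at word boundaries, longest first", {
  t1 <- find_triggers("Pt is NYHA class II today")
  expect_identical(nrow(t1), 1L)
  expect_identical(t1$span_start, 6L)
  expect_identical(t1$span_end, 10L)
  expect_identical(t1$trigger, "NYHA")

  t2 <- find_triggers("New York Heart Association class III")
  expect_identical(nrow(t2), 1L)
  expect_identical(t2$trigger, "New York Heart Association")

  expect_identical(nrow(find_triggers("polynyhapse")), 0L)
  expect_identical(nrow(find_triggers("NY classification 2 and nyha 3")), 2L)
})

test_that("windows parse singles, pairs and the window boundary", {
  cfg <- rule_config()
  expect_identical(parse_window(" class II today", cfg)$classes, 2L)
  expect_identical(parse_window(" class II today", cfg)$raw, "II")
  expect_identical(parse_window(" II/III symptoms", cfg)$classes, c(2L, 3L))
  expect_identical(parse_window(" 1–2 on exertion", cfg)$classes, c(1L, 2L))
  expect_identical(parse_window(" II - III spaced", cfg)$classes, c(2L, 3L))
  expect_null(parse_window(" 1 or 2", cfg))
  expect_null(parse_window(" 2 to 3", cfg))
  expect_null(parse_window(" 2/4 dyspnea", cfg))
  expect_null(parse_window(" II-3 mixed", cfg))
  # token beginning beyond the window
  expect_null(parse_window(paste0(strrep("x", 39), " 2"), cfg))
  expect_identical(parse_window(paste0(strrep("x", 38), " 2"), cfg)$classes, 2L)
  # with pairs disabled a separator-joined expression stays ambiguous
  nopair <- rule_config(allow_pairs = FALSE)
  expect_null(parse_window(" II/III symptoms", nopair))
  expect_identical(parse_window(" II today", nopair)$classes, 2L)
})

test_that("exactly the contiguous ordered digit pairs are accepted", {
  cfg <- rule_config()
  for (a in 1:4) for (b in 1:4) {
    res <- parse_window(sprintf(" %d/%d rest", a, b), cfg)
    if (abs(a - b) == 1L) {
      expect_identical(res$classes, sort(c(a, b)), info = paste(a, b))
    } else {
      expect_null(res, info = paste(a, b))
    }
  }
})

test_that("mentions cover trigger through token, in document order", {
  m <- extract_mentions("NYHA class III. Stable.")
  expect_identical(nrow(m), 1L)
  expect_identical(m$class_lo, 3L)
  expect_identical(m$span_start, 0L)
  expect_identical(m$span_end, 14L)  # through the end of "III"

  m2 <- extract_mentions("NYHA II. Previously NYHA III.")
  expect_identical(m2$class_lo, c(2L, 3L))
  expect_true(all(diff(m2$span_start) > 0))

  # text before a trigger is never scanned
  expect_identical(nrow(extract_mentions("Gave IV fluids; no NYHA documented this visit")), 0L)
  # Roman followed by a letter never matches
  m3 <- extract_mentions("Patient on IVF support. NYHA class IV.")
  expect_identical(m3$class_lo, 4L)
})

test_that("note reduction follows the pair and mention policies", {
  expect_identical(classify_note_rule("NYHA class 2."), 2L)
  expect_identical(classify_note_rule("NYHA II/III."), 3L)          # pair -> higher
  expect_identical(classify_note_rule("NYHA II/III.",
                                      config = rule_config(pair_policy = "lower")), 2L)
  expect_identical(classify_note_rule("NYHA 2. NYHA 2. NYHA 3."), 2L)  # majority
  expect_identical(classify_note_rule("NYHA 2. NYHA 4."), 4L)          # tie -> last mention
  expect_identical(classify_note_rule("NYHA 2. NYHA 4.",
                                      config = rule_config(mention_policy = "first")), 2L)
  expect_identical(classify_note_rule("No class documented."), NA_integer_)
})

test_that("encounter reduction pools mentions and rejects mixed encounters", {
  notes <- clinical_notes(rep("p1", 2), rep("e1", 2), rep("2015-01-01", 2),
                          c("NYHA III noted.", "Plan unchanged. NYHA III."))
  expect_identical(classify_encounter_rule(notes), 3L)
  notes$text[2] <- "No mention here."
  expect_identical(classify_encounter_rule(notes), 3L)
  notes$text <- c("NYHA 2.", "NYHA 4.")
  expect_identical(classify_encounter_rule(notes), 4L)  # tie -> later note's mention
  mixed <- notes
  mixed$encounter_id <- c("e1", "e2")
  expect_error(classify_encounter_rule(mixed), "multiple encounters")
})

test_that("extractor agrees with the brute-force oracle on fuzzed text", {
  withr::with_seed(1234, {
    for (i in 1:400) {
      txt <- fuzz_text()
      got <- extract_mentions(txt)
      want <- oracle_extract_mentions(txt)
      rownames(got) <- rownames(want) <- NULL
      expect_identical(got, want, info = txt)
    }
  })
})

test_that("mention tokens lie within the window and grow monotonically with it", {
  withr::with_seed(4321, {
    for (i in 1:150) {
      txt <- fuzz_text()
      m40 <- extract_mentions(txt)
      if (nrow(m40)) {
        trig_end <- m40$span_start + nchar(m40$trigger)
        expect_true(all(m40$span_end - trig_end <= 40L), info = txt)
      }
      m20 <- extract_mentions(txt, config = rule_config(window_chars = 20))
      m60 <- extract_mentions(txt, config = rule_config(window_chars = 60))
      key <- function(m) paste(m$span_start, m$span_end, m$raw)
      expect_true(all(key(m20) %in% key(m40)), info = txt)
      expect_true(all(key(m40) %in% key(m60)), info = txt)
      # determinism
      expect_identical(extract_mentions(txt), m40)
    }
  })
})
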