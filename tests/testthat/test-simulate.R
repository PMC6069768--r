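test_that("generation is byte-identical under a fixed seed", {
  c1 <- generate_corpus(generator_config(n_patients = 40, seed = 7))
  c2 <- generate_corpus(generator_config(n_patients = 40, seed = 7))
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$encounters, c2$encounters)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_corpus(generator_config(n_patients = 40, seed = 8))
  expect_false(identical(c1$notes$text, c3$notes$text))
})

test_that("the extractor recovers every planted unambiguous mention", {
  cfg <- generator_config(n_patients = 200, notes_per_patient = c(1L, 2L),
                          mention_style_mix = c(digit = 0.3, roman = 0.5, pair = 0.2),
                          seed = 21)
  corp <- generate_corpus(cfg)
  pred <- vapply(corp$notes$text, classify_note_rule, integer(1), USE.NAMES = FALSE)
  expect_identical(pred, corp$truth$planted_class)
  # exactly one mention per note
  n_m <- vapply(corp$notes$text, function(t) nrow(extract_mentions(t)), integer(1),
                USE.NAMES = FALSE)
  expect_true(all(n_m == 1L))
})

test_that("noiseless reference labels equal the planted classes", {
  corp <- generate_corpus(generator_config(n_patients = 150, seed = 31))
  ct <- build_code_table(corp$encounters)
  lab <- match_notes_to_codes(corp$notes, ct, corp$encounters)
  tr <- corp$truth
  expect_identical(nrow(lab), sum(!is.na(tr$planted_class)))
  key <- paste(tr$patient_id, tr$note_date)
  planted <- tr$planted_class[match(paste(lab$patient_id, lab$note_date), key)]
  expect_identical(lab$gold, planted)
})

test_that("label noise converges to its nominal rate", {
  p <- 0.2
  corp <- generate_corpus(generator_config(n_patients = 700, notes_per_patient = c(2L, 2L),
                                           label_noise = p, seed = 41))
  tr <- corp$truth
  has <- !is.na(tr$planted_class)
  disagree <- mean(tr$label_class[has] != tr$planted_class[has])
  se <- sqrt(p * (1 - p) / sum(has))
  expect_lt(abs(disagree - p), 3 * se)
})

test_that("realized class frequencies follow the configured distribution", {
  cfg <- generator_config(n_patients = 700, notes_per_patient = c(2L, 2L), seed = 51)
  corp <- generate_corpus(cfg)
  tr <- corp$truth[!is.na(corp$truth$planted_class), ]
  n <- nrow(tr)
  freq <- tabulate(tr$planted_class, 4) / n
  expect_true(all(abs(freq - cfg$class_distribution) <
                    3 * sqrt(cfg$class_distribution * (1 - cfg$class_distribution) / n)))
})

test_that("worked examples cover the pattern grammar and are stable", {
  wx <- generate_worked_examples()
  expect_gt(length(wx), 15)
  raws <- vapply(wx, `[[`, character(1), "text")
  expect_true(any(grepl("II/III", raws)))
  expect_true(any(grepl("1 or 2", raws)))
  expect_identical(generate_worked_examples(), wx)
})
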