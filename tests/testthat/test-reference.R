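ref_fixture <- function() {
  notes <- clinical_notes(
    patient_id = c("p1", "p2", "p3", "p3"),
    encounter_id = c("e1", "e2", "e3", "e4"),
    note_date = c("2015-03-02", "2015-03-02", "2015-05-01", "2015-05-02"),
    text = c("NYHA class 2.", "No codes here.", "NYHA 3.", "NYHA 3 again.")
  )
  enc <- coded_encounters(
    patient_id = c("p1", "p3", "p3", "p3"),
    encounter_id = c("e1", "e3", "e3b", "e4"),
    date = c("2015-03-02", "2015-05-01", "2015-05-01", "2015-05-02"),
    code = c("FV20", "FV30", "FV21", "FV30"),
    description = c("CHF (NYHA class 2) (H)", "CHF (NYHA class 3) (H)",
                    "CHF (NYHA class 2) (H)", "CHF (NYHA class 3) (H)")
  )
  list(notes = notes, enc = enc, ct = build_code_table(enc))
}

test_that("notes are labelled by same-patient same-date mapped codes", {
  f <- ref_fixture()
  lab <- match_notes_to_codes(f$notes, f$ct, f$enc)
  # p1 labelled 2; p2 unmatched; p3 on 05-01 conflicting (2 vs 3) -> excluded;
  # p3 on 05-02 labelled 3
  expect_identical(nrow(lab), 2L)
  expect_identical(lab$gold, c(2L, 3L))
  expect_identical(lab$source_code, c("FV20", "FV30"))
  conf <- attr(lab, "conflicts")
  expect_identical(nrow(conf), 1L)
  expect_identical(conf$classes, "2/3")
  expect_identical(attr(lab, "n_unmatched"), 1L)
  # every label has a supporting mapped code for its patient/date
  enc_keys <- paste(f$enc$patient_id, f$enc$date)
  expect_true(all(paste(lab$patient_id, lab$note_date) %in% enc_keys))
})

test_that("the majority conflict policy keeps the modal class", {
  f <- ref_fixture()
  extra <- coded_encounters("p3", "e3c", "2015-05-01", "FV31", "CHF (NYHA class 3) (H)")
  enc <- rbind(f$enc, extra)
  ct <- build_code_table(enc)
  lab <- match_notes_to_codes(f$notes, ct, enc, conflict = "majority")
  expect_identical(lab$gold[lab$patient_id == "p3" & lab$note_date == as.Date("2015-05-01")], 3L)
  # strict encounter matching only links codes on the same encounter id
  lab_strict <- match_notes_to_codes(f$notes, f$ct, f$enc, match_on = "encounter")
  expect_identical(lab_strict$gold, c(2L, 3L, 3L))  # e3's conflict is gone: e3b is a different encounter
})

test_that("splits are seeded, disjoint and exhaustive", {
  lab <- make_labeled(rep(1:4, times = c(22, 41, 29, 8)))
  s1 <- split_corpus(lab, 0.4, seed = 13)
  s2 <- split_corpus(lab, 0.4, seed = 13)
  expect_identical(s1$train, s2$train)
  expect_identical(s1$test, s2$test)
  expect_identical(nrow(s1$train) + nrow(s1$test), nrow(lab))
  expect_identical(intersect(s1$train$patient_id, s1$test$patient_id), character(0))
  expect_identical(nrow(s1$test), 40L)
  expect_error(split_corpus(lab[0, ], 0.4, seed = 1), "empty")
  expect_error(split_corpus(lab, 1.2, seed = 1), "test_fraction")
})

test_that("stratified splits balance classes to within one note", {
  lab <- make_labeled(rep(1:2, each = 5))
  s <- split_corpus(lab, 0.3, seed = 5, stratify = TRUE)
  expect_identical(nrow(s$test), 3L)
  expect_true(all(table(factor(s$test$gold, 1:2)) %in% 1:2))
  lab2 <- make_labeled(rep(1:4, times = c(220, 410, 290, 80)))
  s2 <- split_corpus(lab2, 0.4, seed = 5, stratify = TRUE)
  overall <- nrow(s2$test) / nrow(lab2)
  per_class_test <- table(factor(s2$test$gold, 1:4))
  per_class_all <- table(factor(lab2$gold, 1:4))
  expect_true(all(abs(per_class_test - overall * per_class_all) <= 1))
})

test_that("corpus summaries conserve counts across the split", {
  lab <- make_labeled(rep(1:4, times = c(12, 25, 17, 6)))
  s <- split_corpus(lab, 0.4, seed = 3)
  summ <- corpus_summary(s)
  expect_identical(summ$total, summ$train + summ$test)
  expect_identical(summ$total[5], nrow(lab))
  expect_identical(summ$train[5], sum(summ$train[1:4]))
  expect_equal(sum(summ$proportion[1:4]), 1)
  empty <- corpus_summary(make_labeled(integer(0)))
  expect_identical(empty$total, rep(0L, 5))
})
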