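# linearly separable 4-class fixture: feature k is hot for class k
separable_fixture <- function(n = 48, seed = 9) {
  withr::with_seed(seed, {
    k <- rep(1:4, each = n / 4)
    x <- matrix(stats::rnorm(n * 6, sd = 0.1), n, 6,
                dimnames = list(NULL, paste0("t", 1:6)))
    for (i in seq_len(n)) x[i, k[i]] <- 3
    list(x = x, y = k)
  })
}

test_that("every family separates a separable fixture and trains reproducibly", {
  fx <- separable_fixture()
  probe <- separable_fixture(n = 24, seed = 77)
  for (fam in c("support_vector_machine", "logistic_regression", "random_forest")) {
    fit <- nyha_train(classifier_spec(fam, seed = 3), fx$x, fx$y)
    expect_identical(mean(predict(fit, fx$x) == fx$y), 1, info = fam)
    fit2 <- nyha_train(classifier_spec(fam, seed = 3), fx$x, fx$y)
    expect_identical(predict(fit, probe$x), predict(fit2, probe$x), info = fam)
  }
})

test_that("training contracts are enforced", {
  fx <- separable_fixture()
  expect_error(nyha_train(classifier_spec("rf"), fx$x, fx$y[-1]), "labels length")
  expect_error(nyha_train(classifier_spec("rf"), fx$x[1:12, ], rep(2L, 12)),
               "missing classes: 1, 3, 4")
})

test_that("cross-validation folds are stratified, exhaustive and conserved", {
  fx <- separable_fixture(n = 100, seed = 2)
  cv <- cross_validate(classifier_spec("lr", seed = 4), fx$x, fx$y, folds = 10)
  expect_identical(as.integer(table(cv$fold_assignments)), rep(10L, 10))
  # each class spread across folds
  expect_true(all(table(fx$y, cv$fold_assignments) <= 4))
  expect_identical(sum(cv$pooled$confusion), 100L)
  expect_identical(length(cv$fold_reports), 10L)
  expect_error(cross_validate(classifier_spec("lr"), fx$x[1:5, ], fx$y[1:5], folds = 10),
               "cannot run")
})

test_that("planted signal beats a permuted-label baseline under cross-validation", {
  fx <- separable_fixture(n = 80, seed = 6)
  spec <- classifier_spec("rf", hyperparameters = list(num_trees = 100L), seed = 8)
  cv <- cross_validate(spec, fx$x, fx$y, folds = 5)
  perm <- withr::with_seed(99, sample(fx$y))
  cv_perm <- cross_validate(spec, fx$x, perm, folds = 5)
  expect_gt(cv$pooled$overall_f_macro, cv_perm$pooled$overall_f_macro)
  expect_gt(cv$pooled$overall_f_macro, 0.9)
})

test_that("evaluation handles abstentions and perfect predictions", {
  ev <- evaluate(c(1L, 2L, 2L, NA), c(1L, 2L, 3L, 4L))
  expect_identical(sum(ev$confusion) + sum(ev$abstained), 4L)
  expect_identical(ev$abstained, c(0L, 0L, 0L, 1L))
  expect_identical(ev$per_class$recall, c(1, 1, 0, 0))
  expect_identical(ev$per_class$precision[2], 0.5)

  perfect <- evaluate(rep(1:4, 3), rep(1:4, 3))
  expect_identical(unname(diag(perfect$confusion)), rep(3L, 4))
  expect_identical(perfect$overall_f_macro, 1)
  expect_identical(perfect$overall_f_harmonic, 1)
  expect_error(evaluate(1:3, 1:4), "differ in length")
})

test_that("macro-averaging helper reduces per-class values on any scale", {
  out <- macro_overall(c(80, 90, 100, 70), c(60, 80, 100, 40))
  expect_equal(out$macro_precision, 85)
  expect_equal(out$macro_recall, 70)
  expect_equal(out$f_harmonic, 2 * 85 * 70 / 155)
  expect_equal(macro_overall(c(1, 1), c(1, 1), c(0.5, 0.7))$f_macro, 0.6)
})

test_that("feature reports rank a planted discriminative bigram at the top", {
  # class-2 notes always contain "nyha class ii"; others carry fillers
  withr::with_seed(10, {
    mk <- function(lab) {
      base <- sample(c("stable", "chf", "follow", "up", "clinic", "med"), 6, replace = TRUE)
      if (lab == 2) c(base[1:2], "nyha", "class", "ii", base[3:6])
      else c(base, sample(c("nyha", "chart"), 1))
    }
    labs <- rep(c(1L, 2L), each = 30)
    docs <- lapply(labs, mk)
  })
  v <- fit_vocabulary(docs, pipeline_config(feature_set = "ngram", prune_percentile = 0))
  x <- vectorize(docs, v)
  fit <- nyha_train(classifier_spec("rf", hyperparameters = list(num_trees = 200L), seed = 2),
                    x, labs)
  rep5 <- feature_report(fit, v, top_k = 5)
  expect_true("nyha class ii" %in% rep5$term)
  full <- feature_report(fit, v, top_k = Inf)
  expect_identical(nrow(full), length(v$terms))
  expect_true(all(diff(full$score) <= 0))
  # linear families expose coefficients too
  fit_lr <- nyha_train(classifier_spec("lr", seed = 2), x, labs)
  expect_true("nyha class ii" %in% feature_report(fit_lr, v, top_k = 5)$term)
})
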