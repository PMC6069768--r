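test_that("tokenization lowercases, strips stopwords and keeps codes intact", {
  cfg <- pipeline_config(stopwords = "of")
  expect_identical(tokenize_normalize("NYHA Class II of record", cfg),
                   c("nyha", "class", "ii", "record"))
  expect_identical(tokenize_normalize("", cfg), character())
  expect_identical(tokenize_normalize("ICD 428.0 recorded", pipeline_config())[2], "428.0")
  # inflectional variants collapse to one canonical form
  norm <- pipeline_config()$normalizer
  expect_identical(norm("dyspneic"), norm("dyspnea"))
  expect_identical(norm("symptoms"), "symptom")
  expect_identical(norm("classes"), "class")
  expect_identical(norm("class"), "class")
})

test_that("n-gram formation yields exactly the contiguous windows", {
  cfg <- pipeline_config(feature_set = "ngram", ngram_min = 2, ngram_max = 2,
                         prune_percentile = 0)
  v <- fit_vocabulary(list(c("nyha", "class", "ii")), cfg)
  expect_setequal(v$terms, c("nyha class", "class ii"))
  # count identity: length L contributes max(L - n + 1, 0) n-grams per n
  withr::with_seed(8, {
    for (i in 1:20) {
      L <- sample(0:12, 1)
      toks <- sample(letters, L, replace = TRUE)
      nmin <- sample(1:3, 1); nmax <- nmin + sample(0:3, 1)
      got <- length(nyhaclass:::make_ngrams(toks, nmin, nmax))
      want <- sum(pmax(L - (nmin:nmax) + 1, 0))
      expect_identical(got, as.integer(want))
    }
  })
})

test_that("frequency pruning matches a brute-force quantile oracle", {
  toks <- c(rep(paste0("t", 1:99), each = 5), "rare")
  cfg <- pipeline_config(feature_set = "bow", prune_percentile = 0.01)
  v <- fit_vocabulary(list(toks), cfg)
  expect_identical(length(v$terms), 99L)
  expect_false("rare" %in% v$terms)
  # oracle: inverse-ECDF quantile, drop everything at or below it
  freqs <- table(toks)
  thr <- sort(as.integer(freqs))[ceiling(0.01 * length(freqs))]
  expect_setequal(v$terms, names(freqs)[as.integer(freqs) > thr])
  # zero percentile keeps everything
  v0 <- fit_vocabulary(list(toks), pipeline_config(prune_percentile = 0))
  expect_identical(length(v0$terms), 100L)
  # pruning monotonicity: a larger cut never grows the vocabulary
  docs <- withr::with_seed(21, replicate(40, sample(paste0("w", 1:30),
                            sample(3:15, 1), replace = TRUE), simplify = FALSE))
  prev <- NULL
  for (p in c(0, 0.05, 0.2, 0.5)) {
    vv <- fit_vocabulary(docs, pipeline_config(prune_percentile = p))
    if (!is.null(prev)) expect_true(all(vv$terms %in% prev))
    prev <- vv$terms
  }
  expect_error(fit_vocabulary(list(), cfg), "empty")
})

test_that("vectorization counts conserve vocabulary frequencies", {
  docs <- withr::with_seed(5, replicate(30, sample(c("nyha", "class", "ii", "iii", "chf", "stable"),
                            sample(2:10, 1), replace = TRUE), simplify = FALSE))
  for (fs in c("bow", "ngram")) {
    v <- fit_vocabulary(docs, pipeline_config(feature_set = fs, prune_percentile = 0))
    x <- vectorize(docs, v)
    expect_identical(as.integer(Matrix::colSums(x)), as.integer(v$frequencies))
    # refitting is byte-identical
    v2 <- fit_vocabulary(docs, pipeline_config(feature_set = fs, prune_percentile = 0))
    expect_identical(v$terms, v2$terms)
  }
  # out-of-vocabulary-only notes keep a flagged all-zero row
  v <- fit_vocabulary(docs, pipeline_config(feature_set = "bow", prune_percentile = 0))
  x <- vectorize(list(c("nyha", "nyha", "nyha"), c("unseen", "words")), v)
  expect_identical(as.integer(x[1, "nyha"]), 3L)
  expect_identical(as.integer(Matrix::rowSums(x)[2]), 0L)
  expect_identical(attr(x, "zero_rows"), 2L)
})

test_that("vocabularies and feature matrices round-trip through CSV and MTX", {
  docs <- list(c("nyha", "class", "ii"), c("chf", "stable", "nyha", "class", "iii"))
  v <- fit_vocabulary(docs, pipeline_config(feature_set = "ngram", ngram_min = 2,
                                            ngram_max = 3, prune_percentile = 0))
  vp <- withr::local_tempfile(fileext = ".csv")
  write_vocabulary(v, vp)
  v2 <- read_vocabulary(vp)
  expect_identical(v2$terms, v$terms)
  expect_identical(unname(v2$frequencies), unname(as.integer(v$frequencies)))
  expect_identical(v2$config$feature_set, "ngram")

  x <- vectorize(docs, v)
  fp <- withr::local_tempfile(fileext = ".mtx")
  write_features(x, fp)
  x2 <- read_features(fp)
  expect_identical(as.matrix(x2), as.matrix(x))
  # the re-read vocabulary featurizes identically
  expect_identical(as.matrix(vectorize(docs, v2)), as.matrix(x))
})
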