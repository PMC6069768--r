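#' Classifier specification
#'
#' Describes one of the three classifier families used for NYHA text
#' classification, with its hyperparameters and seed. Defaults: a linear-
#' kernel support vector machine (cost 1, one-vs-rest for multi-class), an
#' L2-regularized (ridge) multinomial logistic regression (`lambda` 0.01),
#' and a 500-tree random forest.
#'
#' @param family `"random_forest"`, `"support_vector_machine"` or
#'   `"logistic_regression"` (aliases `"rf"`, `"svm"`, `"lr"` accepted).
#' @param hyperparameters named list overriding the family defaults
#'   (`cost` for the SVM; `lambda`, `alpha` for logistic regression;
#'   `num_trees`, `mtry` for the random forest).
#' @param seed integer seed fixing any stochastic component of training.
#' @return an object of class `nyha_classifier_spec`.
#' @export
classifier_spec <- function(family = c("random_forest", "support_vector_machine",
                                       "logistic_regression", "rf", "svm", "lr"),
                            hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  family <- switch(family, rf = "random_forest", svm = "support_vector_machine",
                   lr = "logistic_regression", family)
  defaults <- switch(family,
    support_vector_machine = list(cost = 1),
    logistic_regression = list(lambda = 0.01, alpha = 0),
    random_forest = list(num_trees = 500L, mtry = NULL)
  )
  structure(list(family = family,
                 hyperparameters = .merge_defaults(hyperparameters, defaults),
                 seed = as.integer(seed)),
            class = "nyha_classifier_spec")
}

.as_dgc <- function(x) {
  if (inherits(x, "CsparseMatrix")) x else Matrix::Matrix(as.matrix(x), sparse = TRUE)
}

# dense copy with guaranteed column names (ranger requires named predictors)
.named_dense <- function(x) {
  xd <- as.matrix(x)
  if (is.null(colnames(xd))) colnames(xd) <- paste0("f", seq_len(ncol(xd)))
  xd
}

#' Train a multi-class NYHA classifier
#'
#' Fits the family named in `spec` on a feature matrix and integer class
#' labels (1..4). Multi-class handling for the binary-native SVM is
#' one-vs-rest over linear-kernel machines; logistic regression is a
#' multinomial ridge fit; the random forest is grown single-threaded with a
#' fixed seed, so training is reproducible.
#'
#' @param spec a [classifier_spec()].
#' @param x feature matrix (sparse or dense), notes in rows.
#' @param labels integer NYHA classes aligned 1:1 with the rows of `x`; at
#'   least two distinct classes must be present.
#' @return an object of class `nyha_classifier`.
#' @export
nyha_train <- function(spec, x, labels) {
  stopifnot(inherits(spec, "nyha_classifier_spec"))
  labels <- as.integer(labels)
  if (nrow(x) != length(labels)) {
    .stop_contract("labels length (%d) must equal the number of feature rows (%d)",
                   length(labels), nrow(x))
  }
  present <- sort(unique(labels))
  if (length(present) < 2L) {
    .stop_contract("training set contains a single class (%s); missing classes: %s",
                   paste(present, collapse = ","),
                   paste(setdiff(1:4, present), collapse = ", "))
  }
  hp <- spec$hyperparameters
  y <- factor(labels, levels = present)
  fit <- switch(spec$family,
    support_vector_machine = {
      xd <- .named_dense(x)
      withr::with_seed(spec$seed, lapply(present, function(k) {
        yk <- factor(ifelse(labels == k, "pos", "rest"), levels = c("pos", "rest"))
        e1071::svm(xd, yk, kernel = "linear", cost = hp$cost, scale = FALSE)
      }))
    },
    logistic_regression = {
      xs <- .as_dgc(x)
      if (ncol(xs) < 2L) .stop_contract("logistic regression needs at least two features")
      withr::with_seed(spec$seed,
        glmnet::glmnet(xs, y, family = "multinomial",
                       alpha = hp$alpha, lambda = hp$lambda))
    },
    random_forest = {
      args <- list(x = .named_dense(x), y = y, num.trees = hp$num_trees,
                   seed = spec$seed, num.threads = 1L, importance = "impurity",
                   verbose = FALSE)
      if (!is.null(hp$mtry)) args$mtry <- hp$mtry
      # ranger consults the R RNG beyond its seed argument; pin the state too
      withr::with_seed(spec$seed, do.call(ranger::ranger, args))
    }
  )
  structure(list(spec = spec, family = spec$family, fit = fit,
                 classes = present, feature_names = colnames(x)),
            class = "nyha_classifier")
}

#' @export
print.nyha_classifier <- function(x, ...) {
  cat(sprintf("NYHA classifier: %s on %d features, classes {%s}\n",
              x$family, length(x$feature_names %||% character()),
              paste(x$classes, collapse = ",")))
  invisible(x)
}

#' @rdname nyha_train
#' @param object a fitted `nyha_classifier`.
#' @param newdata feature matrix vectorized against the same vocabulary.
#' @param ... unused.
#' @return `predict()`: integer vector of NYHA classes.
#' @export
predict.nyha_classifier <- function(object, newdata, ...) {
  switch(object$family,
    support_vector_machine = {
      xd <- .named_dense(newdata)
      dv <- vapply(object$fit, function(m) {
        p <- predict(m, xd, decision.values = TRUE)
        d <- attr(p, "decision.values")
        v <- d[, 1]
        if (identical(colnames(d), "rest/pos")) -v else v
      }, numeric(nrow(xd)))
      dv <- matrix(dv, nrow = nrow(xd))
      object$classes[max.col(dv, ties.method = "first")]
    },
    logistic_regression = {
      p <- predict(object$fit, .as_dgc(newdata), type = "class",
                   s = object$spec$hyperparameters$lambda)
      as.integer(p)
    },
    random_forest = {
      p <- withr::with_seed(object$spec$seed,
        predict(object$fit, data = .named_dense(newdata), num.threads = 1L,
                verbose = FALSE)$predictions)
      as.integer(as.character(p))
    }
  )
}

# stratified fold assignment: within each class, indices are shuffled and
# dealt cyclically, the deal continuing across classes so overall fold sizes
# stay balanced
.stratified_folds <- function(labels, folds, seed) {
  n <- length(labels)
  fold_of <- integer(n)
  withr::with_seed(seed, {
    counter <- 0L
    for (cl_idx in split(seq_len(n), labels)) {
      cl_idx <- if (length(cl_idx) > 1L) sample(cl_idx) else cl_idx
      fold_of[cl_idx] <- ((counter + seq_along(cl_idx) - 1L) %% folds) + 1L
      counter <- counter + length(cl_idx)
    }
  })
  fold_of
}

#' Stratified k-fold cross-validation
#'
#' Splits the notes into `folds` seeded, class-stratified folds; each note is
#' scored exactly once by a model trained on the remaining folds. Returns the
#' per-fold evaluation reports and the pooled report computed from the union
#' of out-of-fold predictions.
#'
#' @inheritParams nyha_train
#' @param folds number of folds (default 10; must not exceed the number of
#'   notes).
#' @param seed seed for the fold assignment (defaults to the spec seed).
#' @return an object of class `nyha_cv`: list with `fold_reports`, `pooled`
#'   (an [evaluate()] report), `predictions` and `fold_assignments`.
#' @export
cross_validate <- function(spec, x, labels, folds = 10L, seed = spec$seed) {
  labels <- as.integer(labels)
  folds <- as.integer(folds)
  if (folds < 2L) .stop_contract("cross_validate() needs at least 2 folds")
  n <- length(labels)
  if (n < folds) .stop_contract("cannot run %d-fold cross-validation on %d notes", folds, n)
  if (nrow(x) != n) .stop_contract("labels length must equal the number of feature rows")
  fold_of <- .stratified_folds(labels, folds, seed)
  preds <- rep(NA_integer_, n)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    fit <- nyha_train(spec, x[tr, , drop = FALSE], labels[tr])
    preds[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  fold_reports <- lapply(seq_len(folds), function(f) {
    te <- fold_of == f
    evaluate(preds[te], labels[te])
  })
  structure(list(fold_reports = fold_reports,
                 pooled = evaluate(preds, labels),
                 predictions = preds,
                 fold_assignments = fold_of),
            class = "nyha_cv")
}

#' @export
print.nyha_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, pooled report:\n", length(x$fold_reports)))
  print(x$pooled)
  invisible(x)
}

#' Multi-class evaluation report
#'
#' Compares predictions against gold NYHA classes. Per class c, precision is
#' TP/(TP+FP) over notes predicted c and recall is TP/(TP+FN) over notes with
#' gold c; an absent (`NA`) prediction — a rule-based abstention — counts as
#' a false negative for its gold class and as a prediction of no class.
#' Overall (macro) precision and recall are unweighted means of the four
#' per-class values. Because "overall F" is used in two senses in practice,
#' both are reported: `overall_f_macro`, the unweighted mean of per-class F,
#' and `overall_f_harmonic`, the harmonic mean of macro precision and macro
#' recall.
#'
#' @param predictions integer NYHA classes, `NA` allowed (abstention).
#' @param gold integer NYHA classes in 1..4, same length.
#' @return an object of class `nyha_eval`: list with `confusion` (4x4 gold x
#'   predicted counts), `abstained` (per-gold-class abstention counts),
#'   `per_class` (precision/recall/F data frame), `overall_macro_p`,
#'   `overall_macro_r`, `overall_f_macro`, `overall_f_harmonic`, `n`.
#' @examples
#' evaluate(c(1, 2, 2, NA), c(1, 2, 3, 4))
#' @export
evaluate <- function(predictions, gold) {
  if (length(predictions) != length(gold)) {
    .stop_contract("predictions (%d) and gold (%d) differ in length",
                   length(predictions), length(gold))
  }
  gold <- as.integer(gold)
  pred <- as.integer(predictions)
  conf <- table(gold = factor(gold, levels = 1:4),
                predicted = factor(pred, levels = 1:4))
  conf <- unclass(conf)
  abst <- as.integer(table(factor(gold[is.na(pred)], levels = 1:4)))
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp + abst
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f <- ifelse(is.na(precision) | is.na(recall), NA_real_,
              ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0))
  mp <- mean(precision, na.rm = TRUE)
  mr <- mean(recall, na.rm = TRUE)
  structure(list(
    confusion = conf,
    abstained = abst,
    per_class = data.frame(class = 1:4, precision = as.numeric(precision),
                           recall = as.numeric(recall), f_measure = as.numeric(f)),
    overall_macro_p = mp,
    overall_macro_r = mr,
    overall_f_macro = mean(f, na.rm = TRUE),
    overall_f_harmonic = if (isTRUE(mp + mr > 0)) 2 * mp * mr / (mp + mr) else 0,
    n = length(gold)
  ), class = "nyha_eval")
}

#' @export
print.nyha_eval <- function(x, ...) {
  pc <- x$per_class
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f%%", 100 * v))
  tab <- data.frame(NYHA = .ROMAN,
                    Precision = fmt(pc$precision),
                    Recall = fmt(pc$recall),
                    `F-Measure` = fmt(pc$f_measure),
                    check.names = FALSE)
  tab <- rbind(tab, data.frame(NYHA = "Overall",
                               Precision = fmt(x$overall_macro_p),
                               Recall = fmt(x$overall_macro_r),
                               `F-Measure` = fmt(x$overall_f_macro),
                               check.names = FALSE))
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("overall F (harmonic of macro P/R): %s; n = %d; abstentions = %d\n",
              fmt(x$overall_f_harmonic), x$n, sum(x$abstained)))
  invisible(x)
}

#' Macro-average per-class metric values
#'
#' The macro-averaging arithmetic behind the report's "Overall" row, exposed
#' directly so that per-class precision/recall/F values (on any scale, e.g.
#' percent) can be reduced to overall values: macro precision and recall are
#' unweighted means, `f_harmonic` is the harmonic mean of the two macros,
#' and `f_macro` is the unweighted mean of the per-class F values.
#'
#' @param precision,recall numeric per-class values.
#' @param f_measure optional numeric per-class F values.
#' @return list with `macro_precision`, `macro_recall`, `f_harmonic`, and
#'   (when `f_measure` is given) `f_macro`.
#' @examples
#' macro_overall(c(95.07, 95.72, 94.34, 94.83), c(97.39, 97.10, 95.07, 78.95))
#' @export
macro_overall <- function(precision, recall, f_measure = NULL) {
  mp <- mean(precision)
  mr <- mean(recall)
  out <- list(macro_precision = mp, macro_recall = mr,
              f_harmonic = 2 * mp * mr / (mp + mr))
  if (!is.null(f_measure)) out$f_macro <- mean(f_measure)
  out
}

#' Ranked feature-importance report
#'
#' Ranks features by importance: impurity importance for the random forest,
#' the maximum absolute per-class coefficient for the linear families (ridge
#' multinomial coefficients; one-vs-rest hyperplane weights for the SVM).
#'
#' @param model a fitted [nyha_train()] classifier.
#' @param vocabulary optional [fit_vocabulary()] object supplying term names
#'   (defaults to the model's stored feature names).
#' @param top_k number of features to return (the full ranking if larger
#'   than the vocabulary).
#' @return data frame with columns `rank`, `term`, `score`, scores
#'   non-increasing.
#' @export
feature_report <- function(model, vocabulary = NULL, top_k = Inf) {
  stopifnot(inherits(model, "nyha_classifier"))
  terms <- if (!is.null(vocabulary)) vocabulary$terms else model$feature_names
  score <- switch(model$family,
    random_forest = {
      imp <- ranger::importance(model$fit)
      as.numeric(imp)
    },
    logistic_regression = {
      cf <- stats::coef(model$fit, s = model$spec$hyperparameters$lambda)
      mat <- vapply(cf, function(m) as.numeric(m)[-1], numeric(length(terms)))
      apply(abs(matrix(mat, ncol = length(cf))), 1, max)
    },
    support_vector_machine = {
      ws <- vapply(model$fit, function(m) as.numeric(Matrix::crossprod(m$coefs, m$SV)),
                   numeric(length(terms)))
      apply(abs(matrix(ws, ncol = length(model$fit))), 1, max)
    },
    .stop_contract("model family '%s' does not expose feature importances", model$family)
  )
  if (is.null(terms)) terms <- as.character(seq_along(score))
  ord <- order(-score, terms)
  k <- min(top_k, length(score))
  data.frame(rank = seq_len(k), term = terms[ord][seq_len(k)],
             score = score[ord][seq_len(k)], stringsAsFactors = FALSE)
}
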