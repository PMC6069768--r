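#' Full-run configuration
#'
#' Bundles the configuration of every stage of the workflow (simulate or
#' load, map codes, build the reference corpus, split, rule-based
#' classification, featurization, model training and evaluation) under one
#' global seed. Every stochastic stage derives its own seed deterministically
#' from `global_seed`, so a run is fully reproducible from its config.
#'
#' @param global_seed integer master seed.
#' @param simulate a [generator_config()] to generate inputs, or `NULL` to
#'   read them from `notes_path` / `encounters_path`.
#' @param notes_path,encounters_path input files (JSONL notes, CSV
#'   encounters) when not simulating.
#' @param rule a [rule_config()].
#' @param test_fraction,stratify corpus split parameters (see
#'   [split_corpus()]).
#' @param families classifier families to train (see [classifier_spec()]).
#' @param feature_sets feature sets to build (`"bow"`, `"ngram"`).
#' @param ngram_range inclusive n-gram range for the `"ngram"` feature set.
#' @param folds if >= 2, also run this many cross-validation folds on the
#'   training set for each family/feature set; 0 skips cross-validation.
#' @return a list of class `nyha_run_config`.
#' @export
run_config <- function(global_seed = 1L,
                       simulate = generator_config(seed = global_seed + 101L),
                       notes_path = NULL, encounters_path = NULL,
                       rule = rule_config(),
                       test_fraction = 2474 / 6174, stratify = FALSE,
                       families = "random_forest",
                       feature_sets = c("bow", "ngram"),
                       ngram_range = c(2L, 5L),
                       folds = 0L) {
  structure(list(global_seed = as.integer(global_seed), simulate = simulate,
                 notes_path = notes_path, encounters_path = encounters_path,
                 rule = rule, test_fraction = test_fraction,
                 stratify = isTRUE(stratify), families = families,
                 feature_sets = match.arg(feature_sets, several.ok = TRUE),
                 ngram_range = as.integer(ngram_range), folds = as.integer(folds)),
            class = "nyha_run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields of the YAML document override the [run_config()] defaults;
#' nested `simulate` and `rule` blocks override the corresponding
#' constructor defaults field by field.
#'
#' @param path YAML file path.
#' @return a `nyha_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$global_seed %||% 1L)
  sim <- if (isFALSE(y$simulate)) NULL else {
    do.call(generator_config, .merge_defaults(
      y$simulate %||% list(),
      list(seed = seed + 101L)))
  }
  rule <- do.call(rule_config, y$rule %||% list())
  run_config(global_seed = seed, simulate = sim,
             notes_path = y$notes_path, encounters_path = y$encounters_path,
             rule = rule,
             test_fraction = y$test_fraction %||% (2474 / 6174),
             stratify = y$stratify %||% FALSE,
             families = y$families %||% "random_forest",
             feature_sets = y$feature_sets %||% c("bow", "ngram"),
             ngram_range = y$ngram_range %||% c(2L, 5L),
             folds = y$folds %||% 0L)
}

.eval_to_df <- function(ev, ...) {
  lab <- data.frame(..., stringsAsFactors = FALSE)
  pc <- ev$per_class
  rows <- cbind(lab[rep(1, 5), , drop = FALSE],
                data.frame(class = c(.ROMAN, "Overall"),
                           precision = c(pc$precision, ev$overall_macro_p),
                           recall = c(pc$recall, ev$overall_macro_r),
                           f_measure = c(pc$f_measure, ev$overall_f_macro),
                           stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}

#' Run the full NYHA identification workflow
#'
#' Executes the complete pipeline into a run directory: obtain notes and
#' encounters (simulated or loaded), build the code-mapping table, construct
#' and split the labelled reference corpus, score the held-out notes with the
#' rule-based extractor, build bag-of-words / n-gram features, train and
#' evaluate the configured classifier families, and write every artifact
#' (JSONL/CSV/MTX) plus a run manifest with the config fingerprint and
#' record counts at each stage. Progress is narrated via `message()` with
#' the record counts that make the funnel auditable. Re-running the same
#' config into a fresh directory reproduces all reports.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the split, evaluation reports and artifact
#'   paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "nyha_run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s0 <- config$global_seed

  if (!is.null(config$simulate)) {
    corp <- generate_corpus(config$simulate)
    notes <- corp$notes
    encounters <- corp$encounters
    say("simulated %d notes for %d patients", nrow(notes), length(unique(notes$patient_id)))
  } else {
    if (is.null(config$notes_path) || is.null(config$encounters_path)) {
      .stop_contract("run_pipeline(): either enable simulation or provide notes_path and encounters_path")
    }
    notes <- read_notes(config$notes_path)
    encounters <- read_encounters(config$encounters_path, format = "csv")
    say("read %d notes and %d encounter rows", nrow(notes), nrow(encounters))
  }
  write_notes(notes, file.path(out_dir, "notes.jsonl"))
  write_encounters(encounters, file.path(out_dir, "encounters.csv"), format = "csv")

  cohort <- filter_hf_cohort(encounters)
  say("heart-failure cohort: %d patients", length(cohort))

  code_table <- build_code_table(encounters, config = config$rule)
  say("code table: %d distinct codes, %d mapped to an NYHA class",
      nrow(code_table), attr(code_table, "n_mapped"))
  utils::write.csv(as.data.frame(code_table), file.path(out_dir, "code_map.csv"),
                   row.names = FALSE)

  labeled <- match_notes_to_codes(notes, code_table, encounters)
  say("reference corpus: %d labelled notes (%d conflicts excluded, %d unmatched)",
      nrow(labeled), nrow(attr(labeled, "conflicts")), attr(labeled, "n_unmatched"))
  write_notes(labeled[NOTE_FIELDS], file.path(out_dir, "labeled_notes.jsonl"))
  utils::write.csv(data.frame(labeled), file.path(out_dir, "labeled.csv"), row.names = FALSE)

  split <- split_corpus(labeled, config$test_fraction, seed = s0 + 202L,
                        stratify = config$stratify)
  summ <- corpus_summary(split)
  say("split: %d training / %d testing notes", nrow(split$train), nrow(split$test))
  utils::write.csv(as.data.frame(summ), file.path(out_dir, "corpus_summary.csv"),
                   row.names = FALSE)

  # rule-based scoring of the held-out notes
  rule_pred <- vapply(split$test$text, classify_note_rule, integer(1),
                      config = config$rule, USE.NAMES = FALSE)
  rule_eval <- evaluate(rule_pred, split$test$gold)
  say("rule-based overall macro F on test: %.4f", rule_eval$overall_f_macro)
  utils::write.csv(.eval_to_df(rule_eval, method = "rule_based", feature_set = "-"),
                   file.path(out_dir, "rule_report.csv"), row.names = FALSE)

  # machine-learning track
  tr_tok <- lapply(split$train$text, tokenize_normalize)
  te_tok <- lapply(split$test$text, tokenize_normalize)
  ml_rows <- list(); cv_rows <- list(); evals <- list()
  for (fs in config$feature_sets) {
    pcfg <- pipeline_config(feature_set = fs,
                            ngram_min = config$ngram_range[1],
                            ngram_max = config$ngram_range[2])
    vocab <- fit_vocabulary(tr_tok, pcfg)
    xtr <- vectorize(tr_tok, vocab)
    xte <- vectorize(te_tok, vocab)
    say("%s features: %d terms", fs, length(vocab$terms))
    write_vocabulary(vocab, file.path(out_dir, paste0("vocabulary_", fs, ".csv")))
    write_features(xtr, file.path(out_dir, paste0("features_train_", fs, ".mtx")))
    for (fam in config$families) {
      spec <- classifier_spec(fam, seed = s0 + 303L)
      fit <- nyha_train(spec, xtr, split$train$gold)
      ev <- evaluate(predict(fit, xte), split$test$gold)
      say("%s / %s overall macro F on test: %.4f", spec$family, fs, ev$overall_f_macro)
      ml_rows[[paste(fam, fs)]] <- .eval_to_df(ev, method = spec$family, feature_set = fs)
      evals[[paste(fam, fs)]] <- ev
      if (config$folds >= 2L) {
        cv <- cross_validate(spec, xtr, split$train$gold, folds = config$folds,
                             seed = s0 + 404L)
        cv_rows[[paste(fam, fs)]] <- .eval_to_df(cv$pooled, method = spec$family,
                                                 feature_set = fs)
      }
    }
  }
  utils::write.csv(do.call(rbind, ml_rows), file.path(out_dir, "ml_report.csv"),
                   row.names = FALSE)
  if (length(cv_rows)) {
    utils::write.csv(do.call(rbind, cv_rows), file.path(out_dir, "cv_report.csv"),
                     row.names = FALSE)
  }

  # manifest: config fingerprint + stage counts
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(.config_for_manifest(config), cfg_path)
  manifest <- list(
    package = "nyhaclass",
    version = as.character(utils::packageVersion("nyhaclass")),
    global_seed = s0,
    config_md5 = unname(tools::md5sum(cfg_path)),
    counts = list(notes = nrow(notes), encounter_rows = nrow(encounters),
                  hf_patients = length(cohort),
                  codes = nrow(code_table), codes_mapped = attr(code_table, "n_mapped"),
                  labeled = nrow(labeled),
                  conflicts = nrow(attr(labeled, "conflicts")),
                  train = nrow(split$train), test = nrow(split$test))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(split = split, rule_eval = rule_eval, ml_evals = evals,
                 out_dir = out_dir))
}

# serializable view of the config (drops function members)
.config_for_manifest <- function(config) {
  sim <- config$simulate
  list(
    global_seed = config$global_seed,
    simulate = if (is.null(sim)) NULL else list(
      n_patients = sim$n_patients,
      notes_per_patient = sim$notes_per_patient,
      class_distribution = as.numeric(sim$class_distribution),
      mention_style_mix = as.list(sim$mention_style_mix),
      trigger_mix = as.list(sim$trigger_mix),
      label_noise = sim$label_noise,
      seed = sim$seed),
    notes_path = config$notes_path,
    encounters_path = config$encounters_path,
    rule = list(window_chars = config$rule$window_chars,
                allow_pairs = config$rule$allow_pairs,
                pair_separators = config$rule$pair_separators,
                roman_case = config$rule$roman_case,
                pair_policy = config$rule$pair_policy,
                mention_policy = config$rule$mention_policy),
    test_fraction = config$test_fraction,
    stratify = config$stratify,
    families = config$families,
    feature_sets = config$feature_sets,
    ngram_range = config$ngram_range,
    folds = config$folds
  )
}
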