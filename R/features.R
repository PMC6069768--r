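#' Default English stopword list
#'
#' A standard English function-word list (the usual snowball-style set,
#' including "of" and "as"). The single-letter pronoun "i" is deliberately
#' not on the list: it is indistinguishable from the Roman numeral for NYHA
#' class I after lower-casing, and removing it would erase the class-I marker
#' from every feature set.
#'
#' @return character vector of lower-case word forms.
#' @export
nyha_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "aren't", "as", "at", "be", "because", "been",
    "before", "being", "below", "between", "both", "but", "by", "can't",
    "cannot", "could", "couldn't", "did", "didn't", "do", "does", "doesn't",
    "doing", "don't", "down", "during", "each", "few", "for", "from",
    "further", "had", "hadn't", "has", "hasn't", "have", "haven't", "having",
    "he", "her", "here", "hers", "herself", "him", "himself", "his", "how",
    "if", "in", "into", "is", "isn't", "it", "its", "itself", "let's", "me",
    "more", "most", "mustn't", "my", "myself", "no", "nor", "not", "of",
    "off", "on", "once", "only", "or", "other", "ought", "our", "ours",
    "ourselves", "out", "over", "own", "same", "shan't", "she", "should",
    "shouldn't", "so", "some", "such", "than", "that", "the", "their",
    "theirs", "them", "themselves", "then", "there", "these", "they", "this",
    "those", "through", "to", "too", "under", "until", "up", "very", "was",
    "wasn't", "we", "were", "weren't", "what", "when", "where", "which",
    "while", "who", "whom", "why", "with", "won't", "would", "wouldn't",
    "you", "your", "yours", "yourself", "yourselves")
}

#' Default lexical normalizer
#'
#' Collapses common inflectional variants to a canonical form with a small
#' ordered set of suffix rules (plural stripping, "-ies"/"-sses" endings,
#' "-ing"/"-ed" inflections, and the "-eic" to "-ea" adjectival family so
#' that "dyspneic" and "dyspnea" share one form). Tokens containing digits
#' are left untouched, so codes such as "428.0" survive as single tokens.
#' Any function mapping a character vector of tokens to a character vector
#' of the same length can be plugged in instead via
#' [pipeline_config()]'s `normalizer`.
#'
#' @param tokens character vector of lower-case tokens.
#' @return character vector of canonical token forms.
#' @examples
#' default_normalizer(c("symptoms", "dyspneic", "dyspnea", "classes", "nyha"))
#' @export
default_normalizer <- function(tokens) {
  vapply(tokens, function(w) {
    if (!grepl("^[a-z]+$", w)) return(w)
    if (grepl("eic$", w)) return(sub("eic$", "ea", w))
    if (grepl("sses$", w)) return(sub("es$", "", w))
    if (grepl("ies$", w) && nchar(w) >= 5L) return(sub("ies$", "y", w))
    if (grepl("[a-z]s$", w) && !grepl("(ss|us|is)$", w) && nchar(w) >= 4L) return(sub("s$", "", w))
    if (grepl("ing$", w) && nchar(w) >= 6L) return(sub("ing$", "", w))
    if (grepl("ed$", w) && nchar(w) >= 6L) return(sub("ed$", "", w))
    w
  }, character(1), USE.NAMES = FALSE)
}

#' Featurization pipeline configuration
#'
#' @param stopwords set of word forms removed before feature formation.
#' @param prune_percentile terms in the lowest `prune_percentile` of the
#'   corpus term-frequency distribution are discarded (default 0.01, i.e. the
#'   least frequently used 1 percent; 0 disables pruning).
#' @param feature_set `"bow"` (unigram bag-of-words) or `"ngram"`
#'   (contiguous n-grams, space-joined).
#' @param ngram_min,ngram_max inclusive n-gram range (defaults 2 and 5).
#' @param lowercase lower-case text before tokenization (default `TRUE`).
#' @param normalizer pluggable lexical normalizer (see [default_normalizer()]).
#' @param prune_mode `"quantile"` (default): discard every term whose corpus
#'   frequency is at or below the `prune_percentile` frequency quantile (ties
#'   at the threshold are all discarded). `"rank"`: drop the bottom
#'   `prune_percentile` share of distinct terms ranked by frequency.
#' @param weighting feature-matrix cell values: raw `"count"` (default),
#'   `"binary"`, or `"tfidf"`.
#' @return an object of class `nyha_pipeline_config`.
#' @export
pipeline_config <- function(stopwords = nyha_stopwords(),
                            prune_percentile = 0.01,
                            feature_set = c("bow", "ngram"),
                            ngram_min = 2L, ngram_max = 5L,
                            lowercase = TRUE,
                            normalizer = default_normalizer,
                            prune_mode = c("quantile", "rank"),
                            weighting = c("count", "binary", "tfidf")) {
  feature_set <- match.arg(feature_set)
  ngram_min <- as.integer(ngram_min); ngram_max <- as.integer(ngram_max)
  if (!(ngram_min >= 1L && ngram_min <= ngram_max)) {
    .stop_contract("ngram range must satisfy 1 <= ngram_min <= ngram_max")
  }
  if (!(prune_percentile >= 0 && prune_percentile < 1)) {
    .stop_contract("prune_percentile must lie in [0, 1)")
  }
  structure(list(
    stopwords = as.character(stopwords),
    prune_percentile = prune_percentile,
    feature_set = feature_set,
    ngram_min = ngram_min, ngram_max = ngram_max,
    lowercase = isTRUE(lowercase),
    normalizer = normalizer,
    prune_mode = match.arg(prune_mode),
    weighting = match.arg(weighting)
  ), class = "nyha_pipeline_config")
}

#' Tokenize and normalize note text
#'
#' Splits text into word tokens (punctuation split off; decimal codes such as
#' "428.0" kept as single tokens), lower-cases, removes stopwords, then maps
#' each token to its canonical form with the configured normalizer.
#'
#' @param text a character string.
#' @param config a [pipeline_config()].
#' @return character vector of normalized tokens (empty for empty text).
#' @examples
#' tokenize_normalize("NYHA Class II of record")
#' @export
tokenize_normalize <- function(text, config = pipeline_config()) {
  if (length(text) != 1L) .stop_contract("tokenize_normalize() handles one text at a time")
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- regmatches(text, gregexpr("[A-Za-z]+|[0-9]+(?:\\.[0-9]+)?", text))[[1]]
  if (config$lowercase) toks <- tolower(toks)
  toks <- toks[!(toks %in% config$stopwords)]
  if (!length(toks)) return(character())
  config$normalizer(toks)
}

# all contiguous n-grams for n in [nmin, nmax], space-joined; a sequence of
# length L contributes max(L - n + 1, 0) n-grams for each n
make_ngrams <- function(tokens, nmin, nmax) {
  L <- length(tokens)
  out <- vector("list", nmax - nmin + 1L)
  for (n in nmin:nmax) {
    if (L < n) break
    k <- L - n + 1L
    cols <- lapply(seq_len(n) - 1L, function(off) tokens[seq_len(k) + off])
    out[[n - nmin + 1L]] <- do.call(paste, cols)
  }
  unlist(out, use.names = FALSE)
}

.featurize_tokens <- function(tokens, config) {
  if (config$feature_set == "bow") tokens
  else make_ngrams(tokens, config$ngram_min, config$ngram_max)
}

#' Fit a vocabulary on a tokenized corpus
#'
#' Collects the feature terms of the configured feature set (unigrams for
#' bag-of-words, space-joined n-grams otherwise), counts corpus frequencies,
#' and discards the least frequent terms: under the default quantile rule,
#' every term whose corpus frequency is at or below the `prune_percentile`
#' quantile of the term-frequency distribution is removed (ties at the
#' threshold are all removed); `prune_percentile = 0` keeps everything.
#' Term order is fixed at fit time (decreasing frequency, ties alphabetical),
#' so refitting the same corpus with the same configuration is byte-identical.
#'
#' @param corpus_tokens list of token vectors, one per note (see
#'   [tokenize_normalize()]).
#' @param config a [pipeline_config()].
#' @return an object of class `nyha_vocabulary`: list with `terms`,
#'   `frequencies` (named corpus counts, in term order), `doc_freq`,
#'   `n_docs` and the fitting `config`.
#' @export
fit_vocabulary <- function(corpus_tokens, config = pipeline_config()) {
  if (!length(corpus_tokens)) .stop_contract("fit_vocabulary(): the corpus is empty")
  feats <- lapply(corpus_tokens, .featurize_tokens, config = config)
  all_terms <- unlist(feats, use.names = FALSE)
  if (!length(all_terms)) .stop_contract("fit_vocabulary(): no features after preprocessing")
  tf <- table(all_terms)
  freq <- as.integer(tf)
  names(freq) <- names(tf)
  df_tab <- table(unlist(lapply(feats, unique), use.names = FALSE))
  doc_freq <- as.integer(df_tab)[match(names(freq), names(df_tab))]

  keep <- rep(TRUE, length(freq))
  if (config$prune_percentile > 0) {
    if (config$prune_mode == "quantile") {
      thr <- stats::quantile(freq, probs = config$prune_percentile, type = 1, names = FALSE)
      keep <- freq > thr
    } else {
      k <- floor(config$prune_percentile * length(freq))
      if (k > 0) {
        drop_ord <- order(freq, names(freq))
        keep[drop_ord[seq_len(k)]] <- FALSE
      }
    }
  }
  freq <- freq[keep]
  doc_freq <- doc_freq[keep]
  ord <- order(-freq, names(freq))
  structure(list(terms = names(freq)[ord],
                 frequencies = freq[ord],
                 doc_freq = doc_freq[ord],
                 n_docs = length(corpus_tokens),
                 config = config),
            class = "nyha_vocabulary")
}

#' @export
print.nyha_vocabulary <- function(x, ...) {
  cat(sprintf("NYHA %s vocabulary: %d terms fitted on %d notes\n",
              x$config$feature_set, length(x$terms), x$n_docs))
  utils::head(data.frame(term = x$terms, frequency = as.integer(x$frequencies)), 10)
}

#' Vectorize tokenized notes against a fitted vocabulary
#'
#' Counts each vocabulary term per note; out-of-vocabulary terms are ignored.
#' A note with no in-vocabulary terms keeps its all-zero row; such rows are
#' flagged in the `zero_rows` attribute.
#'
#' @param corpus_tokens list of token vectors, one per note.
#' @param vocabulary a fitted [fit_vocabulary()] object.
#' @param ids optional row identifiers.
#' @param weighting overrides the vocabulary config's weighting.
#' @return a sparse `dgCMatrix` (notes x terms) with attribute `zero_rows`.
#' @export
vectorize <- function(corpus_tokens, vocabulary, ids = NULL,
                      weighting = vocabulary$config$weighting) {
  stopifnot(inherits(vocabulary, "nyha_vocabulary"))
  feats <- lapply(corpus_tokens, .featurize_tokens, config = vocabulary$config)
  j <- match(unlist(feats, use.names = FALSE), vocabulary$terms)
  i <- rep.int(seq_along(feats), lengths(feats))
  ok <- !is.na(j)
  ids <- ids %||% as.character(seq_along(feats))
  m <- Matrix::sparseMatrix(i = i[ok], j = j[ok], x = 1,
                            dims = c(length(feats), length(vocabulary$terms)),
                            dimnames = list(ids, vocabulary$terms))
  m <- methods::as(m, "CsparseMatrix")
  if (weighting == "binary") {
    m@x[] <- 1
  } else if (weighting == "tfidf") {
    idf <- log(vocabulary$n_docs / pmax(vocabulary$doc_freq, 1L))
    m <- m %*% Matrix::Diagonal(x = idf)
    dimnames(m) <- list(ids, vocabulary$terms)
    m <- methods::as(m, "CsparseMatrix")
  }
  attr(m, "zero_rows") <- unname(which(Matrix::rowSums(m) == 0))
  m
}

#' Persist vocabularies and feature matrices
#'
#' The vocabulary is written as CSV (`term`, `frequency`, `doc_frequency`,
#' `column_index`) with a JSON sidecar (`<path>.meta.json`) holding the
#' scalar configuration needed to re-featurize. Feature matrices are written
#' in Matrix Market (MTX) sparse format with `<path>.rows` / `<path>.cols`
#' label sidecars.
#'
#' @param vocabulary a [fit_vocabulary()] object.
#' @param path output file path.
#' @return the path, invisibly (readers return the reconstructed object).
#' @export
write_vocabulary <- function(vocabulary, path) {
  utils::write.csv(data.frame(term = vocabulary$terms,
                              frequency = as.integer(vocabulary$frequencies),
                              doc_frequency = as.integer(vocabulary$doc_freq),
                              column_index = seq_along(vocabulary$terms)),
                   path, row.names = FALSE)
  cfg <- vocabulary$config
  meta <- list(feature_set = cfg$feature_set, ngram_min = cfg$ngram_min,
               ngram_max = cfg$ngram_max, lowercase = cfg$lowercase,
               prune_percentile = cfg$prune_percentile, prune_mode = cfg$prune_mode,
               weighting = cfg$weighting, n_docs = vocabulary$n_docs)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @param config a [pipeline_config()] supplying the non-scalar pieces
#'   (stopwords, normalizer); scalar fields are restored from the sidecar.
#' @export
read_vocabulary <- function(path, config = pipeline_config()) {
  tab <- utils::read.csv(path, colClasses = c(term = "character"))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  cfg <- pipeline_config(stopwords = config$stopwords,
                         prune_percentile = meta$prune_percentile,
                         feature_set = meta$feature_set,
                         ngram_min = meta$ngram_min, ngram_max = meta$ngram_max,
                         lowercase = meta$lowercase,
                         normalizer = config$normalizer,
                         prune_mode = meta$prune_mode,
                         weighting = meta$weighting)
  freq <- as.integer(tab$frequency)
  names(freq) <- tab$term
  structure(list(terms = tab$term, frequencies = freq,
                 doc_freq = as.integer(tab$doc_frequency),
                 n_docs = meta$n_docs, config = cfg),
            class = "nyha_vocabulary")
}

#' @rdname write_vocabulary
#' @param features a sparse feature matrix from [vectorize()].
#' @export
write_features <- function(features, path) {
  Matrix::writeMM(features, path)
  writeLines(rownames(features) %||% as.character(seq_len(nrow(features))),
             paste0(path, ".rows"))
  writeLines(colnames(features) %||% as.character(seq_len(ncol(features))),
             paste0(path, ".cols"))
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_features <- function(path) {
  m <- methods::as(Matrix::readMM(path), "CsparseMatrix") * 1  # force numeric cells
  dimnames(m) <- list(readLines(paste0(path, ".rows")),
                      readLines(paste0(path, ".cols")))
  attr(m, "zero_rows") <- unname(which(Matrix::rowSums(m) == 0))
  m
}
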