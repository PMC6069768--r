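---
title: "Identifying NYHA functional class in clinical notes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying NYHA functional class in clinical notes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nyhaclass)
```

## The problem

The New York Heart Association (NYHA) functional classification grades
heart-failure severity on an ordinal scale I–IV by how much a patient's
symptoms limit physical activity: class I patients are unrestricted, class
IV patients are symptomatic at rest. Because the class summarizes a bedside
assessment rather than a measurement, it is documented almost exclusively in
free text — clinical notes and the descriptive labels of local
("custom") diagnosis codes — and hardly ever as a structured field. Research
uses such as tracking response to cardiac resynchronization therapy
therefore need an extraction step. `nyhaclass` provides two complementary
extractors (rules and supervised text classification), the machinery to
build a labelled corpus from structured codes, and the evaluation
conventions for comparing them.

## The rule-based method

The extractor anchors on a lexicon of NYHA trigger phrases — by default
"new york heart association", "new york heart classification", "nyha",
"ny classification" and "ny class" — matched case-insensitively at word
boundaries, preferring the longest trigger at a position. After each trigger
a **window** of `window_chars = 40` characters is scanned for the first
class pattern:

* a single digit 1–4 or Roman numeral I–IV, at token boundaries;
* a contiguous pair of two digits or two Roman numerals separated by `-`,
  `/` or an en-dash, with optional spaces ("II/III", "1–2", "II - III").
  A pair is preferred over a single when both start at the same position;
  descending pairs ("III/II") are normalized to ascending order.

Any characters may sit between the trigger and the first class token; the
window bounds only the distance, and the matched token must lie entirely
within it. Three guards suppress the classic false positives:

* Roman numerals never match adjacent to a letter, so "IVF" is not class IV;
* digits never match adjacent to a digit or within a decimal, so the "1" of
  "428.1" is not class 1 (but a sentence-final "NYHA 2." still matches);
* a class token linked to another by "or"/"to" ("NYHA 1 or 2"), a
  non-contiguous separator pair ("2/4"), or a mixed digit/Roman pair
  ("II-3") is treated as ambiguous: the whole expression is skipped and
  produces no mention. The "1 or 2" family is a documented error category
  for window-based extraction, and we extend the same reasoning to the other
  two forms — "2/4" in practice is usually a severity scale, not a class
  statement — rather than silently emitting the first token.

Mentions reduce to a note-level class in two configurable steps: a pair
contributes its **higher** class by default (heart-failure staging
conventionally errs toward the more severe grade; `pair_policy = "lower"`
inverts this), and multiple mentions are resolved by **majority vote** with
ties going to the tied class mentioned last in document order (the most
recent statement in a note is usually the current assessment). An encounter
is classified by pooling the mentions of all its notes and applying the same
reduction. Text before a trigger is never scanned, and a note without a
parseable mention yields an abstention (`NA`), which evaluation counts as a
false negative for the gold class.

Two details of the window convention were genuinely open and are fixed here
once: the window is measured from the character after the trigger, and the
matched token must *end* within it (a token beginning at offset 40 or
truncated by the boundary is not a mention). This choice keeps the invariant
"every reported token lies within the window" exact and makes window
enlargement strictly monotone (a larger window can only add mentions).

## Mapping custom diagnosis codes

Local diagnosis-code labels such as "CHF (NYHA class III, ACC/AHA stage C)
(H)" embed a curated class statement. `map_description()` reuses the note
grammar with one difference: the window spans the whole description, because
code labels are short curated strings where the 40-character bound has no
rationale. Since code-derived classes become gold labels, only unambiguous
descriptions map: a class pair or conflicting statements yield no mapping.

## The reference standard

A note is labelled when at least one mapped code exists for the **same
patient on the same calendar date**; the code's class becomes the note's
gold label. The construction assumes notes agree with the codes attached to
their encounters — the package therefore *excludes* notes whose same-date
codes disagree (a `conflict = "majority"` option keeps the modal class
instead), and records them, since such notes violate the assumption the
labels rest on. An encounter-strict matching mode is available; date
matching is the default key. `split_corpus()` makes a seeded random split —
at the reference test fraction 2474/6174 a 6174-note corpus splits exactly
into 3700 training and 2474 testing notes — with an optional stratified mode
that allocates test notes per class by largest-remainder rounding
(per-class deviation at most one note). The default split is unstratified
because the reference corpus this emulates had train/test class ratios that
are similar but not exactly proportional.

## The machine-learning method

Preprocessing runs in a fixed order: tokenize (punctuation split off;
decimal codes like "428.0" kept whole), lower-case, remove stopwords,
normalize, featurize, prune.

* **Stopwords.** A standard English list, with one deliberate exception: the
  pronoun "i" is kept, because after lower-casing it is indistinguishable
  from the Roman numeral for class I and removing it would delete the
  class-I marker from every feature set.
* **Normalizer.** Lexical normalization is a pluggable contract — any
  token-vector function can be supplied. The default is a small ordered set
  of suffix rules (plurals, "-ies"/"-sses", "-ing"/"-ed", and "-eic" to
  "-ea" so that "dyspneic" and "dyspnea" share a form). It reproduces the
  *role* of a lexical-variant generator, not any specific tool.
* **Features.** Feature set 1 is unigram bag-of-words counts; feature set 2
  is space-joined contiguous n-grams with n from `ngram_min = 2` to
  `ngram_max = 5` (unigrams excluded by default; the range is
  configurable). Cells are raw counts by default, with binary and tf-idf
  options — no weighting is assumed beyond counts.
* **Pruning.** "Discard the least frequent terms" is implemented as a
  frequency-quantile cut: every term whose corpus frequency is at or below
  the 1st percentile (inverse-ECDF quantile, `type = 1`) of the
  term-frequency distribution is removed, ties at the threshold included;
  `prune_percentile = 0` disables pruning. A rank-based alternative (drop
  the bottom 1% of distinct types) sits behind `prune_mode = "rank"`.
  The quantile reading matches the stated intent — removing the least
  frequently *used* words — and, unlike the rank reading, is invariant to
  how many hapax variants a corpus happens to contain.

Three classifier families are supported, with deliberately standard
defaults since none are dictated by the problem: a linear-kernel SVM
(cost 1) decomposed one-vs-rest for the four classes, an L2-regularized
(ridge, `lambda = 0.01`) multinomial logistic regression, and a 500-tree
random forest grown single-threaded under a fixed seed. Cross-validation is
stratified and seeded: with class IV at only ~8% of notes, unstratified
folds would be unstable. Feature importance reports use impurity importance
for the forest and maximum absolute per-class coefficients for the linear
families.

## Evaluation conventions

Per class `c`: precision `P_c = TP_c/(TP_c+FP_c)` over notes predicted `c`,
recall `R_c = TP_c/(TP_c+FN_c)` over notes with gold `c`,
`F_c = 2 P_c R_c / (P_c + R_c)`. Rule-based abstentions count as false
negatives for their gold class and as no prediction for any class. The
"Overall" row is macro-averaged (unweighted means over the four classes).
Published work mixes two conventions for the overall F — sometimes the
unweighted mean of per-class F, sometimes the harmonic mean of macro
precision and macro recall — and the two disagree in general, so
`evaluate()` reports both, labelled `overall_f_macro` and
`overall_f_harmonic`. A degenerate class (no predictions, or no gold
instances) has undefined precision or recall, reported as `NA` and omitted
from the macro means.

## The synthetic EHR generator

`generate_corpus()` emulates the *structure* of the extraction problem: each
note is a handful of clinical filler sentences followed by at most one NYHA
statement, each patient carries a heart-failure ICD code, and each note with
a planted mention carries a same-date custom code whose label encodes the
planted class — the reference-standard assumption holds by construction,
with a `label_noise` knob to break it at a controlled rate. The default
class mix (22.1 / 40.5 / 29.0 / 8.3 percent over I–IV) reproduces the class
imbalance of the corpus this package emulates, so the hard case — sparse
class IV — is stressed in every test. Mention styles include digits, Roman
numerals, pairs (planted as the pair's higher class, matching the default
pair policy; a class-1 draw falls back to a Roman single since no pair
resolves upward to 1), trigger-free notes, the "1 or 2" ambiguity and an
"IV fluids" distractor. Filler sentences deliberately include class-like
tokens in non-NYHA contexts ("IV fluids", "grade II/VI murmur", "walked 3
laps") to pollute unigram features the way real notes do.

What the generator does *not* emulate: real lexical diversity (templates,
not language), historical-vs-current mentions ("history of NYHA III in
2012" — the rule method cannot distinguish these in real notes either, a
known limitation), negation, section structure, spelling errors, or
multiple notes per encounter with disagreeing content. Perfect scores on
synthetic corpora therefore validate the machinery and the closed loop
between generator, extractor and reference builder — not clinical
performance, which on real EHR text is bounded by exactly the phenomena the
generator omits.

## Numerical and design choices

* Character offsets are 0-based, half-open everywhere.
* ICD codes are normalized by deleting internal whitespace before matching;
  code ranges ("428.1–428.4", "I50.1–I50.4") are inclusive on the decimal
  extension read as a decimal fraction, and "428.*" accepts any or no
  extension.
* Vocabulary order is fixed at fit time (decreasing frequency, ties
  alphabetical), so refits are byte-identical; splits, folds, the generator
  and the forests all consume explicit seeds, and `run_pipeline()` derives
  every stage seed from one global seed, making a whole run reproducible
  from its manifest.
* Tie-breaks are always explicit: majority-vote ties go to the last mention
  in document order; stratified-split remainders go to classes in order;
  SVM decision-value ties go to the lower class.
* Degenerate inputs: empty text yields no tokens and no mentions; an empty
  corpus is a contract violation for vocabulary fitting and splitting;
  out-of-vocabulary-only notes keep a flagged all-zero feature row.

## Problem sizes used in the test suite

The package's own checks run at sizes chosen to exercise the claims while
staying quick on one CPU: closed-loop rule extraction on 5000 synthetic
notes; 10-fold random-forest cross-validation on a ~1250-note corpus for
the feature-set comparison (n-gram versus bag-of-words); 1000 fuzzed texts
against a brute-force scanner oracle; and the full 6174-note / 3700 / 2474
split bookkeeping. The acceptance script regenerates a full-size 6174-note
corpus and reports rule-based and random-forest metrics on its 2474-note
held-out set.

## Known limitations

The rule method is window-based: it has no notion of negation, hedging,
recommendation sections, or historical statements, and a trigger whose
class sits more than 40 characters away is missed. The code mapper trusts
curated labels; free-text fields that merely mention NYHA without asserting
a class are unmapped by design. The reference standard inherits any
miscoding in the structured data, and conflict exclusion discards precisely
the encounters where that is detectable. The classifiers are bounded by the
reference labels and, on synthetic data, by template diversity; their
near-ceiling synthetic scores should be read as correctness checks, not
clinical benchmarks.
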