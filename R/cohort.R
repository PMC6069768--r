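#' Heart-failure diagnosis codes and cohort filter
#'
#' `is_hf_diagnosis()` tests whether an ICD-9 / ICD-10 code belongs to the
#' heart-failure code list used to assemble the study cohort:
#'
#' * ICD-9: 398.91; 402.01, 402.11, 402.91; 404.01, 404.03, 404.11, 404.13,
#'   404.91, 404.93; all codes with root 428 (any or no decimal extension,
#'   which subsumes the 428.1-428.4 range and 428.9);
#' * ICD-10: I11.0; I13.0, I13.2; I50.1-I50.4 (inclusive on the decimal
#'   extension), I50.9; I97.13.
#'
#' Codes are normalized by deleting internal whitespace and upper-casing
#' before matching; a range such as I50.1-I50.4 covers any code whose decimal
#' extension, read as a decimal fraction, lies in the closed interval
#' (so I50.25 is inside, I50.45 is not). Unrecognized codes simply return
#' `FALSE`.
#'
#' @param code character vector of diagnosis codes.
#' @return `is_hf_diagnosis()`: a logical vector. `filter_hf_cohort()`: the
#'   sorted set of patient identifiers with at least one heart-failure coded
#'   encounter.
#' @examples
#' is_hf_diagnosis(c("428.0", "I50.9", "J45.0"))
#' @export
is_hf_diagnosis <- function(code) {
  x <- toupper(gsub("[[:space:]]+", "", as.character(code)))
  exact <- c(
    "398.91", "402.01", "402.11", "402.91",
    "404.01", "404.03", "404.11", "404.13", "404.91", "404.93",
    "428.9",
    "I11.0", "I13.0", "I13.2", "I50.9", "I97.13"
  )
  hit <- x %in% exact
  hit <- hit | grepl("^428(\\.[0-9]*)?$", x)
  hit <- hit | .ext_in_range(x, "I50", 0.1, 0.4)
  hit[is.na(x)] <- FALSE
  hit
}

# decimal-extension range membership: root.ext with value(".ext") in [lo, hi]
.ext_in_range <- function(x, root, lo, hi) {
  pref <- paste0(root, ".")
  ok <- startsWith(x, pref)
  ext <- substring(x[ok], nchar(pref) + 1L)
  val <- suppressWarnings(as.numeric(paste0("0.", ext)))
  inside <- grepl("^[0-9]+$", ext) & !is.na(val) & val >= lo & val <= hi
  res <- logical(length(x))
  res[ok] <- inside
  res
}

#' @rdname is_hf_diagnosis
#' @param encounters an encounter table (see [coded_encounters()]).
#' @param crt_patients optional character vector of patient ids with evidence
#'   of a CRT device, supplied externally; these are added to the cohort.
#' @export
filter_hf_cohort <- function(encounters, crt_patients = character()) {
  encounters <- validate_encounters(encounters)
  ids <- encounters$patient_id[is_hf_diagnosis(encounters$code)]
  sort(unique(c(ids, as.character(crt_patients))))
}
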