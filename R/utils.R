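`%||%` <- function(a, b) if (is.null(a)) b else a

.ROMAN <- c("I", "II", "III", "IV")
.roman_to_class <- function(x) match(toupper(x), .ROMAN)

# deterministic merge of user hyperparameters over family defaults
.merge_defaults <- function(user, defaults) {
  out <- defaults
  for (nm in names(user)) out[[nm]] <- user[[nm]]
  out
}

.stop_contract <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
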