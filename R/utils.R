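# Internal helpers shared across modules.

# Canonicalise a sex column to "female"/"male". Accepts M/F/male/female,
# any case; anything else is an error naming the offending values.
canonical_sex <- function(x) {
  lowered <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    lowered %in% c("f", "female") ~ "female",
    lowered %in% c("m", "male") ~ "male",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(paste0(
      "Unrecognised sex value(s): ", paste(bad, collapse = ", "),
      " (accepted: M, F, male, female, case-insensitive)"
    ))
  }
  out
}

# Deterministic 32-bit-safe seed derived from a base seed and a string key,
# so e.g. each rater gets a distinct but reproducible stream.
derive_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% 1977326743L
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Format a number for embedding in deterministic SVG/JSON text.
num_fmt <- function(x, digits = 4) {
  formatC(x, format = "f", digits = digits)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing mandatory column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
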