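# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character strings (alphabet
#' `ACGTN`, case preserved for upper case input).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ACGGT")
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# Random DNA string of length n, drawn from the current RNG stream.
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(DNA_BASES[sample.int(4L, n, replace = TRUE)], collapse = "")
}

# Round half away from zero to `digits` decimals (base round() is half-even).
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

# Normalise sex tokens to "M"/"F"; returns NA for unrecognised tokens.
normalize_sex <- function(x) {
  key <- toupper(trimws(x))
  out <- rep(NA_character_, length(key))
  out[key %in% c("M", "MALE")] <- "M"
  out[key %in% c("F", "FEMALE")] <- "F"
  out
}
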