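# Small shared helpers.

#' Round half-up
#'
#' Rounds to `digits` decimal places with halves always rounded away from
#' zero, the convention used in published summary tables. Base [round()]
#' uses IEC 60559 round-half-even, which would turn 0.125 into 0.12.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' @param count numeric count(s).
#' @param total denominator; `total == 0` yields 0 for zero counts.
#' @return numeric percentage(s) on the 0-100 scale.
#' @export
percent_of <- function(count, total) {
  if (total == 0) return(rep(0, length(count)))
  round_half_up(100 * count / total, 2)
}

# Case-insensitive, whitespace-normalized term key used for all string
# matching (drug names, MedDRA terms, SMQ terms). Collapses internal runs
# of whitespace and trims.
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_faersddi <- function(...) stop(..., call. = FALSE)
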