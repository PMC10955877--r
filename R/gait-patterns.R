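#' Gait pattern codes
#'
#' The four gait patterns handled by the classifier: normal gait (`"N"`),
#' toe-out (`"TO"`), trunk-lean (`"TL"`) and their combination (`"TOTL"`).
#' Internally each pattern is encoded by two binary indicators, a TO bit and
#' a TL bit, so that the two detector output channels jointly identify the
#' four classes: N = (0,0), TO = (1,0), TL = (0,1), TOTL = (1,1).
#'
#' @return `gait_patterns()` returns the character vector of the four codes
#'   in canonical order.
#' @export
gait_patterns <- function() c("N", "TO", "TL", "TOTL")

#' @describeIn gait_patterns Map pattern codes to the (TO, TL) indicator
#'   pair. Accepts a vector of codes and returns a 2-row matrix with rows
#'   `TO` and `TL` (one column per input).
#' @param pattern character vector of pattern codes.
#' @export
pattern_to_onehot <- function(pattern) {
  pattern <- match_pattern(pattern)
  rbind(
    TO = as.numeric(pattern %in% c("TO", "TOTL")),
    TL = as.numeric(pattern %in% c("TL", "TOTL"))
  )
}

#' @describeIn gait_patterns Inverse mapping: two binary indicator vectors
#'   to pattern codes.
#' @param to_bit,tl_bit binary (0/1 or logical) vectors of equal length.
#' @export
onehot_to_pattern <- function(to_bit, tl_bit) {
  stopifnot(length(to_bit) == length(tl_bit))
  to_bit <- as.integer(as.logical(to_bit))
  tl_bit <- as.integer(as.logical(tl_bit))
  c("N", "TO", "TL", "TOTL")[1L + to_bit + 2L * tl_bit]
}

match_pattern <- function(pattern) {
  pattern <- as.character(pattern)
  bad <- !(pattern %in% gait_patterns())
  if (any(bad)) {
    stop("unknown gait pattern code(s): ",
         paste(unique(pattern[bad]), collapse = ", "))
  }
  pattern
}
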