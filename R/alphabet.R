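#' The 21-state alphabet
#'
#' The model works over 21 states: the 20 canonical amino acids (alphabetical
#' one-letter order) followed by the gap symbol \code{"-"}, which is treated
#' as an additional amino-acid state during fitting and excluded only at
#' scoring time.
#'
#' @return Character vector of length 21; the gap is the last element.
#' @export
smrf_alphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
}

#' @rdname smrf_alphabet
#' @export
gap_state <- function() 21L

#' Encode residue letters as state indices
#'
#' Letters outside the 20 canonical amino acids (ambiguity codes X/B/Z/J/U/O,
#' \code{"."}, anything else) encode as the gap state; the model has no notion
#' of ambiguity.
#'
#' @param chars character vector of single letters (case-insensitive).
#' @return Integer vector of states in \code{1..21}.
#' @export
encode_states <- function(chars) {
  idx <- match(toupper(chars), smrf_alphabet())
  idx[is.na(idx)] <- gap_state()
  idx
}

#' Decode state indices back to letters
#' @param states integer vector in \code{1..21}.
#' @return Character vector of letters.
#' @export
decode_states <- function(states) {
  stopifnot(all(states >= 1L & states <= 21L))
  smrf_alphabet()[states]
}
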