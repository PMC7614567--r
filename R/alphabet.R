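#' The 21-letter protein alphabet
#'
#' Twenty standard amino acids (alphabetical one-letter codes) followed by the
#' gap character `-`. Encoded states are the integer positions `1..21`, so the
#' gap is the distinguished state `21`. Synthetic toy models with `q < 21`
#' states use the first `q` symbols of this alphabet and have no gap state.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

#' Index of the gap state in a q-state alphabet
#' @param q Number of states.
#' @return `21L` for the full alphabet, otherwise `NA` (toy alphabets have no gap).
#' @export
gap_state <- function(q = 21L) {
  if (q == 21L) 21L else NA_integer_
}

#' Encode character sequences as integer state matrices
#'
#' Case-insensitive; `.` is treated as a gap. Unknown characters are an error
#' reporting the record and position.
#'
#' @param x Character vector of equal-length sequences.
#' @param q Alphabet size (first `q` symbols of [aa_alphabet()] are legal).
#' @return Integer matrix with one row per sequence, entries in `1..q`.
#' @export
encode_sequences <- function(x, q = 21L) {
  stopifnot(is.character(x))
  if (length(x) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  lens <- nchar(x)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop("ragged alignment: record ", bad, " has length ", lens[bad],
         " but record 1 has length ", lens[1], call. = FALSE)
  }
  chars <- toupper(do.call(rbind, strsplit(x, "", fixed = TRUE)))
  chars[chars == "."] <- "-"
  states <- match(chars, aa_alphabet()[seq_len(q)])
  if (anyNA(states)) {
    bad <- which(is.na(states))[1]
    ij <- arrayInd(bad, dim(chars))
    stop("unknown character '", chars[bad], "' in record ", ij[1],
         " at position ", ij[2], call. = FALSE)
  }
  matrix(states, nrow = length(x), ncol = lens[1])
}

#' Decode integer state matrices back to character sequences
#' @param states Integer matrix (rows are sequences) or vector (one sequence).
#' @return Character vector of sequences.
#' @export
decode_sequences <- function(states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  if (ncol(states) == 0L) return(rep("", nrow(states)))
  apply(states, 1L, function(s) paste(aa_alphabet()[s], collapse = ""))
}
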