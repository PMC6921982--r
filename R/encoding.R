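#' Bit-pack a UMI sequence with the equidistant 3-bit nucleotide code
#'
#' Encodes a nucleotide sequence over \{A, C, G, T, N\} into 64-bit machine
#' words, three bits per position, using the pairwise-equidistant codes
#' \code{e_A = 110}, \code{e_T = 011}, \code{e_C = 101}, \code{e_G = 000}.
#' Because any two distinct codes differ in exactly two bits, the Hamming
#' distance between two N-free sequences equals half the popcount of the XOR
#' of their coded bits, so distances cost one XOR and one popcount per word.
#' Undetermined \code{N} positions are recorded in a separate position mask
#' and hold the canonical pattern \code{000} in the coded bits; \code{N} acts
#' as a fifth letter for distance purposes (it mismatches A/C/G/T and matches
#' another N).
#'
#' @param x character vector of sequences over A/C/G/T/N (case-insensitive).
#' @return For a single sequence, an object of class \code{encoded_umi} with
#'   elements \code{words} (hex-encoded 64-bit words of packed codes),
#'   \code{bits} (the concatenated 3-bit codes as a \code{0}/\code{1}
#'   string), \code{n_positions} (1-based positions flagged as N),
#'   \code{length}, and \code{sequence}.  For a vector, a list of such
#'   objects.
#' @seealso [umi_decode()], [umi_hamming()], [umi_word_capacity()]
#' @examples
#' umi_encode("AAT")$bits  # "110110011"
#' umi_hamming("AAT", "AAA")
#' @export
umi_encode <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  enc1 <- function(s) structure(cpp_encode(s), class = "encoded_umi")
  if (length(x) == 1L) enc1(x) else lapply(x, enc1)
}

#' Decode a bit-packed UMI back to its nucleotide sequence
#'
#' Exact inverse of [umi_encode()]: reads each 3-bit group out of the packed
#' words and maps it back to a nucleotide, emitting \code{N} at masked
#' positions.  A 3-bit group that is neither a valid nucleotide code nor the
#' canonical N pattern raises an integrity error.
#'
#' @param e an \code{encoded_umi} object.
#' @return the decoded sequence (uppercase character scalar).
#' @export
umi_decode <- function(e) {
  stopifnot(inherits(e, "encoded_umi"))
  cpp_decode(e$words, e$n_positions, e$length)
}

#' @export
print.encoded_umi <- function(x, ...) {
  cat("<encoded_umi> ", x$sequence, " (M = ", x$length, ", ",
      length(x$words), " word", if (length(x$words) > 1) "s", ")\n", sep = "")
  cat("  coded bits: ", x$bits, "\n", sep = "")
  if (length(x$n_positions))
    cat("  N positions: ", paste(x$n_positions, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
format.encoded_umi <- function(x, ...) x$sequence

#' Hamming distance between UMI sequences
#'
#' Counts mismatching positions between equal-length sequences, computed
#' word-parallel on the 3-bit packed encoding: popcount of the XOR of the
#' coded bits restricted to non-N positions, halved, plus the popcount of the
#' XOR of the N masks.  \code{N} is a fifth letter: a position where exactly
#' one sequence has \code{N} counts as a mismatch, a position where both do
#' counts as a match.
#'
#' @param a,b character vectors of sequences (recycled to a common length),
#'   or \code{encoded_umi} objects.
#' @return integer vector of distances.
#' @examples
#' umi_hamming("AAT", "AAA")    # 1
#' umi_hamming("ANT", "AAT")    # 1
#' umi_hamming("ANT", "ANT")    # 0
#' @export
umi_hamming <- function(a, b) {
  if (inherits(a, "encoded_umi")) a <- a$sequence
  if (inherits(b, "encoded_umi")) b <- b$sequence
  cpp_hamming(a, b)
}

#' Popcount of the XOR of two packed encodings
#'
#' Returns \code{popcount(encode(a) XOR encode(b))} over the coded bits.  For
#' N-free sequences this is exactly twice the Hamming distance, which is the
#' property that makes the 3-bit code useful.
#'
#' @inheritParams umi_hamming
#' @return integer vector of set-bit counts.
#' @examples
#' umi_xor_popcount("AAT", "AAA")  # 2
#' @export
umi_xor_popcount <- function(a, b) {
  if (inherits(a, "encoded_umi")) a <- a$sequence
  if (inherits(b, "encoded_umi")) b <- b$sequence
  cpp_xor_popcount(a, b)
}

#' Number of nucleotide positions that fit in one 64-bit word
#'
#' At three bits per position, \code{floor(64 / 3) = 21} positions are packed
#' per word; longer UMIs span an array of words.
#'
#' @return the integer 21.
#' @export
umi_word_capacity <- function() 21L
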