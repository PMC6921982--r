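#' Index backends implementing the near-neighbor contract
#'
#' @format character vector of the eight backend names accepted everywhere a
#'   \code{backend} argument appears: \code{"naive"} (linear scan; the
#'   reference), \code{"combo"} (generate-and-probe), \code{"subseq"}
#'   (placeholder-masked subsequence hash), \code{"ngram"} (n-gram inverted
#'   index), \code{"trie"}, \code{"bktree"}, \code{"fenwickbk"} (Fenwick
#'   tree over BK-trees), \code{"ngrambk"} (n-gram bins of BK-trees).
#' @export
UMI_BACKENDS <- c("naive", "combo", "subseq", "ngram", "trie", "bktree",
                  "fenwickbk", "ngrambk")

#' Build a dynamic near-neighbor index over a UMI frequency table
#'
#' The index implicitly represents the UMI graph G = (V, E) with an edge
#' between UMIs at Hamming distance at most \code{k}, and supports two
#' operations: [umi_remove_near()] (return and delete all alive UMIs within
#' \code{k} edits of a query, subject to a frequency ceiling) and
#' [umi_contains()].  All eight backends answer identically; they differ
#' only in how much of the candidate space they prune.
#'
#' @param table a \code{umi_table} (see [umi_count()]) or a data frame with
#'   columns \code{umi} and \code{count}.
#' @param k maximum Hamming distance (edit threshold) the index serves;
#'   fixed at build time.
#' @param backend one of [UMI_BACKENDS].
#' @return a \code{umi_index} object.
#' @examples
#' idx <- umi_index(umi_count(c("AAAA", "AAAA", "AAAT", "TTTT")), k = 1)
#' umi_remove_near(idx, "AAAA")
#' umi_contains(idx, "AAAT")
#' @export
umi_index <- function(table, k = 1L, backend = "ngrambk") {
  table <- as_umi_table(table)
  backend <- match.arg(backend, UMI_BACKENDS)
  structure(
    list(ptr = cpp_index_build(table$umi, table$count, as.integer(k),
                               backend),
         k = as.integer(k), backend = backend,
         umi_length = attr(table, "umi_length"), n = nrow(table)),
    class = "umi_index")
}

#' Return and remove all UMIs near a query
#'
#' Returns the set S of alive UMIs v with d(u, v) <= k and f(v) <= f_max,
#' plus the queried UMI u itself whenever u is still alive (u is included
#' regardless of its own frequency).  Every returned UMI is marked removed
#' before the call returns, so a UMI is returned by at most one
#' \code{umi_remove_near} call over the index's lifetime.
#'
#' @param index a \code{umi_index}.
#' @param umi the query sequence.  Must have been in the table unless
#'   \code{strict = FALSE}, in which case an arbitrary same-length sequence
#'   may be used (its neighbors are still returned and removed).
#' @param k edit threshold; must equal the build-time \code{k} of the index
#'   (passing anything else is an error, not a rebuild).
#' @param f_max frequency ceiling F; \code{Inf} (the default) means no
#'   ceiling.
#' @param strict if \code{TRUE} (default), querying a UMI that was never in
#'   the table is an error.
#' @return character vector of removed UMI sequences (set semantics; order
#'   unspecified).
#' @export
umi_remove_near <- function(index, umi, k = index$k, f_max = Inf,
                            strict = TRUE) {
  stopifnot(inherits(index, "umi_index"), is.character(umi),
            length(umi) == 1L)
  cpp_index_remove_near(index$ptr, umi, as.integer(k), as.numeric(f_max),
                        isTRUE(strict))
}

#' Test whether a UMI is present and not yet removed
#'
#' @inheritParams umi_remove_near
#' @return \code{TRUE} iff \code{umi} was in the table and has not been
#'   returned by any [umi_remove_near()] call; \code{FALSE} for absent UMIs.
#' @export
umi_contains <- function(index, umi) {
  stopifnot(inherits(index, "umi_index"), is.character(umi),
            length(umi) == 1L)
  cpp_index_contains(index$ptr, umi)
}

#' List the UMIs still alive in an index
#'
#' @inheritParams umi_remove_near
#' @return character vector of not-yet-removed UMI sequences.
#' @export
umi_alive <- function(index) {
  stopifnot(inherits(index, "umi_index"))
  cpp_index_alive(index$ptr)
}

#' @export
print.umi_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("<umi_index> backend=", info$backend, " k=", info$k, " N=", info$n,
      " M=", info$m, if (!info$fresh) " (partially consumed)", "\n", sep = "")
  invisible(x)
}

#' Split a UMI into k + 1 contiguous non-overlapping n-grams
#'
#' For sequences within k substitutions of each other, the pigeonhole
#' principle guarantees at least one of the k + 1 grams matches exactly in
#' both, which is what makes the n-gram inverted index a complete filter.
#' Gram length is \code{floor(M / (k + 1))}; the last gram absorbs the
#' remainder.
#'
#' @param seq a UMI sequence.
#' @param k edit threshold; requires \code{nchar(seq) >= k + 1}.
#' @return data frame with columns \code{slot} (0-based gram index),
#'   \code{start} (1-based), \code{length} and \code{gram}.
#' @examples
#' split_ngrams("ACGTACGTAC", 1)  # two grams of length 5
#' @export
split_ngrams <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_split_ngrams(seq, as.integer(k))
}

#' Enumerate the placeholder-masked subsequence keys of a UMI
#'
#' Replaces every choice of k positions with a placeholder character,
#' yielding choose(M, k) keys.  Two UMIs share a key if and only if they
#' differ in at most k positions, all covered by the mask — so bin
#' membership needs no distance verification.
#'
#' @inheritParams split_ngrams
#' @param placeholder single character used for masked positions (internal
#'   to the key; never written to output files).
#' @return character vector of masked keys.
#' @examples
#' mask_subsequences("ATCG", 1)
#' @export
mask_subsequences <- function(seq, k, placeholder = "*") {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_mask_subsequences(seq, as.integer(k), placeholder)
}

#' Generate all sequences within k substitutions of a UMI
#'
#' Enumerates the full Hamming ball of radius k around \code{seq} over the
#' given alphabet, including \code{seq} itself; this is the candidate set
#' probed by the combinations backend.  Its cardinality is
#' \code{sum(choose(M, j) * (A - 1)^j)} for j in 0..k, with A the alphabet
#' size.
#'
#' @inheritParams split_ngrams
#' @param alphabet character vector of single letters (default the 5-letter
#'   UMI alphabet).
#' @return character vector of sequences (each generated exactly once).
#' @export
generate_within <- function(seq, k, alphabet = c("A", "C", "G", "T", "N")) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_generate_within(seq, as.integer(k), paste(alphabet, collapse = ""))
}

#' Prefix decomposition of a Fenwick (binary indexed) tree over frequencies
#'
#' Given the distinct UMI frequency values in increasing order (the
#' rank-compressed array the Fenwick-of-BK-trees backend is built on),
#' returns the O(log N) Fenwick nodes whose rank intervals tile
#' [1, rank(F)], where rank(F) is the largest rank with value <= F.  These
#' are exactly the BK-trees visited for a query with frequency ceiling F.
#'
#' @param freq_values strictly increasing numeric vector of distinct
#'   frequency values.
#' @param f_max frequency ceiling F (may be \code{Inf}).
#' @return list with \code{node} (Fenwick node ids), \code{rank_lo},
#'   \code{rank_hi} (the 1-based rank interval each node covers) and
#'   \code{rank_of_f}.
#' @examples
#' fenwick_prefix_decompose(1:7, 5)  # nodes covering [1..4] and [5..5]
#' @export
fenwick_prefix_decompose <- function(freq_values, f_max) {
  cpp_fenwick_decompose(as.numeric(freq_values), as.numeric(f_max))
}

#' Structural statistics of an index backend
#'
#' Builds the requested backend over a frequency table and reports its
#' internal statistics: bin counts and sizes for the hash-based backends,
#' node count for the trie, node depths for the BK-tree family.
#'
#' @inheritParams umi_index
#' @return a named list of statistics (contents depend on the backend).
#' @export
umi_index_stats <- function(table, k = 1L, backend = "ngrambk") {
  table <- as_umi_table(table)
  backend <- match.arg(backend, UMI_BACKENDS)
  ptr <- cpp_index_build(table$umi, table$count, as.integer(k), backend)
  cpp_index_stats(ptr)
}
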