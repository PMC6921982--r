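#' Group UMIs by network collapsing
#'
#' Partitions the unique UMIs of a frequency table into groups of presumed
#' PCR/sequencing duplicates, using one of three algorithms expressed purely
#' over the near-neighbor contract:
#' \describe{
#'   \item{\code{cluster}}{connected components of the UMI graph: every UMI
#'     reachable through a chain of <= k-distance steps joins one group
#'     (transitive "bridging" can merge UMIs more than k apart).}
#'   \item{\code{adjacency}}{UMIs are visited in decreasing frequency order;
#'     each still-alive seed claims exactly its alive neighbors, with no
#'     recursion.}
#'   \item{\code{directional}}{like adjacency but recursive, admitting a
#'     neighbor v of u only when f(v) <= epsilon * (f(u) + 1); with the
#'     default epsilon = 0.5 this is the classic 2 f(v) - 1 <= f(u) rule.}
#' }
#' Each group's representative is its highest-frequency member (ties broken
#' by lexicographically smallest sequence).  The grouping is invariant to
#' the index backend used to answer the near-neighbor queries.
#'
#' @param table a \code{umi_table} or data frame with columns \code{umi},
#'   \code{count}.
#' @param k maximum Hamming distance between directly-linked UMIs.
#' @param method one of \code{"directional"}, \code{"adjacency"},
#'   \code{"cluster"}.
#' @param backend one of [UMI_BACKENDS]; the default is the n-grams
#'   BK-trees hybrid.
#' @param epsilon directional admission threshold in [0, 1].
#' @param index optionally, a fresh \code{umi_index} built from the same
#'   table; it is consumed by the run.  An index that has already served
#'   queries is rejected.
#' @return a \code{umi_grouping}: the table with added columns \code{group}
#'   (1-based group id) and \code{representative} (logical), plus attributes
#'   \code{n_groups}, \code{method}, \code{k}, \code{epsilon},
#'   \code{backend} and \code{hamming_evals} (number of Hamming distance
#'   evaluations the backend performed).
#' @examples
#' tab <- umi_count(c(rep("AAAA", 10), rep("AAAT", 5), rep("AATT", 2)))
#' umi_group(tab, k = 1, method = "directional")
#' @export
umi_group <- function(table, k = 1L,
                      method = c("directional", "adjacency", "cluster"),
                      backend = "ngrambk", epsilon = 0.5, index = NULL) {
  method <- match.arg(method)
  table <- as_umi_table(table)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 ||
      epsilon > 1)
    stop("epsilon must be a single number in [0, 1]")
  if (nrow(table) == 0L) {
    res <- table
    res$group <- integer(0)
    res$representative <- logical(0)
    return(structure(res, n_groups = 0L, method = method,
                     k = as.integer(k), epsilon = epsilon,
                     backend = backend, hamming_evals = 0,
                     class = c("umi_grouping", "data.frame")))
  }
  if (is.null(index)) {
    backend <- match.arg(backend, UMI_BACKENDS)
    out <- cpp_dedup(table$umi, table$count, as.integer(k), method, backend,
                     epsilon)
  } else {
    stopifnot(inherits(index, "umi_index"))
    info <- cpp_index_info(index$ptr)
    if (!info$fresh)
      stop("index has already served remove_near queries; ",
           "build a fresh one for grouping")
    if (info$k != as.integer(k))
      stop("index was built with k = ", info$k, ", not k = ", k)
    if (info$n != nrow(table))
      stop("index does not match the table (", info$n, " vs ", nrow(table),
           " UMIs)")
    backend <- info$backend
    out <- cpp_dedup_on_index(index$ptr, method, epsilon)
  }
  res <- table
  res$group <- out$group
  res$representative <- seq_len(nrow(table)) %in% out$representative
  structure(res, n_groups = out$n_groups, method = method,
            k = as.integer(k), epsilon = epsilon, backend = backend,
            hamming_evals = out$hamming_evals,
            class = c("umi_grouping", "data.frame"))
}

#' @export
print.umi_grouping <- function(x, ...) {
  cat("UMI grouping (", attr(x, "method"), ", k = ", attr(x, "k"),
      ", backend = ", attr(x, "backend"), "): ",
      nrow(x), " unique UMIs -> ", attr(x, "n_groups"), " groups\n",
      sep = "")
  NextMethod()
}

#' Number of groups in a grouping
#' @param x a \code{umi_grouping}.
#' @return integer group count.
#' @export
n_groups <- function(x) {
  stopifnot(inherits(x, "umi_grouping"))
  attr(x, "n_groups")
}

#' Pick the representative (consensus) UMI of a group
#'
#' The member with the highest frequency; frequency ties are broken by the
#' lexicographically smallest sequence so the choice is deterministic.
#'
#' @param umis character vector of member sequences (non-empty).
#' @param counts their frequencies.
#' @return the representative sequence.
#' @examples
#' select_representative(c("AAAA", "AAAT"), c(5, 5))  # "AAAA"
#' @export
select_representative <- function(umis, counts) {
  if (length(umis) == 0L) stop("cannot select a representative of an empty group")
  stopifnot(length(umis) == length(counts))
  ord <- order(-as.numeric(counts), umis)
  umis[ord[1L]]
}
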