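#' Simulate a (C, M, k) UMI dataset
#'
#' Generates the synthetic datasets used throughout the package's
#' evaluation: \code{n_centers} "center" UMIs drawn uniformly over
#' \{A,C,G,T,N\}^M, each surrounded by \code{neighbors_per_center} random
#' UMIs within \code{k} substitutions.  For \code{k = 1} every neighbor is
#' exactly one substitution away (a uniformly chosen position changed to a
#' uniformly chosen different letter); for \code{k >= 2} the number of
#' edited positions is drawn uniformly from 1..k.  Centers receive "higher"
#' random frequencies and non-centers "lower" ones, such that every
#' center/non-center pair (u, v) satisfies 2 f(v) - 1 <= f(u) — with the
#' default ranges, neighbors draw from 1..10 and centers from 19..100, tight
#' at the boundary 2*10 - 1 = 19.
#'
#' Duplicate sequences are collapsed into the unique-UMI table; a neighbor
#' that collides with a center keeps its center role and frequency.  Draws
#' happen in a fixed order (center letters, then per-center neighbor edits,
#' then center frequencies, then neighbor frequencies), so a seed fully
#' determines the dataset.
#'
#' @param n_centers number of center UMIs (C).
#' @param umi_length UMI length (M).
#' @param k maximum substitutions between a neighbor and its center.
#' @param neighbors_per_center neighbors generated per center (default 20).
#' @param seed mandatory integer seed.
#' @param center_freq,neighbor_freq inclusive integer ranges for the
#'   "higher" and "lower" frequency draws.
#' @return a \code{umi_sim} object: list with \code{table} (the unique-UMI
#'   \code{umi_table}), \code{centers} (unique center sequences),
#'   \code{roles} (\code{"center"}/\code{"neighbor"} per table row) and
#'   \code{params}.
#' @examples
#' sim <- simulate_umi_dataset(100, 10, 1, seed = 1)
#' nrow(sim$table)  # about 1.7k unique UMIs
#' @export
simulate_umi_dataset <- function(n_centers, umi_length, k = 1L,
                                 neighbors_per_center = 20L, seed,
                                 center_freq = c(19L, 100L),
                                 neighbor_freq = c(1L, 10L)) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  C <- as.integer(n_centers); M <- as.integer(umi_length)
  k <- as.integer(k); npc <- as.integer(neighbors_per_center)
  if (C < 0L) stop("n_centers must be >= 0")
  if (M < 1L) stop("umi_length must be >= 1")
  if (k < 0L || k >= M) stop("k must satisfy 0 <= k < umi_length")
  if (2L * neighbor_freq[2L] - 1L > center_freq[1L])
    stop("frequency ranges must guarantee 2 f(neighbor) - 1 <= f(center)")
  alpha <- c("A", "C", "G", "T", "N")
  params <- list(n_centers = C, umi_length = M, k = k,
                 neighbors_per_center = npc, seed = as.integer(seed),
                 center_freq = center_freq, neighbor_freq = neighbor_freq)
  empty <- function() {
    structure(list(table = umi_count(character(0)), centers = character(0),
                   roles = character(0), params = params),
              class = "umi_sim")
  }
  if (C == 0L) return(empty())
  set.seed(as.integer(seed))

  cm <- matrix(sample(alpha, C * M, replace = TRUE), nrow = C)
  nb <- cm[rep(seq_len(C), each = npc), , drop = FALSE]
  n <- C * npc
  if (n > 0L) {
    e <- if (k == 1L) rep(1L, n) else sample.int(k, n, replace = TRUE)
    for (edit in seq_len(max(e))) {
      todo <- which(e >= edit)
      # positions are redrawn until distinct from this neighbor's earlier
      # edits; with e <= k << M collisions are rare, so resampling is cheap
      if (edit == 1L) {
        pos <- matrix(NA_integer_, nrow = n, ncol = max(e))
      }
      p <- sample.int(M, length(todo), replace = TRUE)
      if (edit > 1L) {
        repeat {
          clash <- vapply(seq_along(todo), function(i)
            p[i] %in% pos[todo[i], seq_len(edit - 1L)], logical(1))
          if (!any(clash)) break
          p[clash] <- sample.int(M, sum(clash), replace = TRUE)
        }
      }
      pos[todo, edit] <- p
      cur <- nb[cbind(todo, p)]
      off <- sample.int(length(alpha) - 1L, length(todo), replace = TRUE)
      nb[cbind(todo, p)] <- alpha[(match(cur, alpha) + off - 1L) %%
                                    length(alpha) + 1L]
    }
  }
  centers <- do.call(paste0, as.data.frame(cm, stringsAsFactors = FALSE))
  neighbors <- if (n > 0L)
    do.call(paste0, as.data.frame(nb, stringsAsFactors = FALSE))
  else character(0)

  ctr_u <- unique(centers)
  ngh_u <- setdiff(unique(neighbors), ctr_u)
  f_ctr <- sample(seq.int(center_freq[1L], center_freq[2L]), length(ctr_u),
                  replace = TRUE)
  f_ngh <- sample(seq.int(neighbor_freq[1L], neighbor_freq[2L]),
                  length(ngh_u), replace = TRUE)
  tab <- structure(
    data.frame(umi = c(ctr_u, ngh_u), count = c(f_ctr, f_ngh),
               stringsAsFactors = FALSE, row.names = NULL),
    umi_length = M, class = c("umi_table", "data.frame"))
  structure(list(table = tab, centers = ctr_u,
                 roles = rep(c("center", "neighbor"),
                             c(length(ctr_u), length(ngh_u))),
                 params = params),
            class = "umi_sim")
}

#' @export
print.umi_sim <- function(x, ...) {
  p <- x$params
  cat("Simulated UMI dataset (C = ", p$n_centers, ", M = ", p$umi_length,
      ", k = ", p$k, ", seed = ", p$seed, "): ",
      nrow(x$table), " unique UMIs (", length(x$centers), " centers)\n",
      sep = "")
  invisible(x)
}

#' Write / read a UMI frequency table as TSV
#'
#' Plain two-column TSV with header \code{sequence}, \code{count}; the
#' round trip is the identity.
#'
#' @param table a \code{umi_table} or \code{umi_sim}.
#' @param path file path.
#' @return \code{write_umi_tsv} returns \code{path} invisibly;
#'   \code{read_umi_tsv} returns a \code{umi_table}.
#' @export
write_umi_tsv <- function(table, path) {
  if (inherits(table, "umi_sim")) table <- table$table
  table <- as_umi_table(table)
  df <- data.frame(sequence = table$umi, count = table$count)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_umi_tsv
#' @export
read_umi_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character"),
                   stringsAsFactors = FALSE)
  if (!all(c("sequence", "count") %in% names(df)))
    stop("expected TSV columns 'sequence' and 'count' in ", path)
  cnt <- suppressWarnings(as.integer(df$count))
  bad <- which(is.na(cnt) | cnt < 1L | is.na(df$sequence) |
                 df$sequence == "")
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, " of ", path)
  as_umi_table(data.frame(umi = df$sequence, count = cnt,
                          stringsAsFactors = FALSE))
}

#' Emit FASTQ or SAM fixture reads from a dataset
#'
#' Materializes a frequency table as raw reads: each UMI appears once per
#' unit of frequency.  In FASTQ mode the read sequence is the UMI itself
#' (the whole-read deduplication convention).  In SAM mode the UMI is
#' appended to the read name after \code{"_"} and the full read set is
#' replicated at each of \code{positions} alignment coordinates, producing
#' a valid single-end, coordinate-sorted SAM v1.6 file (flag 0, MAPQ 60,
#' fully-matched CIGAR, dummy qualities).
#'
#' @param x a \code{umi_sim} or \code{umi_table}.
#' @param path output file path.
#' @param format \code{"fastq"} or \code{"sam"}.
#' @param positions number of distinct alignment coordinates (SAM mode).
#' @param seed optional seed; when given, read order is shuffled within
#'   each coordinate (the grouping result must not depend on read order).
#' @param rname reference sequence name for SAM mode.
#' @return \code{path}, invisibly.
#' @export
emit_fixture_reads <- function(x, path, format = c("fastq", "sam"),
                               positions = 1L, seed = NULL,
                               rname = "chr1") {
  format <- match.arg(format)
  table <- if (inherits(x, "umi_sim")) x$table else as_umi_table(x)
  M <- attr(table, "umi_length")
  umis <- rep(table$umi, table$count)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    if (length(umis)) umis <- sample(umis)
  }
  if (format == "fastq") {
    ids <- if (length(umis)) sprintf("read%06d", seq_along(umis))
           else character(0)
    if (length(umis) == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    reads <- Biostrings::DNAStringSet(umis)
    names(reads) <- ids
    Biostrings::writeXStringSet(
      reads, path, format = "fastq",
      qualities = Biostrings::BStringSet(rep(strrep("I", M), length(umis))))
    return(invisible(path))
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", rname, "\tLN:100000000"))
  recs <- character(0)
  if (length(umis)) {
    for (j in seq_len(positions)) {
      pos <- 100L + (j - 1L) * 1000L
      qname <- sprintf("read%d.%06d_%s", j, seq_along(umis), umis)
      recs <- c(recs, paste(qname, 0L, rname, pos, 60L,
                            paste0(M, "M"), "*", 0L, 0L, umis,
                            strrep("I", M), sep = "\t"))
    }
  }
  writeLines(c(header, recs), path)
  invisible(path)
}
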