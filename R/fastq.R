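#' Deduplicate a FASTQ file by full read sequence
#'
#' Treats each (fixed-length) read sequence as its own UMI: builds one
#' global frequency table over the read sequences, groups it with the
#' chosen algorithm and backend, and writes one read per group.  The
#' emitted read is, among the reads whose sequence equals the group's
#' representative UMI, the one with the highest mean Phred quality (ties
#' broken by file order).  Gzip input is read transparently.
#'
#' @param input,output FASTQ file paths.
#' @param k maximum Hamming distance between directly-linked reads.
#' @param method,backend,epsilon as in [umi_group()].
#' @return invisibly, a list of summary statistics: \code{reads_in},
#'   \code{reads_out}, \code{unique_umis}, \code{n_groups}.
#' @export
dedup_fastq <- function(input, output, k = 1L,
                        method = c("directional", "adjacency", "cluster"),
                        backend = "ngrambk", epsilon = 0.5) {
  method <- match.arg(method)
  if (length(readLines(input, n = 1L)) == 0L) {
    writeLines(character(0), output)
    stats <- list(reads_in = 0L, reads_out = 0L, unique_umis = 0L,
                  n_groups = 0L)
    return(invisible(stats))
  }
  reads <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(input),
    warning = function(w) {
      # ids live in names(); the dropped mcols carry nothing we use
      if (grepl("metadata columns.*dropped", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  seqs <- as.character(reads)
  if (length(unique(nchar(seqs))) > 1L)
    stop("reads have variable lengths; the substitution-only model ",
         "requires fixed-length reads")
  tab <- umi_count(seqs)
  grouping <- umi_group(tab, k = k, method = method, backend = backend,
                        epsilon = epsilon)
  reps <- grouping$umi[grouping$representative]
  # per-read mean Phred score, for picking the best copy of each consensus
  phred <- vapply(as(Biostrings::quality(reads), "IntegerList"),
                  function(q) mean(as.integer(q)), numeric(1))
  keep <- integer(length(reps))
  for (i in seq_along(reps)) {
    cand <- which(seqs == reps[i])
    keep[i] <- cand[choose_consensus_read(rep(0L, length(cand)),
                                          phred[cand])]
  }
  keep <- sort(keep)
  Biostrings::writeQualityScaledXStringSet(reads[keep], output)
  stats <- list(reads_in = length(seqs), reads_out = length(keep),
                unique_umis = nrow(tab), n_groups = n_groups(grouping))
  invisible(stats)
}
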