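#' Extract the UMI from a read name
#'
#' Reads are expected to carry their UMI as the suffix of the read name
#' after the last occurrence of \code{separator} (the convention used by
#' common UMI preprocessing tools, which move the UMI into the header
#' before alignment).
#'
#' @param read_name character vector of read names.
#' @param separator single separator character (default \code{"_"}).
#' @return character vector of UMI strings; \code{NA} where the separator
#'   is absent.
#' @examples
#' extract_umi("READ1_ACGTACGTA")
#' extract_umi("A_B_ACGT")  # last separator wins
#' @export
extract_umi <- function(read_name, separator = "_") {
  stopifnot(is.character(read_name), nchar(separator) == 1L)
  has <- grepl(separator, read_name, fixed = TRUE)
  out <- rep(NA_character_, length(read_name))
  pat <- paste0(".*\\", separator)
  out[has] <- sub(pat, "", read_name[has])
  out
}

# reference-consumed length of a CIGAR string (M/D/N/=/X operations)
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_clip <- function(cigar, side = c("left", "right")) {
  side <- match.arg(side)
  pat <- if (side == "left") "^[0-9]+S" else "[0-9]+S$"
  m <- regexpr(pat, cigar)
  out <- integer(length(cigar))
  out[m > 0L] <- as.integer(sub("S", "", regmatches(cigar, m), fixed = TRUE))
  out
}

#' Alignment coordinate key for UMI deduplication
#'
#' Reads sharing a key are deduplicated together: the key is the reference
#' name, the strand, and — for forward reads — the 5' alignment start, or
#' — for reverse reads — the 3' alignment end (start + reference-consumed
#' CIGAR length - 1).  With \code{soft_clip_aware = TRUE} (the default) the
#' coordinate is additionally un-clipped: leading soft-clipped bases are
#' subtracted from forward starts and trailing ones added to reverse ends,
#' so reads differing only in clipping still share a key.
#'
#' @param rname reference sequence names.
#' @param flag SAM flag values (bit 16 marks reverse strand).
#' @param pos 1-based leftmost alignment positions.
#' @param cigar CIGAR strings.
#' @param soft_clip_aware whether to adjust for soft clips.
#' @return data frame with columns \code{reference}, \code{strand},
#'   \code{position}, and a canonical string \code{key}.
#' @export
sam_coordinate_key <- function(rname, flag, pos, cigar,
                               soft_clip_aware = TRUE) {
  reverse <- bitwAnd(as.integer(flag), 16L) > 0L
  pos <- as.integer(pos)
  reflen <- cigar_ref_length(cigar)
  coord <- ifelse(reverse, pos + reflen - 1L, pos)
  if (soft_clip_aware) {
    coord <- ifelse(reverse, coord + cigar_clip(cigar, "right"),
                    coord - cigar_clip(cigar, "left"))
  }
  strand <- ifelse(reverse, "-", "+")
  data.frame(reference = rname, strand = strand, position = coord,
             key = paste(rname, strand, coord, sep = ":"),
             stringsAsFactors = FALSE)
}

#' Pick the consensus read among copies of a representative UMI
#'
#' Among candidate reads (all carrying the group's representative UMI),
#' selects by highest mapping quality, then highest mean Phred score, then
#' first position in file order.
#'
#' @param mapq integer mapping qualities (use 0 when absent, e.g. FASTQ).
#' @param mean_phred mean per-base Phred scores.
#' @return the index of the chosen candidate.
#' @export
choose_consensus_read <- function(mapq, mean_phred) {
  stopifnot(length(mapq) == length(mean_phred), length(mapq) >= 1L)
  order(-as.numeric(mapq), -as.numeric(mean_phred),
        seq_along(mapq))[1L]
}

# read a SAM (or BAM, via Rsamtools) file into header lines + record lines
read_sam_lines <- function(input) {
  if (grepl("\\.bam$", input, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM input requires the Rsamtools package")
    sam <- Rsamtools::asSam(input, tempfile())
    on.exit(unlink(sam))
    lines <- readLines(sam)
  } else {
    lines <- readLines(input)
  }
  is_hdr <- startsWith(lines, "@")
  list(header = lines[is_hdr], records = lines[!is_hdr])
}

#' Deduplicate a coordinate-keyed SAM/BAM file by UMI
#'
#' Groups reads per alignment coordinate key (see [sam_coordinate_key()])
#' and, independently at each key, collapses the UMIs embedded in the read
#' names with the chosen algorithm and backend, writing one consensus read
#' per UMI group.  The consensus read is selected by [choose_consensus_read()]
#' among the reads carrying the group's representative UMI.  Output is SAM
#' text with the input header plus an \code{@PG} line; every output read is
#' an unmodified input record.
#'
#' @param input path to a SAM file, or a BAM file (converted via
#'   Rsamtools).
#' @param output output SAM path.
#' @param k,method,backend,epsilon as in [umi_group()].
#' @param umi_sep separator before the UMI suffix in read names.
#' @param keep_unmapped pass unmapped reads through to the output
#'   unchanged (default drops them).
#' @param keep_secondary pass secondary/supplementary alignments through
#'   unchanged (default drops them; they never participate in grouping).
#' @param soft_clip_aware see [sam_coordinate_key()].
#' @param missing_umi \code{"drop"} (count, warn and drop reads whose name
#'   has no separator) or \code{"error"}.
#' @return invisibly, summary statistics: \code{reads_in},
#'   \code{reads_out}, \code{positions}, \code{max_unique_umis},
#'   \code{dropped_no_umi}.
#' @export
dedup_bam <- function(input, output, k = 1L,
                      method = c("directional", "adjacency", "cluster"),
                      backend = "ngrambk", epsilon = 0.5, umi_sep = "_",
                      keep_unmapped = FALSE, keep_secondary = FALSE,
                      soft_clip_aware = TRUE,
                      missing_umi = c("drop", "error")) {
  method <- match.arg(method)
  missing_umi <- match.arg(missing_umi)
  sam <- read_sam_lines(input)
  rec <- sam$records
  n_in <- length(rec)
  pg <- paste0("@PG\tID:umidedup\tPN:umidedup\tVN:",
               as.character(packageVersion("umidedup")),
               "\tCL:dedup-bam -k ", k, " --algo ", method,
               " --backend ", backend)
  header <- c(sam$header, pg)
  if (n_in == 0L) {
    writeLines(header, output)
    return(invisible(list(reads_in = 0L, reads_out = 0L, positions = 0L,
                          max_unique_umis = 0L, dropped_no_umi = 0L)))
  }
  fld <- data.table::tstrsplit(rec, "\t", fixed = TRUE, keep = 1:11)
  qname <- fld[[1]]; flag <- as.integer(fld[[2]]); rname <- fld[[3]]
  pos <- as.integer(fld[[4]]); mapq <- as.integer(fld[[5]])
  cigar <- fld[[6]]; qual <- fld[[11]]

  secondary <- bitwAnd(flag, 2304L) > 0L # secondary (256) or suppl. (2048)
  unmapped <- bitwAnd(flag, 4L) > 0L | rname == "*"
  passthrough <- (secondary & keep_secondary) |
    (unmapped & !secondary & keep_unmapped)
  use <- !secondary & !unmapped

  umi <- extract_umi(qname[use], umi_sep)
  if (anyNA(umi)) {
    if (missing_umi == "error")
      stop("read '", qname[use][which(is.na(umi))[1]],
           "' has no UMI suffix (separator '", umi_sep, "')")
    warning(sum(is.na(umi)), " read(s) without a '", umi_sep,
            "'-separated UMI suffix were dropped")
  }
  dropped_no_umi <- sum(is.na(umi))
  idx <- which(use)[!is.na(umi)]
  umi <- umi[!is.na(umi)]
  if (length(umi)) {
    ulen <- nchar(umi)
    if (length(unique(ulen)) > 1L)
      stop("inconsistent UMI length at read '",
           qname[idx][which(ulen != ulen[1])[1]], "'")
  }
  keys <- sam_coordinate_key(rname[idx], flag[idx], pos[idx], cigar[idx],
                             soft_clip_aware)$key
  phred <- vapply(qual[idx], function(q) {
    if (is.na(q) || q == "*") 0 else mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)

  chosen <- integer(0)
  max_uniq <- 0L
  by_key <- split(seq_along(idx), keys)
  for (rows in by_key) {
    tab <- umi_count(umi[rows])
    max_uniq <- max(max_uniq, nrow(tab))
    grouping <- umi_group(tab, k = k, method = method, backend = backend,
                          epsilon = epsilon)
    for (rep_umi in grouping$umi[grouping$representative]) {
      cand <- rows[umi[rows] == rep_umi]
      pick <- choose_consensus_read(mapq[idx][cand], phred[cand])
      chosen <- c(chosen, idx[cand[pick]])
    }
  }
  out_rows <- sort(unique(c(chosen, which(passthrough))))
  writeLines(c(header, rec[out_rows]), output)
  invisible(list(reads_in = n_in, reads_out = length(out_rows),
                 positions = length(by_key), max_unique_umis = max_uniq,
                 dropped_no_umi = dropped_no_umi))
}
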