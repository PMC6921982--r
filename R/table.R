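#' Build a UMI frequency table from observed UMI sequences
#'
#' Counts the number of occurrences of each unique UMI.  The resulting table
#' is the unit of input for index construction and grouping: N (the number
#' of rows) is the number of unique UMIs and \code{count} is the frequency
#' f(v) of each.
#'
#' @param umis character vector of UMI sequences, all of one length, over
#'   A/C/G/T/N (case-insensitive; stored uppercase).
#' @return a \code{umi_table}: a data frame with columns \code{umi} and
#'   \code{count}, one row per unique UMI, ordered by first appearance, with
#'   attribute \code{umi_length}.
#' @examples
#' umi_count(c("AA", "AA", "AT"))
#' @export
umi_count <- function(umis) {
  stopifnot(is.character(umis))
  if (length(umis) == 0L) {
    return(structure(
      data.frame(umi = character(0), count = integer(0),
                 stringsAsFactors = FALSE),
      umi_length = NA_integer_, class = c("umi_table", "data.frame")))
  }
  umis <- toupper(umis)
  lens <- unique(nchar(umis))
  if (length(lens) != 1L)
    stop("all UMIs must share one length; found lengths ",
         paste(sort(lens), collapse = ", "))
  if (any(grepl("[^ACGTN]", umis)))
    stop("UMIs contain characters outside the A/C/G/T/N alphabet")
  first <- !duplicated(umis)
  tab <- table(factor(umis, levels = umis[first]))
  structure(
    data.frame(umi = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL),
    umi_length = lens, class = c("umi_table", "data.frame"))
}

#' Validate or coerce a data frame into a UMI frequency table
#'
#' @param x a data frame with columns \code{umi} (unique, equal-length
#'   sequences) and \code{count} (positive integers), or an existing
#'   \code{umi_table}.
#' @return a validated \code{umi_table}.
#' @export
as_umi_table <- function(x) {
  if (inherits(x, "umi_table")) return(x)
  stopifnot(is.data.frame(x), all(c("umi", "count") %in% names(x)))
  umi <- toupper(as.character(x$umi))
  count <- as.integer(x$count)
  if (anyNA(count) || any(count < 1L))
    stop("all counts must be positive integers")
  if (anyDuplicated(umi))
    stop("duplicate UMI sequences in table")
  lens <- unique(nchar(umi))
  if (length(lens) > 1L)
    stop("all UMIs must share one length; found lengths ",
         paste(sort(lens), collapse = ", "))
  if (length(umi) && any(grepl("[^ACGTN]", umi)))
    stop("UMIs contain characters outside the A/C/G/T/N alphabet")
  structure(
    data.frame(umi = umi, count = count, stringsAsFactors = FALSE,
               row.names = NULL),
    umi_length = if (length(lens)) lens else NA_integer_,
    class = c("umi_table", "data.frame"))
}

#' @export
print.umi_table <- function(x, ...) {
  cat("UMI frequency table: ", nrow(x), " unique UMIs",
      if (nrow(x)) paste0(" of length ", attr(x, "umi_length")),
      ", ", sum(x$count), " reads\n", sep = "")
  NextMethod()
}
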