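#' Decode a Phred+33 quality string
#'
#' @param qual A single quality string (printable ASCII, codepoints >= 33).
#' @return Integer vector of Phred scores (`codepoint - 33`).
#' @examples
#' phred_decode("II")
#' @export
phred_decode <- function(qual) {
  stopifnot(is.character(qual), length(qual) == 1)
  codes <- utf8ToInt(qual)
  if (any(codes < 33)) {
    data_error("quality character below '!' (not Phred+33)")
  }
  codes - 33L
}

#' Trim reads to length and terminal quality
#'
#' Reads are first truncated to `max_len` bases from the 5' end, then
#' maximal runs of bases with quality below `min_qual` are removed from both
#' ends; interior low-quality bases are retained. Reads shorter than
#' `min_len` after trimming are flagged discarded (an empty read is always
#' discarded).
#'
#' @param reads Read tibble with columns `seq` and `qual` (plus anything
#'   else, carried through).
#' @param max_len Maximum retained length, counted from the 5' end.
#' @param min_qual Terminal bases below this Phred score are removed.
#' @param min_len Reads shorter than this after trimming are discarded
#'   (too short to seed the aligner).
#' @return The tibble with `seq`/`qual` replaced by their trimmed values and
#'   a logical `discarded` column; a per-file style report is attached as
#'   attribute `"report"` (`reads_in`, `discarded`, `mean_len_out`).
#' @examples
#' trim_reads(tibble::tibble(seq = strrep("A", 100), qual = strrep("I", 100)))
#' @export
trim_reads <- function(reads, max_len = 80, min_qual = 30, min_len = 30) {
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  if (max_len < 1) config_error("max_len must be >= 1")
  if (min_qual < 0) config_error("min_qual must be >= 0")
  if (nrow(reads) == 0) {
    out <- mutate(reads, discarded = logical(0))
    attr(out, "report") <- tibble(reads_in = 0L, discarded = 0L,
                                  mean_len_out = NA_real_)
    return(out)
  }
  bounds <- trim_bounds_cpp(reads$qual, as.integer(max_len),
                            as.integer(min_qual))
  start <- bounds[, 1]
  end <- bounds[, 2]
  keep_len <- pmax(0L, end - start + 1L)
  discarded <- keep_len < min_len
  out <- mutate(reads,
                seq = substr(.data$seq, start, end),
                qual = substr(.data$qual, start, end),
                discarded = discarded)
  attr(out, "report") <- tibble(
    reads_in = nrow(reads),
    discarded = sum(discarded),
    mean_len_out = if (all(discarded)) NA_real_ else mean(keep_len[!discarded])
  )
  out
}

#' Trim both mates of a read-pair table
#'
#' Applies [trim_reads()] to each mate; pairs with either mate discarded are
#' dropped so the mates stay synchronized.
#'
#' @param pairs Pair tibble (`name`, `seq1`, `qual1`, `seq2`, `qual2`, ...).
#' @inheritParams trim_reads
#' @return The surviving pairs with trimmed sequences; attribute `"report"`
#'   holds `pairs_in`, `pairs_dropped`, and mean mate lengths out.
#' @export
trim_pairs <- function(pairs, max_len = 80, min_qual = 30, min_len = 30) {
  t1 <- trim_reads(tibble(seq = pairs$seq1, qual = pairs$qual1),
                   max_len, min_qual, min_len)
  t2 <- trim_reads(tibble(seq = pairs$seq2, qual = pairs$qual2),
                   max_len, min_qual, min_len)
  keep <- !t1$discarded & !t2$discarded
  out <- pairs
  out$seq1 <- t1$seq
  out$qual1 <- t1$qual
  out$seq2 <- t2$seq
  out$qual2 <- t2$qual
  out <- out[keep, , drop = FALSE]
  attr(out, "report") <- tibble(
    pairs_in = nrow(pairs),
    pairs_dropped = sum(!keep),
    mean_len1 = if (any(keep)) mean(nchar(out$seq1)) else NA_real_,
    mean_len2 = if (any(keep)) mean(nchar(out$seq2)) else NA_real_
  )
  out
}

#' Write a trimming report
#'
#' @param trimmed Output of [trim_reads()] or [trim_pairs()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_trim_report <- function(trimmed, path) {
  report <- attr(trimmed, "report")
  if (is.null(report)) data_error("no trimming report attached")
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
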