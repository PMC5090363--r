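#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet (case
#' preserved for lower-case input).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp_dna("ACGT")
#' @export
revcomp_dna <- function(x) {
  flipped <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

config_error <- function(msg) {
  abort(msg, class = "bisulfitr_config_error")
}

data_error <- function(msg) {
  abort(msg, class = "bisulfitr_data_error")
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    config_error(sprintf("%s must be a probability in [0, 1]", what))
  }
  invisible(x)
}

# derive a distinct 32-bit sub-seed for each pipeline stage from one master
# seed, so stages stay independently reproducible
stage_seed <- function(seed, stage) {
  offsets <- c(reference = 11L, methylation = 23L, wgbs = 37L, trna = 53L)
  (as.integer(seed) + offsets[[stage]] * 1009L) %% .Machine$integer.max
}
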