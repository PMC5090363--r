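#' Per-cytosine pileup of non-conversion counts
#'
#' For every reference cytosine covered by uniquely mapping proper pairs,
#' counts unconverted (C on Watson for original-top reads; G on Watson,
#' i.e. C on Crick, for original-bottom reads) versus converted (T / A)
#' informative bases. Bases matching neither informative letter are
#' ignored; overlapping mates of one pair are counted once, mate 1 taking
#' precedence. Strand separation is structural: original-top reads can only
#' ever contribute to Watson cytosines and original-bottom reads to Crick
#' cytosines.
#'
#' @param aln Alignment tibble from [align_pairs()] or [read_sam()]
#'   (non-unique or improper rows are dropped).
#' @param genome The `bs_genome` aligned against.
#' @return A tibble of cytosine sites with columns `component`, `pos0`
#'   (0-based Watson coordinate), `strand` (`"+"` Watson C / `"-"` Crick
#'   C), `dinucleotide` (`CpA`..`CpT`, `CpN` at sequence ends), `context`
#'   (`CpG`, `CHG`, `CHH` or `NA` at ends), `n_unconverted`, `n_converted`,
#'   `coverage`, `ratio`. Only sites with coverage >= 1 are emitted.
#' @examples
#' g <- build_reference(reference_spec("chr", 5000), seed = 1)
#' tr <- assign_methylation(g, methylation_model("chr"), seed = 1)
#' reads <- simulate_wgbs(g, tr, bisulfite_params(depth = 2), seed = 1)
#' sites <- pileup(align_pairs(reads, build_bs_index(g)), g)
#' @export
pileup <- function(aln, genome) {
  stopifnot(inherits(genome, "bs_genome"))
  aln <- filter_alignments(aln)
  unknown <- setdiff(unique(aln$component), names(genome$seq))
  if (length(unknown) > 0) {
    data_error(paste0("alignment references unknown component(s): ",
                      paste(unknown, collapse = ", ")))
  }
  if (nrow(aln) == 0) {
    return(tibble(component = character(0), pos0 = integer(0),
                  strand = character(0), dinucleotide = character(0),
                  context = character(0), n_unconverted = integer(0),
                  n_converted = integer(0), coverage = integer(0),
                  ratio = numeric(0)))
  }
  ot <- aln$strand == "+"
  w1 <- ifelse(ot, aln$seq1, revcomp_dna(aln$seq1))
  w2 <- ifelse(ot, revcomp_dna(aln$seq2), aln$seq2)
  comp_idx <- match(aln$component, names(genome$seq))
  counts <- pileup_cpp(unname(genome$seq), comp_idx, ot,
                       aln$pos1, w1, aln$pos2, w2)
  sites <- lapply(seq_along(genome$seq), function(c) {
    unconv <- counts[[c]]$unconverted
    conv <- counts[[c]]$converted
    cov <- unconv + conv
    covered <- which(cov > 0)
    if (length(covered) == 0) return(NULL)
    bytes <- charToRaw(genome$seq[[c]])[covered]
    tibble(component = names(genome$seq)[c],
           pos0 = covered - 1L,
           strand = ifelse(bytes == as.raw(67), "+", "-"),
           n_unconverted = unconv[covered],
           n_converted = conv[covered],
           coverage = cov[covered],
           ratio = unconv[covered] / cov[covered])
  })
  sites <- bind_rows(sites)
  if (nrow(sites) == 0) {
    return(tibble(component = character(0), pos0 = integer(0),
                  strand = character(0), dinucleotide = character(0),
                  context = character(0), n_unconverted = integer(0),
                  n_converted = integer(0), coverage = integer(0),
                  ratio = numeric(0)))
  }
  ctx <- annotate_context(genome, sites$component, sites$pos0, sites$strand)
  out <- mutate(sites, dinucleotide = ctx$dinucleotide, context = ctx$context)
  select(out, "component", "pos0", "strand", "dinucleotide", "context",
         "n_unconverted", "n_converted", "coverage", "ratio")
}

#' Annotate the sequence context of reference cytosines
#'
#' The dinucleotide is the cytosine plus the next base in its own 5'-to-3'
#' direction (read from the reverse complement for Crick-strand cytosines);
#' the trinucleotide class is `CpG`, `CHG` or `CHH` from the two following
#' bases. Cytosines too close to a sequence end get dinucleotide `CpN`
#' and/or class `NA` and are excluded from context tables.
#'
#' @param genome A `bs_genome`.
#' @param component,pos0,strand Parallel vectors identifying cytosines
#'   (0-based Watson coordinate; strand `"+"`/`"-"`).
#' @return A tibble with `dinucleotide` and `context` columns.
#' @examples
#' g <- as_bs_genome(c(chr = "ACGT"))
#' annotate_context(g, "chr", 1L, "+")
#' @export
annotate_context <- function(genome, component, pos0, strand) {
  stopifnot(inherits(genome, "bs_genome"))
  n <- length(pos0)
  stopifnot(length(component) == n, length(strand) == n)
  base_at <- function(comp, p) {
    # per-position lookup, NA outside the sequence
    out <- rep(NA_character_, length(p))
    ok <- !is.na(p) & p >= 0
    lens <- nchar(genome$seq)[comp]
    ok <- ok & p < lens
    out[ok] <- substr(genome$seq[comp[ok]], p[ok] + 1L, p[ok] + 1L)
    out
  }
  here <- base_at(component, pos0)
  plus <- strand == "+"
  bad <- (plus & here != "C") | (!plus & here != "G")
  if (any(bad, na.rm = TRUE) || anyNA(here)) {
    data_error("position is not a cytosine on the given strand")
  }
  nxt_pos <- ifelse(plus, pos0 + 1L, pos0 - 1L)
  thr_pos <- ifelse(plus, pos0 + 2L, pos0 - 2L)
  nxt <- base_at(component, nxt_pos)
  thr <- base_at(component, thr_pos)
  flip <- function(b) chartr("ACGT", "TGCA", b)
  nxt <- ifelse(plus, nxt, flip(nxt))
  thr <- ifelse(plus, thr, flip(thr))
  dinucleotide <- paste0("Cp", ifelse(is.na(nxt) | !nxt %in% c("A", "C", "G", "T"),
                                      "N", nxt))
  context <- dplyr::case_when(
    dinucleotide == "CpN" ~ NA_character_,
    nxt == "G" ~ "CpG",
    is.na(thr) ~ NA_character_,
    thr == "G" ~ "CHG",
    TRUE ~ "CHH"
  )
  tibble(dinucleotide = dinucleotide, context = context)
}

#' Call methylated (unconverted) cytosines
#'
#' A site is called methylated only when covered by at least `min_reads`
#' informative reads (the ">3 reads" rule by default) and its
#' non-conversion ratio exceeds `call_ratio`. These called sites are the
#' "unconverted cytosines" entering dinucleotide context tables.
#'
#' @param sites Site tibble from [pileup()].
#' @param min_reads Minimum informative coverage (default 4, i.e. more than
#'   3 reads).
#' @param call_ratio Non-conversion ratio strictly above which a covered
#'   site is called.
#' @return The called subset of `sites`.
#' @examples
#' call_methylated(tibble::tibble(coverage = c(3, 4), ratio = c(1, 1)))
#' @export
call_methylated <- function(sites, min_reads = 4, call_ratio = 0.5) {
  if (min_reads < 1) config_error("min_reads must be >= 1")
  stopifnot_prob(call_ratio, "call_ratio")
  filter(sites, .data$coverage >= min_reads, .data$ratio > call_ratio)
}

#' Read and write per-site methylation tables
#'
#' TSV with 1-based positions (`pos1`) in files and the fixed column order
#' `component`, `pos1`, `strand`, `dinucleotide`, `context`,
#' `n_unconverted`, `n_converted`, `coverage`, `ratio`. Leading `#` lines
#' carry metadata.
#'
#' @param sites Site tibble from [pileup()].
#' @param path TSV path.
#' @param comments Character vector written as leading `#` lines.
#' @return `read_sites()` returns the site tibble (0-based `pos0` restored);
#'   `write_sites()` returns `path` invisibly.
#' @export
write_sites <- function(sites, path, comments = character(0)) {
  out <- mutate(sites, pos1 = .data$pos0 + 1L)
  out <- select(out, "component", "pos1", "strand", "dinucleotide",
                "context", "n_unconverted", "n_converted", "coverage",
                "ratio")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste0("# ", comments), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  raw <- as_tibble(utils::read.delim(path, comment.char = "#",
                                     stringsAsFactors = FALSE))
  out <- mutate(raw, pos0 = .data$pos1 - 1L,
                strand = as.character(.data$strand))
  select(out, "component", "pos0", "strand", "dinucleotide", "context",
         "n_unconverted", "n_converted", "coverage", "ratio")
}
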