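#' Build a bisulfite alignment index
#'
#' Indexes both reduced-alphabet copies of the genome: the C-to-T reduction
#' searched by original-top reads and the G-to-A reduction searched by
#' original-bottom reads. Seeds are exact k-mers over each reduction.
#'
#' @param genome A `bs_genome`.
#' @param k Seed length (>= 8).
#' @return A `bs_index` object.
#' @examples
#' g <- build_reference(reference_spec("chr", 2000), seed = 1)
#' idx <- build_bs_index(g)
#' @export
build_bs_index <- function(genome, k = 16) {
  stopifnot(inherits(genome, "bs_genome"))
  if (length(genome$seq) == 0 || all(nchar(genome$seq) == 0)) {
    config_error("cannot index an empty genome")
  }
  if (k < 8) config_error("seed length k must be >= 8")
  if (k > 31) config_error("seed length k must be <= 31")
  structure(list(index = build_index_cpp(unname(genome$seq), as.integer(k)),
                 components = genome$components$component,
                 k = as.integer(k)),
            class = "bs_index")
}

#' @export
print.bs_index <- function(x, ...) {
  cat("<bs_index> k =", x$k, "over", length(x$components),
      "component(s):", paste(x$components, collapse = ", "), "\n")
  invisible(x)
}

#' Align trimmed read pairs to the bisulfite index
#'
#' Seed-and-extend paired-end alignment over the three-letter reductions.
#' Mate 1 is searched C-to-T-reduced against the C-to-T reference
#' (original-top) and, reverse-complemented and G-to-A-reduced, against the
#' G-to-A reference (original-bottom); mate 2 is searched in the matching
#' complementary form. Candidate loci from exact k-mer seeds are extended
#' without gaps, mismatches counted in the reduced alphabet. The
#' best-scoring proper pair (both mates within `max_mismatches`, insert in
#' `insert_window`, FR orientation) is reported; a pair is `unique` only
#' when exactly one placement attains the best score — ties are never
#' broken.
#'
#' @param pairs Trimmed pair tibble (`name`, `seq1`, `seq2`, optionally
#'   quality columns, carried through).
#' @param index A [build_bs_index()] result.
#' @param max_mismatches Per-mate reduced-alphabet mismatch cap.
#' @param insert_window Length-2 numeric, accepted insert range.
#' @param max_seeds Maximum non-overlapping seeds tried per mate.
#' @param max_hits Seeds occurring more often than this are skipped as
#'   repetitive.
#' @return The input tibble extended with `mapped`, `unique`, `proper`,
#'   `component`, `strand` (`"+"` original-top / `"-"` original-bottom),
#'   `pos1`, `pos2` (0-based Watson leftmost of each mate), `nm1`, `nm2`,
#'   `n_best`. An alignment summary tibble is attached as attribute
#'   `"report"`.
#' @examples
#' g <- build_reference(reference_spec("chr", 5000), seed = 1)
#' tr <- assign_methylation(g, methylation_model("chr"), seed = 1)
#' reads <- simulate_wgbs(g, tr, bisulfite_params(depth = 1), seed = 1)
#' aln <- align_pairs(reads, build_bs_index(g))
#' @export
align_pairs <- function(pairs, index, max_mismatches = 4,
                        insert_window = c(80, 600), max_seeds = 8,
                        max_hits = 256) {
  stopifnot(inherits(index, "bs_index"))
  if (any(nchar(pairs$seq1) == 0 | nchar(pairs$seq2) == 0)) {
    config_error("align_pairs requires non-empty mates; trim first")
  }
  res <- align_pairs_cpp(index$index, pairs$seq1, pairs$seq2,
                         as.integer(max_mismatches),
                         as.integer(insert_window[1]),
                         as.integer(insert_window[2]),
                         as.integer(max_seeds), as.integer(max_hits))
  out <- mutate(pairs,
                mapped = res$mapped,
                unique = res$unique,
                proper = res$mapped,  # only proper pairs are ever reported
                component = index$components[res$comp],
                strand = dplyr::case_when(is.na(res$ot) ~ NA_character_,
                                          res$ot ~ "+", TRUE ~ "-"),
                pos1 = res$p1, pos2 = res$p2,
                nm1 = res$nm1, nm2 = res$nm2, n_best = res$n_best)
  attr(out, "report") <- tibble(
    pairs_in = nrow(pairs),
    mapped = sum(res$mapped),
    unique_proper = sum(res$mapped & res$unique)
  )
  out
}

#' Keep only uniquely mapping proper pairs
#'
#' The downstream filter of the pipeline: only reads mapping uniquely and
#' with both mates at the correct distance enter methylation calling.
#'
#' @param aln Alignment tibble from [align_pairs()].
#' @return The unique proper subset.
#' @export
filter_alignments <- function(aln) {
  filter(aln, .data$mapped, .data$unique, .data$proper)
}

#' Exhaustive alignment oracle for a single read
#'
#' Scores every position of every component on both bisulfite strands with
#' reduced-alphabet mismatch counting (mate-1 semantics: C-to-T forward for
#' original-top, reverse-complemented G-to-A for original-bottom) and
#' returns all minimal-mismatch placements. Intended as a brute-force
#' reference for the seed-and-extend aligner on small genomes.
#'
#' @param read A single read sequence.
#' @param genome A `bs_genome`.
#' @return Tibble of best placements: `component`, `pos` (0-based),
#'   `strand`, `mm`.
#' @export
brute_force_align <- function(read, genome) {
  stopifnot(inherits(genome, "bs_genome"), is.character(read),
            length(read) == 1)
  if (nchar(read) > max(nchar(genome$seq))) {
    config_error("read longer than every component")
  }
  res <- brute_force_cpp(unname(genome$seq), read)
  tibble(component = genome$components$component[res$comp],
         pos = res$pos, strand = res$strand, mm = res$mm)
}

sam_quote <- function(x) gsub("[ \t]", "_", x)

#' Write alignments as SAM
#'
#' Plain-text SAM with `@SQ` header lines, two records per unique proper
#' pair, 1-based positions, ungapped CIGAR, the bisulfite strand in `ZS:Z`
#' (`+` original-top, `-` original-bottom) and per-mate mismatches in
#' `NM:i`. SEQ is written in Watson (reference) orientation with qualities
#' reversed to match, as aligners emit it.
#'
#' @param aln Alignment tibble from [align_pairs()] (filtered or not; only
#'   unique proper pairs are written).
#' @param genome The `bs_genome` aligned against.
#' @param path Output path.
#' @param extra_header Character vector of additional header lines
#'   (e.g. `@CO` comments).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, genome, path, extra_header = character(0)) {
  aln <- filter_alignments(aln)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seq),
                      nchar(genome$seq)),
              "@PG\tID:bisulfitr\tPN:bisulfitr",
              extra_header)
  if (nrow(aln) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  ot <- aln$strand == "+"
  len1 <- nchar(aln$seq1)
  len2 <- nchar(aln$seq2)
  # Watson-orientation sequence and matching quality per mate
  w1 <- ifelse(ot, aln$seq1, revcomp_dna(aln$seq1))
  w2 <- ifelse(ot, revcomp_dna(aln$seq2), aln$seq2)
  has_q <- all(c("qual1", "qual2") %in% names(aln))
  rev_str <- function(x) vapply(strsplit(x, "", fixed = TRUE),
                                function(ch) paste(rev(ch), collapse = ""),
                                character(1))
  q1 <- if (has_q) ifelse(ot, aln$qual1, rev_str(aln$qual1)) else
    strrep("*", 1)[rep(1, nrow(aln))]
  q2 <- if (has_q) ifelse(ot, rev_str(aln$qual2), aln$qual2) else
    strrep("*", 1)[rep(1, nrow(aln))]
  insert <- ifelse(ot, aln$pos2 + len2 - aln$pos1,
                   aln$pos1 + len1 - aln$pos2)
  # FR orientation: the left-hand mate is forward; flags per mate
  flag1 <- ifelse(ot, 99L, 83L)
  flag2 <- ifelse(ot, 147L, 163L)
  tlen1 <- ifelse(ot, insert, -insert)
  rec <- function(name, flag, pos0, cigar_len, seq, qual, mate_pos0, tlen,
                  nm, zs) {
    paste(sam_quote(name), flag, aln$component, pos0 + 1L, 40L,
          sprintf("%dM", cigar_len), "=", mate_pos0 + 1L, tlen, seq, qual,
          sprintf("ZS:Z:%s", zs), sprintf("NM:i:%d", nm), sep = "\t")
  }
  lines1 <- rec(aln$name, flag1, aln$pos1, len1, w1, q1, aln$pos2, tlen1,
                aln$nm1, aln$strand)
  lines2 <- rec(aln$name, flag2, aln$pos2, len2, w2, q2, aln$pos1, -tlen1,
                aln$nm2, aln$strand)
  body <- as.vector(rbind(lines1, lines2))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a bisulfitr-style SAM file back into an alignment tibble
#'
#' Parses the mandatory SAM columns plus the `ZS` (bisulfite strand) and
#' `NM` tags written by [write_sam()], re-pairing mates by name. SEQ
#' columns are converted back to sequenced orientation.
#'
#' @param path SAM path.
#' @return An alignment tibble equivalent to a filtered [align_pairs()]
#'   result (columns `name`, `seq1`, `seq2`, `mapped`, `unique`, `proper`,
#'   `component`, `strand`, `pos1`, `pos2`, `nm1`, `nm2`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) {
    return(tibble(name = character(0), seq1 = character(0),
                  seq2 = character(0), mapped = logical(0),
                  unique = logical(0), proper = logical(0),
                  component = character(0), strand = character(0),
                  pos1 = integer(0), pos2 = integer(0),
                  nm1 = integer(0), nm2 = integer(0)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  tag <- function(prefix) {
    vapply(f, function(x) {
      hit <- x[startsWith(x, prefix)]
      if (length(hit) == 0) NA_character_ else sub(prefix, "", hit[1])
    }, character(1))
  }
  flag <- as.integer(get(2))
  rec <- tibble(
    name = get(1), flag = flag, component = get(3),
    pos0 = as.integer(get(4)) - 1L, wseq = get(10),
    strand = tag("ZS:Z:"), nm = as.integer(tag("NM:i:")),
    first = bitwAnd(flag, 64L) > 0
  )
  m1 <- filter(rec, .data$first)
  m2 <- filter(rec, !.data$first)
  m2 <- m2[match(m1$name, m2$name), ]
  if (anyNA(m2$name)) data_error("SAM file has unpaired records")
  ot <- m1$strand == "+"
  tibble(
    name = m1$name,
    seq1 = ifelse(ot, m1$wseq, revcomp_dna(m1$wseq)),
    seq2 = ifelse(ot, revcomp_dna(m2$wseq), m2$wseq),
    mapped = TRUE, unique = TRUE, proper = TRUE,
    component = m1$component, strand = m1$strand,
    pos1 = m1$pos0, pos2 = m2$pos0, nm1 = m1$nm, nm2 = m2$nm
  )
}
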