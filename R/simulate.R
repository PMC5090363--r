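#' Bisulfite library and sequencing parameters
#'
#' @param failure_rate Probability an unmethylated C escapes conversion and
#'   still reads as C. Estimated in real libraries from the unmethylated
#'   spike; default 0.002 is a typical modern library.
#' @param overconversion_rate Probability a methylated C converts anyway and
#'   reads as T.
#' @param seq_error_rate Per-base substitution error rate.
#' @param read_length Mate length in bp.
#' @param insert_mean,insert_sd Fragment (insert) length distribution;
#'   truncated normal bounded below by `read_length`.
#' @param depth Mean informative coverage of a cytosine site, i.e. the mean
#'   per-base depth contributed by reads of that site's own bisulfite
#'   strand. This matches how WGBS coverage at cytosines is reported
#'   (for example "26x CpG coverage"); the total number of simulated pairs
#'   is `depth * genome_length / read_length`, half per strand.
#' @param qual Constant Phred quality written for every base.
#' @return A validated list of class `bisulfite_params`.
#' @examples
#' bisulfite_params(depth = 5)
#' @export
bisulfite_params <- function(failure_rate = 0.002, overconversion_rate = 0,
                             seq_error_rate = 0, read_length = 80,
                             insert_mean = 250, insert_sd = 40, depth = 26,
                             qual = 37) {
  stopifnot_prob(failure_rate, "failure_rate")
  stopifnot_prob(overconversion_rate, "overconversion_rate")
  stopifnot_prob(seq_error_rate, "seq_error_rate")
  if (depth <= 0) config_error("depth must be > 0")
  if (read_length < 1) config_error("read_length must be >= 1")
  if (read_length > insert_mean) {
    config_error("read_length must not exceed insert_mean")
  }
  if (qual < 0 || qual > 60) config_error("qual must be a Phred score in [0, 60]")
  structure(list(failure_rate = failure_rate,
                 overconversion_rate = overconversion_rate,
                 seq_error_rate = seq_error_rate,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 depth = depth, qual = as.integer(qual)),
            class = "bisulfite_params")
}

#' Simulate a directional paired-end WGBS library
#'
#' Draws fragments from the genome (components weighted by their mass
#' fraction), assigns each to the original-top or original-bottom strand
#' with equal probability, bisulfite-converts the original strand according
#' to the ground truth (unmethylated C reads T except with probability
#' `failure_rate`; methylated C reads C except with probability
#' `overconversion_rate`), then sequences both mates: mate 1 is the 5' end
#' of the converted strand, mate 2 the reverse complement of its 3' end.
#' Read names encode the true origin as `id|component|start0|insert|strand`
#' so alignments can be checked against the simulation.
#'
#' @param genome A `bs_genome`.
#' @param truth Ground truth from [assign_methylation()].
#' @param params A [bisulfite_params()] object.
#' @param seed Integer random seed.
#' @return A tibble of read pairs: `name`, `seq1`, `qual1`, `seq2`, `qual2`,
#'   plus origin columns `component`, `start0`, `insert`, `strand`
#'   (`"+"` original-top, `"-"` original-bottom).
#' @examples
#' g <- build_reference(reference_spec("chr", 5000), seed = 1)
#' tr <- assign_methylation(g, methylation_model("chr"), seed = 1)
#' reads <- simulate_wgbs(g, tr, bisulfite_params(depth = 2), seed = 1)
#' @export
simulate_wgbs <- function(genome, truth, params = bisulfite_params(),
                          seed = 1) {
  stopifnot(inherits(genome, "bs_genome"),
            inherits(params, "bisulfite_params"))
  comps <- genome$components
  lens <- nchar(genome$seq)
  r <- params$read_length
  if (any(lens < r)) {
    config_error("every component must be at least read_length long")
  }
  set.seed(as.integer(seed))
  total_len <- sum(lens)
  n_pairs <- rpois(1, params$depth * total_len / r)
  if (n_pairs == 0) {
    return(tibble(name = character(0), seq1 = character(0),
                  qual1 = character(0), seq2 = character(0),
                  qual2 = character(0), component = character(0),
                  start0 = integer(0), insert = integer(0),
                  strand = character(0)))
  }
  comp_idx <- sample.int(nrow(comps), n_pairs, replace = TRUE,
                         prob = comps$mass_fraction)
  insert <- pmax(r, pmin(lens[comp_idx],
                         as.integer(round(rnorm(n_pairs, params$insert_mean,
                                                params$insert_sd)))))
  start <- as.integer(floor(runif(n_pairs) * (lens[comp_idx] - insert + 1)))
  is_ot <- runif(n_pairs) < 0.5

  tv <- truth_strand_vectors(genome, truth)
  sim <- simulate_pairs_cpp(unname(genome$seq), comp_idx, start, insert,
                            is_ot, lapply(tv, `[[`, "plus"),
                            lapply(tv, `[[`, "minus"),
                            params$failure_rate, params$overconversion_rate,
                            params$seq_error_rate, r)
  strand <- ifelse(is_ot, "+", "-")
  qual <- strrep(intToUtf8(params$qual + 33L), r)
  tibble(
    name = sprintf("rd%07d|%s|%d|%d|%s", seq_len(n_pairs),
                   comps$component[comp_idx], start, insert, strand),
    seq1 = sim$seq1, qual1 = qual, seq2 = sim$seq2, qual2 = qual,
    component = comps$component[comp_idx],
    start0 = start, insert = insert, strand = strand
  )
}

#' Recover simulated read origins from read names
#'
#' @param name Character vector of simulated read names
#'   (`id|component|start0|insert|strand`).
#' @return A tibble with columns `component`, `start0`, `insert`, `strand`.
#' @export
parse_read_origin <- function(name) {
  parts <- strsplit(name, "|", fixed = TRUE)
  bad <- lengths(parts) != 5
  if (any(bad)) data_error("read name does not encode a simulated origin")
  tibble(
    component = vapply(parts, `[[`, character(1), 2),
    start0 = as.integer(vapply(parts, `[[`, character(1), 3)),
    insert = as.integer(vapply(parts, `[[`, character(1), 4)),
    strand = vapply(parts, `[[`, character(1), 5)
  )
}

#' Read and write FASTQ files
#'
#' Biostrings-backed FASTQ I/O for the package's tibble read representation
#' (`name`, `seq`, `qual`). Paths ending in `.gz` are compressed.
#'
#' @param reads Tibble with columns `name`, `seq`, `qual`.
#' @param path FASTQ path.
#' @return `read_fastq()` returns a read tibble; `write_fastq()` returns
#'   `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  qs <- Biostrings::PhredQuality(reads$qual)
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq), qs)
  names(set) <- reads$name
  Biostrings::writeQualityScaledXStringSet(
    set, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on FASTQ input
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(name = names(set), seq = as.character(set),
         qual = as.character(Biostrings::quality(set)))
}

#' @rdname write_fastq
#' @param pairs A pair tibble (`name`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param prefix Output prefix; mates go to `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (plus `.gz` when `gz = TRUE`).
#' @param gz Compress output.
#' @export
write_fastq_pairs <- function(pairs, prefix, gz = FALSE) {
  ext <- if (gz) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_1", ext)
  p2 <- paste0(prefix, "_2", ext)
  write_fastq(tibble(name = pairs$name, seq = pairs$seq1, qual = pairs$qual1), p1)
  write_fastq(tibble(name = pairs$name, seq = pairs$seq2, qual = pairs$qual2), p2)
  invisible(c(p1, p2))
}

#' @rdname write_fastq
#' @param path1,path2 Mate FASTQ paths.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (nrow(r1) != nrow(r2) || any(r1$name != r2$name)) {
    data_error("mate FASTQ files are not synchronized")
  }
  tibble(name = r1$name, seq1 = r1$seq, qual1 = r1$qual,
         seq2 = r2$seq, qual2 = r2$qual)
}

#' Simulate a tRNA bisulfite amplicon read set
#'
#' Each read independently draws the methylation state of every reference
#' cytosine from `site_probs`; methylated cytosines read C, unmethylated
#' ones T, all other bases are copied. Homopolymer-style indel errors of the
#' 454 chemistry are emulated by deleting or inserting single bases at
#' `indel_rate`.
#'
#' @param ref A [trna_reference()].
#' @param site_probs Named numeric vector of methylation probabilities keyed
#'   by 1-based reference cytosine position (unlisted cytosines default
#'   to 0). Use e.g. `c("38" = 0.95)` for near-complete C38 methylation.
#' @param n_reads Number of reads.
#' @param indel_rate Per-base indel probability (half deletions, half
#'   insertions).
#' @param seed Integer random seed.
#' @return A read tibble (`name`, `seq`, `qual`) with the per-read true
#'   states in attribute `"truth"` (logical matrix reads x cytosines).
#' @examples
#' ref <- example_trna_references()[["tRNA-Gly-synthetic"]]
#' reads <- simulate_trna_amplicon(ref, c("38" = 0.95), n_reads = 20, seed = 1)
#' @export
simulate_trna_amplicon <- function(ref, site_probs = numeric(0),
                                   n_reads = 500, indel_rate = 0, seed = 1) {
  stopifnot(inherits(ref, "trna_reference"))
  stopifnot_prob(unname(site_probs), "site_probs")
  stopifnot_prob(indel_rate, "indel_rate")
  cyt <- ref$cytosine_positions
  probs <- setNames(numeric(length(cyt)), cyt)
  if (length(site_probs) > 0) {
    unknown <- setdiff(names(site_probs), as.character(cyt))
    if (length(unknown) > 0) {
      config_error(paste0("site_probs positions not cytosines in the ",
                          "reference: ", paste(unknown, collapse = ", ")))
    }
    probs[names(site_probs)] <- site_probs
  }
  set.seed(as.integer(seed))
  base <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  truth <- matrix(runif(n_reads * length(cyt)) <
                    rep(probs, each = n_reads),
                  nrow = n_reads, dimnames = list(NULL, names(probs)))
  alphabet <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_reads), function(i) {
    b <- base
    b[cyt] <- ifelse(truth[i, ], "C", "T")
    if (indel_rate > 0) {
      u <- runif(length(b))
      drop <- u < indel_rate / 2
      ins <- u >= indel_rate / 2 & u < indel_rate
      out <- character(0)
      ins_bases <- sample(alphabet, sum(ins), replace = TRUE)
      j <- 0
      for (p in seq_along(b)) {
        if (ins[p]) {
          j <- j + 1
          out <- c(out, ins_bases[j])
        }
        if (!drop[p]) out <- c(out, b[p])
      }
      b <- out
    }
    paste(b, collapse = "")
  }, character(1))
  reads <- tibble(name = sprintf("amp%05d", seq_len(n_reads)), seq = seqs,
                  qual = strrep("I", nchar(seqs)))
  attr(reads, "truth") <- truth
  reads
}
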