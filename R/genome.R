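#' Describe the components of a synthetic reference genome
#'
#' Builds the component table consumed by [build_reference()]. Each row is
#' one genome component (for example a mosquito-genome analog, a
#' lambda-phage-like unmethylated spike, a human-blood-like methylated
#' spike). `mass_fraction` is the fraction of sequenced material contributed
#' by the component and must sum to 1 over the table.
#'
#' @param component Character vector of component names.
#' @param length Integer vector of sequence lengths in bp (>= 1).
#' @param gc Numeric GC fraction in `[0, 1]`.
#' @param cpg_factor Non-negative CpG enrichment factor; 1 leaves the CpG
#'   dinucleotide at its independence expectation `(gc/2)^2`, values above 1
#'   enrich, values below 1 deplete.
#' @param mass_fraction Numeric fractions in `[0, 1]` summing to 1.
#' @return A tibble with one row per component.
#' @examples
#' reference_spec("chr", 1e4)
#' @export
reference_spec <- function(component, length, gc = 0.5, cpg_factor = 1,
                           mass_fraction = 1) {
  spec <- tibble(
    component = as.character(component),
    length = as.integer(length),
    gc = as.numeric(gc),
    cpg_factor = as.numeric(cpg_factor),
    mass_fraction = as.numeric(mass_fraction)
  )
  validate_reference_spec(spec)
}

validate_reference_spec <- function(spec) {
  spec <- as_tibble(spec)
  needed <- c("component", "length", "gc", "cpg_factor", "mass_fraction")
  missing_cols <- setdiff(needed, names(spec))
  if (length(missing_cols) > 0) {
    config_error(paste0("reference spec is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(spec) == 0) config_error("reference spec has no components")
  if (anyDuplicated(spec$component)) {
    config_error("component names must be unique")
  }
  if (any(spec$length < 1)) config_error("component lengths must be >= 1")
  stopifnot_prob(spec$gc, "gc")
  stopifnot_prob(spec$mass_fraction, "mass_fraction")
  if (any(spec$cpg_factor < 0)) config_error("cpg_factor must be >= 0")
  if (abs(sum(spec$mass_fraction) - 1) > 1e-6) {
    config_error("mass_fraction values must sum to 1")
  }
  spec
}

#' The three-genome spike-in design
#'
#' A ready-made [reference_spec()] emulating a WGBS spike-in experiment:
#' a large unmethylated genome (91% of the sequenced mass), a ~48.5 kb
#' unmethylated lambda-like negative control (1% by mass), and a
#' CpG-methylated human-like positive control (8% by mass). Component
#' lengths other than the lambda analog are scaled to desk size and
#' configurable.
#'
#' @param main_length Length of the main (mosquito-analog) component in bp.
#' @param human_length Length of the positive-control component in bp.
#' @param human_cpg_factor CpG enrichment factor of the positive control;
#'   vertebrate genomes are CpG-depleted genome-wide but the methylated
#'   fraction concentrates at CpG, so the default keeps enrichment neutral.
#' @return A reference spec tibble with components `main`, `lambda`, `human`.
#' @examples
#' spike_in_design(main_length = 50000)
#' @export
spike_in_design <- function(main_length = 200000, human_length = 30000,
                            human_cpg_factor = 1) {
  reference_spec(
    component = c("main", "lambda", "human"),
    length = c(main_length, 48502L, human_length),
    gc = c(0.38, 0.50, 0.41),
    cpg_factor = c(1, 1, human_cpg_factor),
    mass_fraction = c(0.91, 0.01, 0.08)
  )
}

#' Generate a synthetic reference genome
#'
#' Draws one random sequence per component of a [reference_spec()] using a
#' first-order Markov model: bases are sampled i.i.d. from the GC-determined
#' composition except following a C, where the G transition probability is
#' scaled by `cpg_factor` (and the remaining bases renormalised), so the
#' realised CpG dinucleotide frequency responds monotonically to the factor.
#' Output is reproducible for a given seed.
#'
#' @param spec A reference spec tibble (see [reference_spec()]).
#' @param seed Integer random seed.
#' @return A `bs_genome` object: named component sequences plus the spec.
#' @examples
#' g <- build_reference(reference_spec("chr", 2000), seed = 1)
#' nchar(g$seq)
#' @export
build_reference <- function(spec, seed = 1) {
  spec <- validate_reference_spec(spec)
  set.seed(as.integer(seed))
  seqs <- vapply(seq_len(nrow(spec)), function(i) {
    gc <- spec$gc[i]
    p_base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    pg <- min(0.95, spec$cpg_factor[i] * gc / 2)
    rest <- p_base[c("A", "C", "T")]
    scale <- if (sum(rest) > 0) (1 - pg) / sum(rest) else 0
    p_after_c <- c(rest[["A"]] * scale, rest[["C"]] * scale, pg,
                   rest[["T"]] * scale)
    markov_seq_cpp(spec$length[i], unname(p_base), p_after_c)
  }, character(1))
  names(seqs) <- spec$component
  structure(list(seq = seqs, components = spec, seed = as.integer(seed)),
            class = "bs_genome")
}

#' @export
print.bs_genome <- function(x, ...) {
  cat("<bs_genome> ", nrow(x$components), " component(s), ",
      format(sum(nchar(x$seq)), big.mark = ","), " bp total\n", sep = "")
  print(mutate(x$components, realized_length = unname(nchar(x$seq))))
  invisible(x)
}

#' Wrap named sequences as a genome object
#'
#' Builds a `bs_genome` from a named character vector of sequences, e.g.
#' user-provided references that were not simulated. Mass fractions default
#' to equal shares and only matter for simulation.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param mass_fraction Optional numeric vector of sequenced-mass fractions.
#' @return A `bs_genome` object.
#' @examples
#' as_bs_genome(c(chr = "ACGTACGT"))
#' @export
as_bs_genome <- function(seqs, mass_fraction = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    config_error("genome sequences must have unique names")
  }
  n <- length(seqs)
  mf <- mass_fraction %||% rep(1 / n, n)
  spec <- tibble(component = names(seqs), length = nchar(seqs),
                 gc = NA_real_, cpg_factor = NA_real_, mass_fraction = mf)
  structure(list(seq = seqs, components = spec, seed = NA_integer_),
            class = "bs_genome")
}

#' Read and write reference FASTA files
#'
#' Thin wrappers around Biostrings FASTA I/O, keeping the package's
#' character-vector genome representation. `write_fasta()` wraps lines at
#' 70 columns.
#'
#' @param genome A `bs_genome` object (or named character vector for
#'   `write_fasta()`).
#' @param path File path.
#' @param mass_fraction Optional per-component mass fractions attached when
#'   reading (defaults to equal shares).
#' @return `read_fasta()` returns a `bs_genome`; `write_fasta()` returns
#'   `path` invisibly.
#' @export
write_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "bs_genome")) genome$seq else genome
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, mass_fraction = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  as_bs_genome(seqs, mass_fraction)
}
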