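# Shared fixture builders. Everything is generated in code at test time.

# a small single-component simulation run through the full pipeline
sim_pipeline <- function(length = 20000, gc = 0.5, p_cpg = 0, p_non_cpg = 0,
                         failure_rate = 0.002, overconversion_rate = 0,
                         seq_error_rate = 0, depth = 10, seed = 42,
                         component = "chr") {
  g <- build_reference(reference_spec(component, length, gc = gc), seed = seed)
  truth <- assign_methylation(
    g, methylation_model(component, p_cpg = p_cpg, p_non_cpg = p_non_cpg),
    seed = seed + 1)
  params <- bisulfite_params(failure_rate = failure_rate,
                             overconversion_rate = overconversion_rate,
                             seq_error_rate = seq_error_rate, depth = depth)
  pairs <- simulate_wgbs(g, truth, params, seed = seed + 2)
  trimmed <- trim_pairs(pairs)
  aln <- align_pairs(trimmed, build_bs_index(g),
                     insert_window = c(params$read_length,
                                       params$insert_mean + 4 * params$insert_sd))
  sites <- pileup(aln, g)
  list(genome = g, truth = truth, params = params, pairs = pairs,
       aln = aln, sites = sites)
}

# a hand-built alignment row in the tibble layout align_pairs() emits;
# mates are given in sequenced orientation
aln_row <- function(name, component, strand, pos1, seq1, pos2, seq2) {
  tibble::tibble(name = name, seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
                 seq2 = seq2, qual2 = strrep("I", nchar(seq2)),
                 mapped = TRUE, unique = TRUE, proper = TRUE,
                 component = component, strand = strand,
                 pos1 = as.integer(pos1), pos2 = as.integer(pos2),
                 nm1 = 0L, nm2 = 0L, n_best = 1L)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
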