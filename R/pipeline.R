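#' Configure the WGBS pipeline
#'
#' Collects every stage's parameters into one validated object. Either a
#' reference spec (to simulate) or FASTA/FASTQ paths (to analyse existing
#' files) can drive the run.
#'
#' @param spec [reference_spec()] tibble used to simulate the genome, or
#'   `NULL` when `fasta` is given.
#' @param model [methylation_model()] tibble (simulation only).
#' @param params [bisulfite_params()] (simulation only).
#' @param fasta Optional path to an existing reference FASTA.
#' @param fastq1,fastq2 Optional paths to existing mate FASTQ files.
#' @param trim_max_len,trim_min_qual,trim_min_len Trimming thresholds
#'   (80 bp cap, Phred 30 terminal trim, 30 bp minimum by default).
#' @param k,max_mismatches Aligner seed length and per-mate mismatch cap.
#' @param insert_window Accepted insert range; `NULL` derives
#'   `[read_length, insert_mean + 4 * insert_sd]` from `params`.
#' @param min_reads,call_ratio Calling thresholds (">3 reads", ratio > 0.5).
#' @param n_bins Ratio histogram bins.
#' @param negative_control Component treated as the unmethylated spike.
#' @param outdir Output directory (created if needed); `NULL` for none.
#' @param seed Global seed; recorded in every output header.
#' @return A `wgbs_config` list.
#' @examples
#' cfg <- wgbs_config(spec = spike_in_design(main_length = 20000),
#'                    model = spike_in_model(),
#'                    params = bisulfite_params(depth = 4), seed = 7)
#' @export
wgbs_config <- function(spec = NULL, model = NULL,
                        params = bisulfite_params(), fasta = NULL,
                        fastq1 = NULL, fastq2 = NULL, trim_max_len = 80,
                        trim_min_qual = 30, trim_min_len = 30, k = 16,
                        max_mismatches = 4, insert_window = NULL,
                        min_reads = 4, call_ratio = 0.5, n_bins = 10,
                        negative_control = NULL, outdir = NULL, seed = 1) {
  if (is.null(spec) && is.null(fasta)) {
    config_error("either a reference spec or a FASTA path is required")
  }
  if (!is.null(spec)) spec <- validate_reference_spec(spec)
  if (!inherits(params, "bisulfite_params")) {
    config_error("params must come from bisulfite_params()")
  }
  if (is.null(insert_window)) {
    insert_window <- c(params$read_length,
                       params$insert_mean + 4 * params$insert_sd)
  }
  if (length(insert_window) != 2 || insert_window[1] > insert_window[2]) {
    config_error("insert_window must be an increasing length-2 range")
  }
  if (trim_max_len < 1 || trim_min_qual < 0 || trim_min_len < 1) {
    config_error("trimming thresholds out of range")
  }
  if (min_reads < 1) config_error("min_reads must be >= 1")
  stopifnot_prob(call_ratio, "call_ratio")
  cfg <- list(spec = spec, model = model, params = params, fasta = fasta,
              fastq1 = fastq1, fastq2 = fastq2,
              trim_max_len = trim_max_len, trim_min_qual = trim_min_qual,
              trim_min_len = trim_min_len, k = k,
              max_mismatches = max_mismatches,
              insert_window = insert_window, min_reads = min_reads,
              call_ratio = call_ratio, n_bins = n_bins,
              negative_control = negative_control, outdir = outdir,
              seed = as.integer(seed))
  structure(cfg, class = "wgbs_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML schema mirrors [wgbs_config()]: top-level scalars for the
#' thresholds plus optional mappings `spec` (parallel lists `component`,
#' `length`, `gc`, `cpg_factor`, `mass_fraction`), `model` (`component`,
#' `p_cpg`, `p_non_cpg`) and `params` (fields of [bisulfite_params()]).
#'
#' @param path YAML file path.
#' @return A `wgbs_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$spec)) as_tibble(y$spec) else NULL
  model <- if (!is.null(y$model)) as_tibble(y$model) else NULL
  params <- do.call(bisulfite_params, y$params %||% list())
  args <- y[setdiff(names(y), c("spec", "model", "params"))]
  do.call(wgbs_config, c(list(spec = spec, model = model, params = params),
                         args))
}

config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  rlang::hash(x)
}

#' Run the WGBS pipeline end to end
#'
#' Orchestrates simulate (or load) -> trim -> align -> pileup -> summarise,
#' logging per-stage counts to stderr. When `outdir` is set, writes the
#' reference FASTA, truth TSV, mate FASTQs, SAM alignments, per-site TSV
#' and the summary JSON + TSV, each stamped with the seed and a hash of the
#' configuration; re-running the same configuration reproduces every
#' machine-readable output byte for byte.
#'
#' @param config A [wgbs_config()].
#' @param quiet Suppress progress messages.
#' @return The [methylome_summary()] for the run, with the site tibble in
#'   attribute `"sites"`, the ground truth (when simulating) in `"truth"`,
#'   and output paths in `"files"`.
#' @examples
#' cfg <- wgbs_config(spec = reference_spec("chr", 20000),
#'                    model = methylation_model("chr"),
#'                    params = bisulfite_params(depth = 4), seed = 7)
#' summary <- run_wgbs_pipeline(cfg, quiet = TRUE)
#' @export
run_wgbs_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "wgbs_config")) {
    config_error("config must come from wgbs_config() or read_pipeline_config()")
  }
  say <- function(...) if (!quiet) message("[bisulfitr] ", sprintf(...))
  hash <- config_hash(config)
  stamp <- c(sprintf("seed: %d", config$seed),
             sprintf("config_hash: %s", hash))
  outdir <- config$outdir
  files <- character(0)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  path <- function(name) file.path(outdir, name)

  truth <- NULL
  if (!is.null(config$spec)) {
    say("building reference: %d component(s)", nrow(config$spec))
    genome <- build_reference(config$spec, seed = stage_seed(config$seed,
                                                             "reference"))
    model <- config$model %||%
      methylation_model(config$spec$component)
    truth <- assign_methylation(genome, model,
                                seed = stage_seed(config$seed, "methylation"))
    say("assigned methylation: %d cytosines, %d methylated",
        nrow(truth), sum(truth$methylated))
    pairs <- simulate_wgbs(genome, truth, config$params,
                           seed = stage_seed(config$seed, "wgbs"))
    say("simulated %d read pairs", nrow(pairs))
    if (!is.null(outdir)) {
      files["fasta"] <- write_fasta(genome, path("reference.fasta"))
      files["truth"] <- write_truth(truth, path("truth.tsv"), stamp)
      fq <- write_fastq_pairs(pairs, file.path(outdir, "reads"))
      files["fastq1"] <- fq[1]
      files["fastq2"] <- fq[2]
    }
  } else {
    if (!file.exists(config$fasta)) {
      config_error(paste0("reference FASTA not found: ", config$fasta))
    }
    if (is.null(config$fastq1) || is.null(config$fastq2) ||
        !file.exists(config$fastq1) || !file.exists(config$fastq2)) {
      config_error("mate FASTQ files are required when not simulating")
    }
    genome <- read_fasta(config$fasta)
    pairs <- read_fastq_pairs(config$fastq1, config$fastq2)
    say("loaded %d read pairs", nrow(pairs))
  }

  trimmed <- trim_pairs(pairs, max_len = config$trim_max_len,
                        min_qual = config$trim_min_qual,
                        min_len = config$trim_min_len)
  trep <- attr(trimmed, "report")
  say("trimmed: %d pairs in, %d dropped", trep$pairs_in, trep$pairs_dropped)

  index <- build_bs_index(genome, k = config$k)
  aln <- align_pairs(trimmed, index, max_mismatches = config$max_mismatches,
                     insert_window = config$insert_window)
  arep <- attr(aln, "report")
  say("aligned: %d mapped, %d unique proper", arep$mapped,
      arep$unique_proper)

  sites <- pileup(aln, genome)
  say("pileup: %d covered cytosine sites", nrow(sites))

  summary <- methylome_summary(sites,
                               negative_control = config$negative_control,
                               min_reads = config$min_reads,
                               call_ratio = config$call_ratio,
                               n_bins = config$n_bins)
  if (!is.null(outdir)) {
    files["sam"] <- write_sam(aln, genome, path("alignments.sam"),
                              extra_header = paste0("@CO\t", stamp))
    files["sites"] <- write_sites(sites, path("sites.tsv"), stamp)
    sm <- write_methylome_summary(summary, file.path(outdir, "summary"),
                                  metadata = list(seed = config$seed,
                                                  config_hash = hash))
    files["summary_json"] <- sm["json"]
    files["summary_tsv"] <- sm["tsv"]
  }
  attr(summary, "sites") <- sites
  attr(summary, "truth") <- truth
  attr(summary, "files") <- files
  summary
}

#' Run the tRNA amplicon pipeline
#'
#' Aligns amplicon reads (from FASTQ or a simulation) to a tRNA reference,
#' builds the read-by-site matrix, and writes the matrix and per-site level
#' TSVs stamped with seed and configuration hash.
#'
#' @param ref A [trna_reference()] or FASTA path (first record used).
#' @param reads Read tibble, FASTQ path, or `NULL` to simulate.
#' @param site_probs,n_reads,indel_rate Simulation settings when
#'   `reads = NULL` (defaults emulate near-complete C38 methylation).
#' @param min_identity Acceptance threshold for [align_amplicon()].
#' @param outdir Output directory or `NULL`.
#' @param seed Seed (simulation and stamping).
#' @param quiet Suppress progress messages.
#' @return The `trna_matrix`, with the per-site levels in attribute
#'   `"levels"` and output paths in `"files"`.
#' @examples
#' mat <- run_trna_pipeline(example_trna_references()[[2]],
#'                          n_reads = 20, quiet = TRUE)
#' @export
run_trna_pipeline <- function(ref, reads = NULL, site_probs = c("38" = 0.95),
                              n_reads = 462, indel_rate = 0.005,
                              min_identity = 0.9, outdir = NULL, seed = 1,
                              quiet = FALSE) {
  say <- function(...) if (!quiet) message("[bisulfitr] ", sprintf(...))
  if (is.character(ref)) {
    if (!file.exists(ref)) {
      config_error(paste0("tRNA reference FASTA not found: ", ref))
    }
    ref <- read_trna_references(ref)[[1]]
  }
  stopifnot(inherits(ref, "trna_reference"))
  if (is.null(reads)) {
    reads <- simulate_trna_amplicon(ref, site_probs, n_reads = n_reads,
                                    indel_rate = indel_rate,
                                    seed = stage_seed(seed, "trna"))
    say("simulated %d amplicon reads for %s", nrow(reads), ref$name)
  } else if (is.character(reads)) {
    if (!file.exists(reads)) {
      config_error(paste0("amplicon FASTQ not found: ", reads))
    }
    reads <- read_fastq(reads)
  }
  if (nrow(reads) == 0) config_error("empty amplicon read set")
  mat <- build_trna_matrix(reads, ref, min_identity = min_identity)
  say("matrix: %dx coverage, %d rejected", mat$coverage, mat$n_rejected)
  levels <- site_levels(mat)
  files <- character(0)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    stamp <- c(sprintf("seed: %d", seed),
               sprintf("reference: %s", ref$name))
    files["matrix"] <- write_trna_matrix(
      mat, file.path(outdir, "trna_matrix.tsv"), comments = stamp)
    lv_path <- file.path(outdir, "trna_levels.tsv")
    con <- file(lv_path, "w")
    writeLines(paste0("# ", stamp), con)
    utils::write.table(levels, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    files["levels"] <- lv_path
  }
  attr(mat, "levels") <- levels
  attr(mat, "files") <- files
  mat
}
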