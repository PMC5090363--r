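#' Per-component methylation model
#'
#' One row per genome component giving the probability that a CpG-context
#' cytosine is methylated (`p_cpg`) and the probability for every other
#' cytosine (`p_non_cpg`). CpG methylation is assigned symmetrically: when a
#' CpG dinucleotide is drawn methylated, both the Watson C and the paired
#' Crick C carry the mark, as maintenance methylation leaves them in animal
#' genomes.
#'
#' @param component Character vector of component names.
#' @param p_cpg,p_non_cpg Probabilities in `[0, 1]`.
#' @return A tibble with columns `component`, `p_cpg`, `p_non_cpg`.
#' @examples
#' methylation_model(c("main", "lambda", "human"), p_cpg = c(0, 0, 0.8),
#'                   p_non_cpg = c(0, 0, 0.005))
#' @export
methylation_model <- function(component, p_cpg = 0, p_non_cpg = 0) {
  model <- tibble(component = as.character(component),
                  p_cpg = as.numeric(p_cpg),
                  p_non_cpg = as.numeric(p_non_cpg))
  stopifnot_prob(model$p_cpg, "p_cpg")
  stopifnot_prob(model$p_non_cpg, "p_non_cpg")
  if (anyDuplicated(model$component)) {
    config_error("model components must be unique")
  }
  model
}

#' The spike-in design's default methylation model
#'
#' Main genome and lambda-like negative control fully unmethylated; the
#' human-blood-like positive control heavily methylated at CpG
#' (`p_cpg = 0.8`) with trace non-CpG methylation (`p_non_cpg = 0.005`),
#' emulating the CpG enrichment a somatic vertebrate methylome shows.
#'
#' @return A [methylation_model()] tibble for components
#'   `main`, `lambda`, `human`.
#' @export
spike_in_model <- function() {
  methylation_model(c("main", "lambda", "human"),
                    p_cpg = c(0, 0, 0.8),
                    p_non_cpg = c(0, 0, 0.005))
}

#' Assign ground-truth methylation states to every cytosine
#'
#' Enumerates every cytosine on both strands of every component (a Crick
#' cytosine sits at a Watson G) and draws its methylation state from the
#' component's [methylation_model()]. CpG dinucleotides are drawn once and
#' applied to both strands; all other cytosines are drawn independently.
#'
#' @param genome A `bs_genome`.
#' @param model A methylation model covering every component.
#' @param seed Integer random seed.
#' @return A tibble (the simulation ground truth) with columns `component`,
#'   `pos0` (0-based Watson coordinate), `strand` (`"+"` Watson, `"-"`
#'   Crick), `cpg` (logical context flag) and `methylated`.
#' @examples
#' g <- build_reference(reference_spec("chr", 500), seed = 1)
#' truth <- assign_methylation(g, methylation_model("chr", p_cpg = 1), seed = 2)
#' table(truth$cpg, truth$methylated)
#' @export
assign_methylation <- function(genome, model, seed = 1) {
  stopifnot(inherits(genome, "bs_genome"))
  missing_comp <- setdiff(names(genome$seq), model$component)
  if (length(missing_comp) > 0) {
    config_error(paste0("methylation model missing component(s): ",
                        paste(missing_comp, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  out <- lapply(names(genome$seq), function(comp) {
    bytes <- charToRaw(genome$seq[[comp]])
    is_c <- bytes == as.raw(67)  # C
    is_g <- bytes == as.raw(71)  # G
    L <- length(bytes)
    p_cpg <- model$p_cpg[model$component == comp]
    p_non <- model$p_non_cpg[model$component == comp]

    watson <- which(is_c)                       # 1-based
    crick <- which(is_g)
    cpg_c <- if (L > 1) which(is_c[-L] & is_g[-1]) else integer(0)

    watson_cpg <- watson %in% cpg_c
    crick_cpg <- crick %in% (cpg_c + 1L)

    meth_w <- logical(length(watson))
    meth_c <- logical(length(crick))
    # symmetric CpG draw, then independent non-CpG draws
    pair_state <- as.logical(rbinom(length(cpg_c), 1, p_cpg))
    meth_w[watson_cpg] <- pair_state[match(watson[watson_cpg], cpg_c)]
    meth_c[crick_cpg] <- pair_state[match(crick[crick_cpg] - 1L, cpg_c)]
    meth_w[!watson_cpg] <- as.logical(rbinom(sum(!watson_cpg), 1, p_non))
    meth_c[!crick_cpg] <- as.logical(rbinom(sum(!crick_cpg), 1, p_non))

    tibble(
      component = comp,
      pos0 = c(watson, crick) - 1L,
      strand = rep(c("+", "-"), c(length(watson), length(crick))),
      cpg = c(watson_cpg, crick_cpg),
      methylated = c(meth_w, meth_c)
    )
  })
  arrange(bind_rows(out), .data$component, .data$pos0, .data$strand)
}

# per-component strand-indexed logical vectors for the read simulator
truth_strand_vectors <- function(genome, truth) {
  lapply(names(genome$seq), function(comp) {
    L <- nchar(genome$seq[[comp]])
    tr <- truth[truth$component == comp, ]
    plus <- logical(L)
    minus <- logical(L)
    pw <- tr[tr$strand == "+", ]
    pc <- tr[tr$strand == "-", ]
    plus[pw$pos0 + 1L] <- pw$methylated
    minus[pc$pos0 + 1L] <- pc$methylated
    list(plus = plus, minus = minus)
  })
}

#' Read and write methylation ground-truth tables
#'
#' Plain TSV with columns `component`, `pos0`, `strand`, `cpg`,
#' `methylated`; leading `#` lines are metadata comments.
#'
#' @param truth A truth tibble from [assign_methylation()].
#' @param path File path.
#' @param comments Character vector written as leading `#` lines.
#' @return `read_truth()` returns the truth tibble; `write_truth()` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste0("# ", comments), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as_tibble(utils::read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE)) |>
    mutate(strand = as.character(.data$strand))
}
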