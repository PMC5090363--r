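#' Distribute sites into non-conversion ratio bins
#'
#' Bins are left-closed/right-open over `[0, 1]` with the last bin closed,
#' e.g. `[0, 0.1), [0.1, 0.2), ..., [0.9, 1]` for 10 bins. Fractions are
#' over all input sites.
#'
#' @param sites Site tibble from [pileup()] (any subset).
#' @param n_bins Number of equal-width bins.
#' @return A tibble with `bin`, `lower`, `upper`, `n`, `fraction`; zero
#'   rows for empty input.
#' @examples
#' ratio_histogram(tibble::tibble(ratio = c(0, 0.05, 0.95)))
#' @export
ratio_histogram <- function(sites, n_bins = 10) {
  if (n_bins < 1) config_error("n_bins must be >= 1")
  edges <- seq(0, 1, length.out = n_bins + 1)
  if (nrow(sites) == 0) {
    return(tibble(bin = integer(0), lower = numeric(0), upper = numeric(0),
                  n = integer(0), fraction = numeric(0)))
  }
  idx <- pmin(n_bins, findInterval(sites$ratio, edges,
                                   rightmost.closed = TRUE))
  counts <- tabulate(idx, nbins = n_bins)
  tibble(bin = seq_len(n_bins), lower = edges[-length(edges)],
         upper = edges[-1], n = counts, fraction = counts / nrow(sites))
}

#' Fraction of sites above a ratio threshold
#'
#' Strict inequality: a site counts only when `ratio > threshold`.
#'
#' @param sites Site tibble.
#' @param threshold Ratio threshold in `(0, 1)`.
#' @return A single fraction (0 for empty input).
#' @examples
#' tail_fraction(tibble::tibble(ratio = c(0.4, 0.6, 0.95)), 0.9)
#' @export
tail_fraction <- function(sites, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    config_error("threshold must lie in (0, 1)")
  }
  if (nrow(sites) == 0) return(0)
  mean(sites$ratio > threshold)
}

#' Dinucleotide context table of called unconverted cytosines
#'
#' Counts called sites by dinucleotide (`CpA`, `CpC`, `CpG`, `CpT`);
#' boundary sites with dinucleotide `CpN` are excluded. An empty table is a
#' valid result (a fully converted negative control yields one).
#'
#' @param called_sites Output of [call_methylated()].
#' @return A tibble with `dinucleotide`, `n`, `fraction`.
#' @export
unconverted_context_table <- function(called_sites) {
  kept <- filter(called_sites,
                 .data$dinucleotide %in% c("CpA", "CpC", "CpG", "CpT"))
  if (nrow(kept) == 0) {
    return(tibble(dinucleotide = character(0), n = integer(0),
                  fraction = numeric(0)))
  }
  out <- count(kept, .data$dinucleotide, name = "n")
  mutate(out, fraction = .data$n / sum(.data$n))
}

#' Bisulfite conversion rate from the negative-control spike
#'
#' The unmethylated spike (lambda in the emulated design) has no true
#' methylation, so every retained C is a conversion failure:
#' `rate = 1 - sum(n_unconverted) / sum(coverage)`.
#'
#' @param negative_control_sites Site tibble restricted to the
#'   negative-control component.
#' @return The conversion rate in `[0, 1]`.
#' @examples
#' conversion_rate(tibble::tibble(n_unconverted = 0L, coverage = 100L))
#' @export
conversion_rate <- function(negative_control_sites) {
  if (nrow(negative_control_sites) == 0) {
    data_error("no negative-control sites: conversion rate unavailable")
  }
  1 - sum(negative_control_sites$n_unconverted) /
    sum(negative_control_sites$coverage)
}

#' Conversion-corrected global methylation level
#'
#' The raw level is the pooled non-conversion ratio
#' `sum(n_unconverted) / sum(coverage)`. Because a conversion failure is
#' indistinguishable from methylation at a single site, the raw level is
#' corrected by the spike-derived conversion rate,
#' `(raw - (1 - rate)) / rate`, clamped at zero, and reported in parts per
#' million.
#'
#' @param sites Site tibble for the component of interest.
#' @param conversion_rate Conversion rate from [conversion_rate()], must
#'   exceed 0.5.
#' @return Corrected global methylation level in ppm; `NA` for empty input.
#' @export
global_methylation_level <- function(sites, conversion_rate = 1) {
  if (!is.numeric(conversion_rate) || conversion_rate <= 0.5 ||
      conversion_rate > 1) {
    config_error("conversion_rate must lie in (0.5, 1]")
  }
  if (nrow(sites) == 0) return(NA_real_)
  raw <- sum(sites$n_unconverted) / sum(sites$coverage)
  corrected <- max(0, (raw - (1 - conversion_rate)) / conversion_rate)
  corrected * 1e6
}

#' Mean coverage of CpG-context sites
#'
#' @param sites Site tibble (one component, or pre-grouped input).
#' @return Mean informative coverage over CpG-context sites; `NA` when the
#'   input has none.
#' @examples
#' mean_cpg_coverage(tibble::tibble(context = "CpG", coverage = c(10, 20, 30)))
#' @export
mean_cpg_coverage <- function(sites) {
  cpg <- filter(sites, !is.na(.data$context), .data$context == "CpG")
  if (nrow(cpg) == 0) return(NA_real_)
  mean(cpg$coverage)
}

#' Summarise a methylome per component
#'
#' Computes, for each genome component, the ratio-bin distribution, the
#' `< 0.1` / `> 0.5` / `> 0.9` tail fractions, the dinucleotide context
#' table of called unconverted cytosines, the mean CpG coverage, and the
#' conversion-corrected global methylation level. The conversion rate is
#' estimated from the negative-control component when one is named,
#' otherwise taken as 1. The ratio histogram uses all covered sites; the
#' coverage filter (`min_reads`) applies only to calling sites unconverted.
#'
#' @param sites Site tibble from [pileup()].
#' @param negative_control Name of the unmethylated spike component, or
#'   `NULL`.
#' @param min_reads,call_ratio Calling thresholds, see [call_methylated()].
#' @param n_bins Ratio histogram bins.
#' @return A `methylome_summary` object with elements `components` (one
#'   row of scalar statistics per component), `bins`, `contexts`,
#'   `conversion_rate` and `params`. Has [tidy()], [glance()],
#'   [autoplot()] and print methods.
#' @examples
#' g <- build_reference(reference_spec("chr", 5000), seed = 1)
#' tr <- assign_methylation(g, methylation_model("chr"), seed = 1)
#' reads <- simulate_wgbs(g, tr, bisulfite_params(depth = 4), seed = 1)
#' sites <- pileup(align_pairs(reads, build_bs_index(g)), g)
#' methylome_summary(sites)
#' @export
methylome_summary <- function(sites, negative_control = NULL, min_reads = 4,
                              call_ratio = 0.5, n_bins = 10) {
  rate <- 1
  if (!is.null(negative_control)) {
    neg <- filter(sites, .data$component == negative_control)
    rate <- conversion_rate(neg)
  }
  called <- call_methylated(sites, min_reads = min_reads,
                            call_ratio = call_ratio)
  comps <- unique(sites$component)
  per_comp <- lapply(comps, function(cp) {
    s <- filter(sites, .data$component == cp)
    hist <- mutate(ratio_histogram(s, n_bins), component = cp)
    ctx <- mutate(unconverted_context_table(
      filter(called, .data$component == cp)), component = cp)
    row <- tibble(
      component = cp,
      n_sites = nrow(s),
      n_called = sum(called$component == cp),
      frac_lt_0.1 = mean(s$ratio < 0.1),
      frac_gt_0.5 = tail_fraction(s, 0.5),
      frac_gt_0.9 = tail_fraction(s, 0.9),
      mean_cpg_coverage = mean_cpg_coverage(s),
      global_level_ppm = global_methylation_level(s, rate)
    )
    list(row = row, hist = hist, ctx = ctx)
  })
  structure(list(
    components = bind_rows(lapply(per_comp, `[[`, "row")),
    bins = select(bind_rows(lapply(per_comp, `[[`, "hist")),
                  "component", "bin", "lower", "upper", "n", "fraction"),
    contexts = select(bind_rows(lapply(per_comp, `[[`, "ctx")),
                      "component", "dinucleotide", "n", "fraction"),
    conversion_rate = rate,
    params = list(negative_control = negative_control,
                  min_reads = min_reads, call_ratio = call_ratio,
                  n_bins = n_bins)
  ), class = "methylome_summary")
}

#' @export
print.methylome_summary <- function(x, ...) {
  cat("<methylome_summary> ", nrow(x$components), " component(s); ",
      "conversion rate ", sprintf("%.4f", x$conversion_rate), "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' @describeIn methylome_summary One row of scalar statistics per component.
#' @param x A `methylome_summary`.
#' @param ... Unused.
#' @export
tidy.methylome_summary <- function(x, ...) {
  x$components
}

#' @describeIn methylome_summary One-row overall summary (total sites,
#'   conversion rate, pooled tail fractions).
#' @export
glance.methylome_summary <- function(x, ...) {
  comp <- x$components
  tot <- sum(comp$n_sites)
  tibble(
    n_components = nrow(comp),
    n_sites = tot,
    n_called = sum(comp$n_called),
    conversion_rate = x$conversion_rate,
    frac_lt_0.1 = sum(comp$frac_lt_0.1 * comp$n_sites) / tot,
    frac_gt_0.5 = sum(comp$frac_gt_0.5 * comp$n_sites) / tot,
    frac_gt_0.9 = sum(comp$frac_gt_0.9 * comp$n_sites) / tot
  )
}

#' @describeIn methylome_summary Ratio-bin histogram faceted by component.
#' @param object A `methylome_summary`.
#' @export
autoplot.methylome_summary <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                               y = .data$fraction)) +
    ggplot2::geom_col(width = 0.09, fill = "grey30") +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "non-conversion ratio", y = "fraction of sites") +
    ggplot2::theme_minimal()
}

#' Serialise a methylome summary
#'
#' `write_methylome_summary()` writes both a machine-readable JSON document
#' (full precision) and a TSV of the per-component table (ppm rounded to
#' 1 ppm for reading).
#'
#' @param summary A `methylome_summary`.
#' @param prefix Output path prefix; writes `<prefix>.json` and
#'   `<prefix>.tsv`.
#' @param metadata Named list merged into the JSON document (e.g. seed and
#'   config hash).
#' @return Paths of the written files, invisibly.
#' @export
write_methylome_summary <- function(summary, prefix, metadata = list()) {
  stopifnot(inherits(summary, "methylome_summary"))
  json_path <- paste0(prefix, ".json")
  tsv_path <- paste0(prefix, ".tsv")
  doc <- c(metadata, list(
    conversion_rate = summary$conversion_rate,
    components = summary$components,
    bins = summary$bins,
    contexts = summary$contexts,
    params = summary$params
  ))
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  tab <- mutate(summary$components,
                global_level_ppm = round(.data$global_level_ppm))
  con <- file(tsv_path, "w")
  on.exit(close(con))
  if (length(metadata) > 0) {
    writeLines(paste0("# ", names(metadata), ": ",
                      vapply(metadata, as.character, character(1))), con)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}
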