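#' tRNA reference for amplicon bisulfite analysis
#'
#' Wraps a tRNA sequence with its cytosine positions (1-based, as displayed
#' in per-site methylation matrices) and the Dnmt2 target site, position 38
#' in the anticodon loop.
#'
#' @param name Reference name, e.g. `"tRNA-Asp"`.
#' @param sequence DNA-alphabet tRNA sequence (the cDNA of the transcript).
#' @param target_site 1-based position of the target cytosine; must be a C.
#' @return A `trna_reference` object with fields `name`, `sequence`,
#'   `cytosine_positions`, `target_site`.
#' @examples
#' trna_reference("toy", "GCATTGGTGC", target_site = 10)
#' @export
trna_reference <- function(name, sequence, target_site = 38) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cyt <- which(bases == "C")
  if (!(target_site %in% cyt)) {
    config_error(sprintf("target_site %d is not a C in %s", target_site, name))
  }
  structure(list(name = name, sequence = sequence,
                 cytosine_positions = cyt,
                 target_site = as.integer(target_site)),
            class = "trna_reference")
}

#' @export
print.trna_reference <- function(x, ...) {
  cat("<trna_reference> ", x$name, ": ", nchar(x$sequence), " nt, ",
      length(x$cytosine_positions), " cytosines, target C",
      x$target_site, "\n", sep = "")
  invisible(x)
}

#' Synthetic example tRNA references
#'
#' Two synthetic 71-nt tRNA-like references (labelled after the Dnmt2
#' substrates tRNA-Asp and tRNA-Gly but not the organism's real sequences,
#' which are not redistributed here) with a cytosine at position 38 and a
#' realistic cytosine density, for examples and tests. Identical to the
#' copies shipped in `inst/extdata/synthetic_trna_refs.fasta`.
#'
#' @return A named list of [trna_reference()] objects.
#' @export
example_trna_references <- function() {
  seqs <- c(
    `tRNA-Asp-synthetic` = paste0(
      "GTCGTTGTAGTATAGTGGTAAGTATTCCCGCCTGTCACGCGGGAGACCGGGGTTCGATTCCCCGCAACGGA"),
    `tRNA-Gly-synthetic` = paste0(
      "GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACCGGGGAGGCCCGGGTTCGATTCCCGGCCAATGCA")
  )
  lapply(names(seqs), function(nm) trna_reference(nm, seqs[[nm]])) |>
    setNames(names(seqs))
}

#' Read tRNA references from FASTA
#'
#' @param path FASTA path.
#' @param target_site Target cytosine position applied to every reference.
#' @return Named list of [trna_reference()] objects.
#' @export
read_trna_references <- function(path, target_site = 38) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    trna_reference(names(set)[i], as.character(set[[i]]), target_site)
  }) |> setNames(names(set))
}

#' Align amplicon reads against a tRNA reference
#'
#' Semi-global affine-gap alignment of each read (both orientations tried)
#' against the reference with C/T equivalence at reference cytosines, so a
#' read's conversion state cannot bias its placement. Reads whose
#' converted identity over aligned reference columns falls below
#' `min_identity` are rejected. Each reference cytosine column is called
#' `M` (read C), `U` (read T), or `-` (gap / other base / outside the
#' aligned span).
#'
#' @param reads Read tibble (`name`, `seq`).
#' @param ref A [trna_reference()].
#' @param min_identity Converted-identity acceptance threshold.
#' @param min_aligned Minimum fraction of reference columns that must be
#'   aligned to read bases; prevents short spurious overlaps from passing
#'   the identity filter.
#' @param match,mismatch,gap_open,gap_extend Alignment scores; gaps cost
#'   `gap_open + gap_extend` to open and `gap_extend` per further base.
#' @return A tibble with one row per read: `name`, `accepted`, `identity`,
#'   `orientation` (`"fwd"`/`"rev"`), `score`, and one `M`/`U`/`-` column
#'   per reference cytosine position (named `C<pos>`).
#' @examples
#' ref <- example_trna_references()[[1]]
#' reads <- simulate_trna_amplicon(ref, c("38" = 1), n_reads = 3, seed = 1)
#' align_amplicon(reads, ref)
#' @export
align_amplicon <- function(reads, ref, min_identity = 0.9,
                           min_aligned = 0.5, match = 1, mismatch = -1,
                           gap_open = -3, gap_extend = -1) {
  stopifnot(inherits(ref, "trna_reference"))
  cyt <- ref$cytosine_positions
  n <- nrow(reads)
  calls <- matrix("-", nrow = n, ncol = length(cyt),
                  dimnames = list(NULL, paste0("C", cyt)))
  identity <- numeric(n)
  aligned_cols <- integer(n)
  orientation <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    fwd <- align_amplicon_cpp(reads$seq[i], ref$sequence, match, mismatch,
                              gap_open, gap_extend)
    rev <- align_amplicon_cpp(revcomp_dna(reads$seq[i]), ref$sequence,
                              match, mismatch, gap_open, gap_extend)
    best <- if (rev$score > fwd$score) rev else fwd
    orientation[i] <- if (rev$score > fwd$score) "rev" else "fwd"
    identity[i] <- best$identity
    aligned_cols[i] <- best$aligned_cols
    score[i] <- best$score
    aligned <- strsplit(best$calls, "", fixed = TRUE)[[1]][cyt]
    calls[i, ] <- dplyr::case_when(aligned == "C" ~ "M",
                                   aligned == "T" ~ "U",
                                   TRUE ~ "-")
  }
  accepted <- identity >= min_identity &
    aligned_cols >= min_aligned * nchar(ref$sequence)
  out <- tibble(name = reads$name, accepted = accepted,
                identity = identity, orientation = orientation,
                score = score)
  bind_cols_matrix(out, calls)
}

bind_cols_matrix <- function(df, m) {
  for (j in colnames(m)) df[[j]] <- unname(m[, j])
  df
}

#' Build the per-read by per-site methylation matrix
#'
#' Runs [align_amplicon()] and assembles accepted reads into the matrix
#' displayed in amplicon bisulfite figures: one row per read, one column
#' per reference cytosine, cells `M` (methylated), `U` (unmethylated) or
#' `-` (gap). Coverage is the accepted-read count.
#'
#' @param reads Read tibble (`name`, `seq`).
#' @param ref A [trna_reference()].
#' @inheritParams align_amplicon
#' @return A `trna_matrix` object (fields `matrix`, `ref`, `coverage`,
#'   `n_rejected`); an accepted-read count of zero yields an empty matrix
#'   flagged by `coverage = 0`.
#' @examples
#' ref <- example_trna_references()[[1]]
#' reads <- simulate_trna_amplicon(ref, c("38" = 0.9), n_reads = 10, seed = 1)
#' build_trna_matrix(reads, ref)
#' @export
build_trna_matrix <- function(reads, ref, min_identity = 0.9,
                              min_aligned = 0.5, match = 1, mismatch = -1,
                              gap_open = -3, gap_extend = -1) {
  aln <- align_amplicon(reads, ref, min_identity, min_aligned, match,
                        mismatch, gap_open, gap_extend)
  acc <- filter(aln, .data$accepted)
  cols <- paste0("C", ref$cytosine_positions)
  m <- as.matrix(acc[, cols, drop = FALSE])
  rownames(m) <- acc$name
  structure(list(matrix = m, ref = ref, coverage = nrow(m),
                 n_rejected = sum(!aln$accepted)),
            class = "trna_matrix")
}

#' @export
print.trna_matrix <- function(x, ...) {
  cat("<trna_matrix> ", x$ref$name, ": coverage ", x$coverage, "x over ",
      ncol(x$matrix), " cytosines (", x$n_rejected, " rejected)\n", sep = "")
  invisible(x)
}

#' Per-site methylation levels of a tRNA matrix
#'
#' `level = M / (M + U)` per cytosine column; gap cells are excluded from
#' the denominator and a column with only gaps reports `NA`.
#'
#' @param mat A `trna_matrix`.
#' @return A tibble with `position`, `n_meth`, `n_unmeth`, `n_gap`,
#'   `level`, `is_target`.
#' @examples
#' ref <- example_trna_references()[[1]]
#' reads <- simulate_trna_amplicon(ref, c("38" = 0.9), n_reads = 10, seed = 1)
#' site_levels(build_trna_matrix(reads, ref))
#' @export
site_levels <- function(mat) {
  stopifnot(inherits(mat, "trna_matrix"))
  pos <- mat$ref$cytosine_positions
  m <- mat$matrix
  n_meth <- unname(colSums(m == "M"))
  n_unmeth <- unname(colSums(m == "U"))
  n_gap <- unname(colSums(m == "-"))
  informative <- n_meth + n_unmeth
  tibble(position = pos,
         n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth),
         n_gap = as.integer(n_gap),
         level = ifelse(informative > 0, n_meth / informative, NA_real_),
         is_target = pos == mat$ref$target_site)
}

#' @describeIn site_levels Long tibble (`read`, `position`, `state`) of the
#'   matrix cells.
#' @param x A `trna_matrix`.
#' @param ... Unused.
#' @export
tidy.trna_matrix <- function(x, ...) {
  m <- x$matrix
  if (nrow(m) == 0) {
    return(tibble(read = character(0), position = integer(0),
                  state = character(0)))
  }
  tibble(read = rep(rownames(m), times = ncol(m)),
         position = rep(x$ref$cytosine_positions, each = nrow(m)),
         state = as.vector(m))
}

#' @describeIn site_levels One-row summary: coverage, rejected reads, and
#'   the target-site (C38) methylation level.
#' @export
glance.trna_matrix <- function(x, ...) {
  lv <- site_levels(x)
  tibble(reference = x$ref$name, coverage = x$coverage,
         n_rejected = x$n_rejected,
         target_site = x$ref$target_site,
         target_level = lv$level[lv$is_target][1])
}

#' @describeIn site_levels Read-by-site grid in the conventional colours
#'   (blue methylated, yellow unmethylated, white gap).
#' @param object A `trna_matrix`.
#' @export
autoplot.trna_matrix <- function(object, ...) {
  cells <- tidy(object)
  cells$read <- factor(cells$read, levels = rev(rownames(object$matrix)))
  ggplot2::ggplot(cells, ggplot2::aes(x = factor(.data$position),
                                      y = .data$read,
                                      fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey80", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(M = "#2166AC", U = "#FFD92F",
                                          `-` = "white"),
                               labels = c(M = "methylated",
                                          U = "unmethylated", `-` = "gap")) +
    ggplot2::labs(x = "cytosine position", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Read and write tRNA methylation matrices
#'
#' TSV serialisation: header row of cytosine positions, one row per read
#' with cells `M`/`U`/`-`. Writing then reading (then writing again) is
#' byte-identical.
#'
#' @param mat A `trna_matrix`.
#' @param path TSV path.
#' @param ref The [trna_reference()] the matrix belongs to (for reading).
#' @param comments Character vector written as leading `#` lines.
#' @return `read_trna_matrix()` returns a `trna_matrix`;
#'   `write_trna_matrix()` returns `path` invisibly.
#' @export
write_trna_matrix <- function(mat, path, comments = character(0)) {
  stopifnot(inherits(mat, "trna_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("read", colnames(mat$matrix)), collapse = "\t"), con)
  if (nrow(mat$matrix) > 0) {
    rows <- apply(mat$matrix, 1, paste, collapse = "\t")
    writeLines(paste(rownames(mat$matrix), rows, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_trna_matrix
#' @export
read_trna_matrix <- function(path, ref) {
  stopifnot(inherits(ref, "trna_reference"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cols <- header[-1]
  if (!identical(cols, paste0("C", ref$cytosine_positions))) {
    data_error("matrix columns do not match the reference's cytosines")
  }
  body <- lines[-1]
  if (length(body) == 0) {
    m <- matrix(character(0), nrow = 0, ncol = length(cols),
                dimnames = list(NULL, cols))
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    m <- do.call(rbind, lapply(f, function(x) x[-1]))
    colnames(m) <- cols
    rownames(m) <- vapply(f, `[[`, character(1), 1)
  }
  structure(list(matrix = m, ref = ref, coverage = nrow(m),
                 n_rejected = NA_integer_),
            class = "trna_matrix")
}
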