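test_that("reference builder preserves lengths and is seed-deterministic", {
  spec <- reference_spec(c("a", "b"), c(1000, 300), mass_fraction = c(.7, .3))
  g1 <- build_reference(spec, seed = 5)
  g2 <- build_reference(spec, seed = 5)
  g3 <- build_reference(spec, seed = 6)
  expect_identical(unname(nchar(g1$seq)), c(1000L, 300L))
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, g3$seq))
  # byte-identical FASTA for the same seed
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g1, f1)
  write_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("realized CpG frequency matches independence at factor 1 and responds monotonically", {
  n <- 100000
  count_cpg <- function(factor) {
    g <- build_reference(reference_spec("c", n, gc = 0.5,
                                        cpg_factor = factor), seed = 11)
    length(gregexpr("CG", g$seq[[1]], fixed = TRUE)[[1]])
  }
  base <- count_cpg(1)
  p <- 0.0625  # (gc/2)^2 under independence
  expect_lt(abs(base / (n - 1) - p), 3 * sqrt(p * (1 - p) / (n - 1)))
  expect_gt(count_cpg(3), base)
  expect_lt(count_cpg(0.2), base)
})

test_that("reference spec validation rejects bad fractions and lengths", {
  expect_error(reference_spec("a", 0), class = "bisulfitr_config_error")
  expect_error(reference_spec(c("a", "b"), c(10, 10),
                              mass_fraction = c(0.5, 0.4)),
               class = "bisulfitr_config_error")
  expect_error(reference_spec("a", 10, gc = 1.2),
               class = "bisulfitr_config_error")
})

test_that("methylation assignment honours all-or-nothing models and CpG symmetry", {
  g <- build_reference(reference_spec("c", 5000, gc = 0.6), seed = 2)
  none <- assign_methylation(g, methylation_model("c"), seed = 1)
  expect_true(all(!none$methylated))

  cpg_only <- assign_methylation(
    g, methylation_model("c", p_cpg = 1, p_non_cpg = 0), seed = 1)
  expect_true(all(cpg_only$methylated[cpg_only$cpg]))
  expect_true(all(!cpg_only$methylated[!cpg_only$cpg]))
  # symmetry: the Crick partner of every methylated Watson CpG is methylated
  w <- dplyr::filter(cpg_only, strand == "+", cpg)
  c_ <- dplyr::filter(cpg_only, strand == "-", cpg)
  expect_setequal(w$pos0 + 1L, c_$pos0)
  expect_error(assign_methylation(g, methylation_model("other"), seed = 1),
               class = "bisulfitr_config_error")
})

test_that("methylated CpG fraction follows the model probability", {
  g <- build_reference(reference_spec("c", 200000, gc = 0.5, cpg_factor = 2),
                       seed = 3)
  truth <- assign_methylation(
    g, methylation_model("c", p_cpg = 0.8, p_non_cpg = 0), seed = 4)
  cpg <- dplyr::filter(truth, cpg, strand == "+")
  expect_gt(nrow(cpg), 10000)
  frac <- mean(cpg$methylated)
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(cpg)))
})

test_that("complete conversion leaves no C at origin-strand cytosines", {
  g <- build_reference(reference_spec("c", 4000), seed = 7)
  truth <- assign_methylation(g, methylation_model("c"), seed = 7)
  pairs <- simulate_wgbs(g, truth,
                         bisulfite_params(failure_rate = 0, depth = 4),
                         seed = 8)
  # original-top mate 1 is a converted Watson segment: no C anywhere
  ot <- dplyr::filter(pairs, strand == "+")
  expect_false(any(grepl("C", ot$seq1, fixed = TRUE)))
  # and mate 2 is its reverse complement: no G
  expect_false(any(grepl("G", ot$seq2, fixed = TRUE)))
  ob <- dplyr::filter(pairs, strand == "-")
  expect_false(any(grepl("C", ob$seq1, fixed = TRUE)))
})

test_that("a fully methylated genome retains every cytosine", {
  g <- build_reference(reference_spec("c", 4000), seed = 9)
  truth <- assign_methylation(
    g, methylation_model("c", p_cpg = 1, p_non_cpg = 1), seed = 9)
  pairs <- simulate_wgbs(g, truth,
                         bisulfite_params(overconversion_rate = 0, depth = 4),
                         seed = 10)
  origin <- parse_read_origin(pairs$name)
  for (i in head(seq_len(nrow(pairs)), 200)) {
    frag <- substr(g$seq[[1]], origin$start0[i] + 1,
                   origin$start0[i] + origin$insert[i])
    tmpl <- if (origin$strand[i] == "+") frag else revcomp_dna(frag)
    expect_identical(pairs$seq1[i], substr(tmpl, 1, 80))
  }
})

test_that("pair counts follow depth and mass-fraction accounting", {
  spec <- reference_spec(c("a", "b"), c(60000, 20000),
                         mass_fraction = c(0.8, 0.2))
  g <- build_reference(spec, seed = 12)
  truth <- assign_methylation(g, methylation_model(c("a", "b")), seed = 12)
  params <- bisulfite_params(depth = 8)
  pairs <- simulate_wgbs(g, truth, params, seed = 13)
  L <- sum(nchar(g$seq))
  # per-strand pair count ~ Poisson(depth * L / (2 * read_length))
  expected_strand <- params$depth * L / (2 * params$read_length)
  for (s in c("+", "-")) {
    n_s <- sum(pairs$strand == s)
    expect_lt(abs(n_s - expected_strand), 3 * sqrt(expected_strand))
  }
  # per-component counts ~ mass_fraction-weighted Poisson
  for (i in 1:2) {
    expected_c <- 2 * expected_strand * spec$mass_fraction[i]
    n_c <- sum(pairs$component == spec$component[i])
    expect_lt(abs(n_c - expected_c), 3 * sqrt(expected_c))
  }
})

test_that("simulated FASTQ output is byte-identical under one seed", {
  g <- build_reference(reference_spec("c", 3000), seed = 1)
  truth <- assign_methylation(g, methylation_model("c"), seed = 1)
  p <- bisulfite_params(depth = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fastq_pairs(simulate_wgbs(g, truth, p, seed = 3),
                    file.path(d1, "r"))
  write_fastq_pairs(simulate_wgbs(g, truth, p, seed = 3),
                    file.path(d2, "r"))
  expect_identical(readLines(file.path(d1, "r_1.fastq")),
                   readLines(file.path(d2, "r_1.fastq")))
  expect_identical(readLines(file.path(d1, "r_2.fastq")),
                   readLines(file.path(d2, "r_2.fastq")))
})

test_that("per-site retained-C counts are binomial at the configured failure rate", {
  run <- sim_pipeline(length = 30000, failure_rate = 0.01, depth = 12,
                      seed = 21)
  sites <- dplyr::filter(run$sites, coverage >= 5)
  expect_gt(nrow(sites), 1000)
  # chi-square goodness of fit of unconverted counts against Binomial(cov, 0.01),
  # pooled over the observed coverage mix into {0, 1, >=2} classes
  obs <- c(sum(sites$n_unconverted == 0), sum(sites$n_unconverted == 1),
           sum(sites$n_unconverted >= 2))
  p0 <- mean(dbinom(0, sites$coverage, 0.01))
  p1 <- mean(dbinom(1, sites$coverage, 0.01))
  probs <- c(p0, p1, 1 - p0 - p1)
  test <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(test$p.value, 0.001)
})

test_that("amplicon simulator respects site probabilities", {
  ref <- example_trna_references()[["tRNA-Gly-synthetic"]]
  none <- simulate_trna_amplicon(ref, n_reads = 20, seed = 1)
  conv <- strsplit(chartr("C", "T", ref$sequence), "")[[1]]
  expect_true(all(vapply(strsplit(none$seq, ""), identical, logical(1), conv)))

  always <- simulate_trna_amplicon(ref, c("38" = 1), n_reads = 20, seed = 2)
  expect_true(all(substr(always$seq, 38, 38) == "C"))

  many <- simulate_trna_amplicon(ref, c("38" = 0.95), n_reads = 462, seed = 3)
  frac <- mean(substr(many$seq, 38, 38) == "C")
  expect_lt(abs(frac - 0.95), 3 * sqrt(0.95 * 0.05 / 462))

  expect_error(simulate_trna_amplicon(ref, c("38" = 1.5), n_reads = 5),
               class = "bisulfitr_config_error")
  expect_error(simulate_trna_amplicon(ref, c("1" = 0.5), n_reads = 5),
               class = "bisulfitr_config_error")
})
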