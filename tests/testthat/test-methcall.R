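test_that("pileup counts converted and unconverted bases from hand-built reads", {
  g <- as_bs_genome(c(chr = "AACCAAAA"))
  # one original-top pair whose mates overlap completely: mate 1 wins,
  # so each reference C is seen exactly once, converted
  aln <- aln_row("r1", "chr", "+", 2, "TT", 2, "AA")
  sites <- pileup(aln, g)
  expect_identical(nrow(sites), 2L)
  expect_true(all(sites$n_converted == 1L))
  expect_true(all(sites$n_unconverted == 0L))
  expect_true(all(sites$ratio == 0))
  expect_true(all(sites$strand == "+"))

  # 5 reads C + 5 reads T at one site -> coverage 10, ratio 0.5
  g2 <- as_bs_genome(c(chr = "AACAAAAA"))
  rows <- dplyr::bind_rows(lapply(1:10, function(i) {
    aln_row(paste0("r", i), "chr", "+", 2, if (i <= 5) "C" else "T", 2, "A")
  }))
  s2 <- pileup(rows, g2)
  expect_identical(s2$coverage, 10L)
  expect_identical(s2$ratio, 0.5)
})

test_that("a methylated CpG shows ratio 1 on both strands", {
  g <- as_bs_genome(c(chr = "TTACGTTA"))
  # two original-top pairs retaining the Watson C, two original-bottom
  # pairs retaining the Crick C (Watson G); mates fully overlap
  aln <- dplyr::bind_rows(
    aln_row("ot1", "chr", "+", 0, "TTACGTTA", 0, revcomp_dna("TTACGTTA")),
    aln_row("ot2", "chr", "+", 0, "TTACGTTA", 0, revcomp_dna("TTACGTTA")),
    aln_row("ob1", "chr", "-", 0, revcomp_dna("TTACGTTA"), 0, "TTACGTTA"),
    aln_row("ob2", "chr", "-", 0, revcomp_dna("TTACGTTA"), 0, "TTACGTTA"))
  sites <- pileup(aln, g)
  watson <- dplyr::filter(sites, strand == "+", pos0 == 3)
  crick <- dplyr::filter(sites, strand == "-", pos0 == 4)
  expect_identical(watson$ratio, 1)
  expect_identical(crick$ratio, 1)
  expect_identical(watson$context, "CpG")
  expect_identical(crick$context, "CpG")
  # strand separation: original-top reads never feed Crick sites
  ot_only <- pileup(dplyr::filter(aln, strand == "+"), g)
  expect_true(all(ot_only$strand == "+"))
  ob_only <- pileup(dplyr::filter(aln, strand == "-"), g)
  expect_true(all(ob_only$strand == "-"))
})

test_that("pileup conserves informative base counts and honours mate-1 precedence", {
  g <- as_bs_genome(c(chr = "AACCAAACCA"))
  # non-overlapping mates: every informative base counts once
  aln <- aln_row("r", "chr", "+", 0, "AATT", 6, "TAAT")
  sites <- pileup(aln, g)
  expect_identical(sum(sites$coverage), 4L)
  # overlapping mates: the shared window counts once
  aln2 <- aln_row("r", "chr", "+", 0, "AATTAAA", 2, "AATTTAA")
  s2 <- pileup(aln2, g)
  expect_identical(sum(s2$coverage), 4L)
  # bases matching neither informative letter are ignored
  aln3 <- aln_row("r", "chr", "+", 2, "GG", 2, "CC")
  expect_identical(nrow(pileup(aln3, g)), 0L)
  # unknown component is a data error
  expect_error(pileup(aln_row("r", "nope", "+", 0, "AA", 0, "TT"), g),
               class = "bisulfitr_data_error")
})

test_that("context annotation reads the strand-correct dinucleotide and class", {
  g <- as_bs_genome(c(chr = "ACGTCATCCGA"))
  # Watson C at 1 followed by G -> CpG
  expect_identical(annotate_context(g, "chr", 1L, "+")$context, "CpG")
  expect_identical(annotate_context(g, "chr", 1L, "+")$dinucleotide, "CpG")
  # Watson C at 4 followed by A, third base T -> CpA / CHH
  ctx <- annotate_context(g, "chr", 4L, "+")
  expect_identical(ctx$dinucleotide, "CpA")
  expect_identical(ctx$context, "CHH")
  # Crick C at Watson G position 2: next base on Crick is complement of
  # Watson position 1 (C) -> CpG
  ctx2 <- annotate_context(g, "chr", 2L, "-")
  expect_identical(ctx2$dinucleotide, "CpG")
  expect_identical(ctx2$context, "CpG")
  # last-position cytosine gets CpN and no class
  g3 <- as_bs_genome(c(chr = "AAC"))
  ctx3 <- annotate_context(g3, "chr", 2L, "+")
  expect_identical(ctx3$dinucleotide, "CpN")
  expect_true(is.na(ctx3$context))
  # non-cytosine positions are a logic error
  expect_error(annotate_context(g, "chr", 0L, "+"),
               class = "bisulfitr_data_error")
})

test_that("the coverage rule calls sites only above 3 reads and the ratio cut", {
  sites <- tibble::tibble(coverage = c(3L, 4L, 10L, 8L),
                          ratio = c(1, 1, 0, 0.6))
  called <- call_methylated(sites)
  expect_identical(called$coverage, c(4L, 8L))
  expect_error(call_methylated(sites, min_reads = 0),
               class = "bisulfitr_config_error")
})

test_that("site ratios recover the conversion expectations on simulated data", {
  run <- sim_pipeline(length = 40000, p_cpg = 0.6, p_non_cpg = 0.02,
                      failure_rate = 0.005, depth = 15, seed = 51)
  truth_key <- paste(run$truth$component, run$truth$pos0, run$truth$strand)
  meth <- run$truth$methylated[match(
    paste(run$sites$component, run$sites$pos0, run$sites$strand), truth_key)]
  p_exp <- ifelse(meth, 1 - 0, 0.005)  # overconversion 0
  lo <- qbinom(0.0005, run$sites$coverage, p_exp)
  hi <- qbinom(0.9995, run$sites$coverage, p_exp)
  inside <- run$sites$n_unconverted >= lo & run$sites$n_unconverted <= hi
  expect_gte(mean(inside), 0.999)
})

test_that("site tables round-trip through TSV with 1-based file coordinates", {
  run <- sim_pipeline(length = 3000, depth = 3, seed = 61)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sites(run$sites, path, comments = "seed: 61")
  line1 <- readLines(path, n = 2)
  expect_true(startsWith(line1[1], "# seed"))
  back <- read_sites(path)
  expect_equal(as.data.frame(back), as.data.frame(run$sites))
})
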