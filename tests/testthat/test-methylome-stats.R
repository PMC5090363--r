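test_that("ratio histogram bins are left-closed, last bin closed, and normalised", {
  sites <- tibble::tibble(ratio = c(0, 0, 0.05, 0.1, 0.95, 1, 1))
  h <- ratio_histogram(sites)
  expect_identical(nrow(h), 10L)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-12)
  expect_identical(h$n[1], 3L)   # [0, 0.1): 0, 0, 0.05
  expect_identical(h$n[2], 1L)   # [0.1, 0.2)
  expect_identical(h$n[10], 3L)  # [0.9, 1] closed: 0.95, 1, 1
  all_zero <- ratio_histogram(tibble::tibble(ratio = rep(0, 5)))
  expect_identical(all_zero$fraction[1], 1)
  expect_true(all(all_zero$fraction[-1] == 0))
  empty <- ratio_histogram(tibble::tibble(ratio = numeric(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("tail fractions use strict inequality and agree with bin sums", {
  sites <- tibble::tibble(ratio = c(0.4, 0.6, 0.95))
  expect_equal(tail_fraction(sites, 0.9), 1 / 3)
  expect_identical(tail_fraction(tibble::tibble(ratio = rep(0, 4)), 0.5), 0)
  expect_error(tail_fraction(sites, 0), class = "bisulfitr_config_error")
  set.seed(7)
  rand <- tibble::tibble(ratio = round(runif(500), 3))
  h <- ratio_histogram(rand)
  expect_equal(tail_fraction(rand, 0.5), sum(h$fraction[6:10]) -
                 mean(rand$ratio == 0.5), tolerance = 1e-9)
})

test_that("context tables count called sites by dinucleotide", {
  one <- tibble::tibble(dinucleotide = "CpA", context = "CHH",
                        coverage = 5L, ratio = 1, n_unconverted = 5L,
                        n_converted = 0L)
  tab <- unconverted_context_table(one)
  expect_identical(tab$dinucleotide, "CpA")
  expect_identical(tab$n, 1L)
  # boundary CpN sites are excluded; empty tables are allowed
  boundary <- dplyr::mutate(one, dinucleotide = "CpN")
  expect_identical(nrow(unconverted_context_table(boundary)), 0L)
})

test_that("conversion rate is estimated from the negative control pool", {
  expect_identical(conversion_rate(
    tibble::tibble(n_unconverted = 0L, coverage = 100L)), 1)
  expect_error(conversion_rate(tibble::tibble(n_unconverted = integer(0),
                                              coverage = integer(0))),
               class = "bisulfitr_data_error")
  run <- sim_pipeline(length = 30000, failure_rate = 0.005, depth = 12,
                      seed = 71)
  n_bases <- sum(run$sites$coverage)
  expect_gt(n_bases, 1e5)
  rate <- conversion_rate(run$sites)
  expect_lt(abs(rate - 0.995), 3 * sqrt(0.005 * 0.995 / n_bases))
})

test_that("global methylation level corrects for conversion failure and clamps at 0", {
  perfect <- tibble::tibble(n_unconverted = c(0L, 0L), coverage = c(5L, 7L))
  expect_identical(global_methylation_level(perfect, 1), 0)
  # raw level below the failure rate clamps to zero, never negative
  low <- tibble::tibble(n_unconverted = 1L, coverage = 1000L)
  expect_identical(global_methylation_level(low, 0.99), 0)
  expect_error(global_methylation_level(low, 0.4),
               class = "bisulfitr_config_error")
})

test_that("a simulated 5.3% methylome is recovered after conversion correction", {
  run <- sim_pipeline(length = 80000, p_cpg = 0.053, p_non_cpg = 0.053,
                      failure_rate = 0.002, depth = 10, seed = 81)
  truth_key <- paste(run$truth$pos0, run$truth$strand)
  meth <- run$truth$methylated[match(paste(run$sites$pos0, run$sites$strand),
                                     truth_key)]
  # coverage-weighted realized truth level is what the pooled ratio estimates
  p_w <- sum(run$sites$coverage * meth) / sum(run$sites$coverage)
  est <- global_methylation_level(run$sites, 1 - 0.002)
  tol <- 3 * sqrt(p_w * (1 - p_w) / sum(run$sites$coverage)) * 1e6
  expect_lt(abs(est - p_w * 1e6), tol)
  # and the nominal 5.3% is itself recovered within its own binomial slack
  n_truth <- nrow(run$truth)
  expect_lt(abs(p_w - 0.053),
            4 * sqrt(0.053 * 0.947 / n_truth) + 0.005)
})

test_that("mean CpG coverage ignores non-CpG sites and tracks depth", {
  mixed <- tibble::tibble(context = c("CpG", "CpG", "CpG", "CHH", "CHH"),
                          coverage = c(10, 20, 30, 999, 1))
  expect_identical(mean_cpg_coverage(mixed), 20)
  expect_true(is.na(mean_cpg_coverage(dplyr::filter(mixed, context == "X"))))
  run <- sim_pipeline(length = 100000, depth = 8, seed = 91)
  expect_lt(abs(mean_cpg_coverage(run$sites) - 8) / 8, 0.05)
})

test_that("raising the conversion failure rate never lowers raw level or tails", {
  rates <- c(0.001, 0.005, 0.02)
  stats <- lapply(rates, function(fr) {
    run <- sim_pipeline(length = 15000, failure_rate = fr, depth = 10,
                        seed = 101)
    list(raw = global_methylation_level(run$sites, 1),
         gt5 = tail_fraction(run$sites, 0.5),
         gt9 = tail_fraction(run$sites, 0.9))
  })
  raw <- vapply(stats, `[[`, numeric(1), "raw")
  expect_true(all(diff(raw) > 0))
  gt5 <- vapply(stats, `[[`, numeric(1), "gt5")
  expect_true(all(diff(gt5) >= 0))
})

test_that("methylome summaries are internally consistent and tidy-able", {
  run <- sim_pipeline(length = 20000, p_cpg = 0.3, failure_rate = 0.002,
                      depth = 8, seed = 111)
  s <- methylome_summary(run$sites)
  td <- tidy(s)
  expect_identical(td$component, "chr")
  bins <- s$bins
  expect_equal(sum(bins$fraction), 1, tolerance = 1e-9)
  expect_equal(td$frac_lt_0.1, bins$fraction[bins$bin == 1])
  expect_equal(td$frac_gt_0.5,
               sum(bins$fraction[bins$bin >= 6]) -
                 mean(run$sites$ratio == 0.5))
  g <- glance(s)
  expect_identical(g$n_sites, nrow(run$sites))
  expect_s3_class(autoplot(s), "ggplot")
})
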