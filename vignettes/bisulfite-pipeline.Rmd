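---
title: "Spike-in controlled bisulfite analysis with bisulfitr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in controlled bisulfite analysis with bisulfitr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisulfitr)
```

## The measurement model

Bisulfite treatment deaminates unmethylated cytosine to uracil, which PCR
amplifies as thymine; 5-methylcytosine resists the reaction and stays
cytosine. Sequencing a treated library therefore turns methylation into a
base-calling problem: at a reference cytosine, reads showing C are
*unconverted* (methylated, or a conversion failure), reads showing T are
*converted*. The per-site **non-conversion ratio**

$$r = \frac{n_\mathrm{C}}{n_\mathrm{C} + n_\mathrm{T}}$$

is the estimator of the methylation level at that site. Two spike-in
controls calibrate it: an unmethylated lambda-phage DNA spike, whose
retained cytosines measure the conversion failure rate directly, and a
human blood DNA spike, whose dense CpG methylation must be recovered for
the experiment to have power to see methylation at all. A genome is called
unmethylated only when its ratio distribution is indistinguishable from
the negative control while the positive control reads back methylated.

`bisulfitr` implements this design end to end at desk scale: a
synthetic-data generator that emulates the three-genome mixture, read
trimming, a bisulfite-aware paired-end aligner, per-cytosine pileup, and
the summary statistics (ratio-bin histogram, tail fractions, dinucleotide
context table of unconverted cytosines, spike-derived conversion rate,
conversion-corrected global level). A companion workflow handles tRNA
amplicon bisulfite data, where the quantity of interest is the
methylation level of cytosine 38, the Dnmt2 target in the anticodon loop.

## What the generator emulates — and what it does not

`build_reference()` draws each component from a first-order Markov model:
bases are i.i.d. at the configured GC content except after a C, where the
G-transition probability is scaled by the component's CpG enrichment
factor. Factor 1 reduces exactly to independent sampling (CpG frequency
$(\mathrm{GC}/2)^2$), and the realised CpG frequency responds
monotonically to the factor. This is enough structure to give CpG-context
statistics realistic denominators; it does not reproduce isochores,
repeats, or real CpG-island architecture.

`spike_in_design()` fixes the study conditions: 91% of sequenced mass from
the main (mosquito-analog) genome, 1% from a 48,502 bp unmethylated
lambda analog, 8% from a human-blood analog with `p_cpg = 0.8` and
`p_non_cpg = 0.005` (`spike_in_model()`). CpG methylation is assigned
symmetrically to both strands of a dinucleotide, as maintenance
methylation leaves it; all other cytosines are independent.

`simulate_wgbs()` models a **directional** library: every fragment is
assigned to the original-top (Watson template) or original-bottom (Crick
template) strand with equal probability, mate 1 always reads the
converted original strand from its 5' end and mate 2 is the reverse
complement of the other end. Unmethylated cytosines on the template
convert to T except with probability `failure_rate` (default 0.002);
methylated cytosines stay C except with probability
`overconversion_rate` (default 0). Insert lengths are truncated normal
(mean 250, sd 40, bounded below by the read length); qualities are
constant Phred 37. Read names carry the true origin
(`id|component|start|insert|strand`) so every placement can be audited.
PCR duplicates, adapter contamination, amplification bias and
non-directional protocols are out of scope, so passing tests demonstrate
correctness of the analysis logic, not robustness to every artefact of
real libraries.

### The meaning of `depth`

`depth` in `bisulfite_params()` is defined as the **mean informative
coverage of a cytosine site** — the per-base depth contributed by reads
of that site's own bisulfite strand. This matches how WGBS studies report
coverage ("26× CpG coverage" counts the reads that can actually call the
cytosine), and it is the quantity the package's own
`mean_cpg_coverage()` estimates. Concretely, the simulator draws
`depth * L / read_length` pairs in total, half per strand, so each strand
contributes `depth * L / (2 * read_length)` pairs and every cytosine sees
`depth` informative reads on average. Note the consequence: total
sequence output is twice what a "genome-wide per-base depth" reading
would give, because only one strand's reads are informative for any
given cytosine.

## Trimming

Following the fixed constants of the emulated protocol, reads are first
truncated to 80 bp from the 5' end, then maximal terminal runs of bases
with Phred score < 30 are removed; interior low-quality bases are kept.
"Stretches at read ends" is read literally as terminal runs (not
BWA-style maximal-subsequence trimming); the cap is applied before the
quality trim, a fixed order chosen for reproducibility where the
protocol text is ambiguous. Reads shorter than 30 bp afterwards are
discarded (they cannot anchor two 16-mer seeds), and a pair is dropped
when either mate is discarded. Trimming is idempotent by construction.

## Bisulfite-aware alignment

Conversion destroys the C/T contrast, so alignment happens in reduced
three-letter alphabets: mate 1 is C→T-reduced and searched against the
C→T-reduced reference (original-top) and, reverse-complemented and
G→A-reduced, against the G→A-reduced reference (original-bottom);
mate 2 is searched in the complementary form. Reduction is applied to the
read as well as the reference, so a fully methylated read (all Cs
retained) maps exactly like a converted one.

Candidates come from exact 16-mer seeds taken at non-overlapping offsets
(up to 8 per mate); each candidate locus is extended without gaps,
counting mismatches in the reduced alphabet with a per-mate cap (default
4). With 80 bp mates and five 16-mers, the pigeonhole principle
guarantees a clean seed whenever a mate has at most four mismatches.
Seeds occurring more than 256 times are skipped as repetitive.

A pair is *proper* when both mates lie on one component in FR
orientation with an insert inside the accepted window, by default
`[read_length, insert_mean + 4·insert_sd]` — the "correct distance" is
not otherwise defined, so the window is explicit and configurable. A pair
is *unique* only when exactly one placement attains the minimal total
mismatch count; ties are discarded, never broken randomly. Only unique
proper pairs enter methylation calling. On genomes up to a few tens of
kilobases, every placement is cross-checked in the tests against
`brute_force_align()`, an independent exhaustive scorer over both
reductions.

Desk-scale genomes make gapped genomic alignment unnecessary; the
aligner is ungapped by design and reports SAM (plain text, `ZS:Z` strand
tag, `NM:i` mismatches) for interoperability.

## Pileup and calling

`pileup()` counts, at every Watson C, C-versus-T among original-top
reads, and at every Watson G (a Crick-strand cytosine), G-versus-A among
original-bottom reads. Bases matching neither informative letter (for
example a sequencing error reading A over a Watson C) are ignored rather
than counted as converted. Overlapping mates of one pair would otherwise
double-count their shared window; mate 1 takes precedence and mate 2's
overlap is skipped. Context is annotated strand-correctly: the
dinucleotide is the cytosine plus the next base 5'→3' on its own strand,
the class CpG/CHG/CHH from the two following bases; cytosines at sequence
ends get `CpN` and are excluded from context tables.

Calling a site *unconverted* (methylated) requires coverage of more than
3 reads **and** ratio above 0.5, both configurable. The ratio histogram,
by contrast, uses all covered sites: the positive-control spike is
sequenced at ~1× in the emulated design, and a coverage-4 histogram
filter would contradict its reported 2% fully methylated fraction. The
coverage rule therefore gates only the calling step, an interpretive
choice recorded here deliberately. Likewise the "fraction of cytosines"
denominators are covered cytosines (coverage ≥ 1), the only denominator
available to a sequencing experiment.

## Summary statistics

* `ratio_histogram()`: ten left-closed bins over `[0, 1]`, last bin
  closed, fractions over all input sites.
* `tail_fraction()`: strict inequality (`ratio > t`).
* `conversion_rate()`: `1 − Σ n_C / Σ coverage` over the
  negative-control component; errors loudly when that component has no
  sites, since an uncalibrated run should not report corrected levels.
* `global_methylation_level()`: pooled raw ratio corrected as
  `(raw − (1 − rate)) / rate`, clamped at zero (a raw level below the
  failure rate must not go negative), reported in ppm. The correction
  inverts the expectation
  `E[raw] = p + (1 − p)(1 − rate)` for true level `p`; it requires
  `rate > 0.5` and is exact for `overconversion_rate = 0`.
* `mean_cpg_coverage()`: mean informative coverage over CpG-context
  sites, the package's estimator of `depth`.

Components are summarised separately (assignment is by alignment target,
never read content), matching the per-genome mapping of a spike-in
experiment. Text reports round ppm to whole numbers; JSON keeps full
precision.

## tRNA amplicon workflow

Amplicon reads are aligned semi-globally (affine gaps, free end gaps,
match/mismatch 1/−1, gap open −3, extend −1) against the tRNA reference
with C/T treated as equivalent at reference cytosines, so conversion
state cannot bias placement; both orientations are tried. A read is
accepted when its converted identity over aligned columns is ≥ 90% *and*
at least half the reference columns are aligned — the span condition
prevents a short spurious overlap from passing the identity filter.
Accepted reads form the read-by-cytosine matrix (`M`/`U`/`-`), coverage
is the accepted-read count, and per-site levels exclude gap cells from
the denominator (an all-gap column reports `NA`, not 0). Column numbers
are the reference's own 1-based cytosine positions; no
secondary-structure renumbering is attempted. The simulator's 454-style
indel errors (default 0.5%) exercise the gap handling.

The shipped tRNA references are synthetic 71-nt stand-ins with a C at
position 38 (the real sequences live in supplementary material not
redistributed here); every statistic is computed against whichever
reference the user supplies.

## Numerical and degenerate-input choices

* Empty inputs return empty, typed results (empty histogram, `NA` mean
  coverage) rather than `NaN`; missing negative controls raise errors.
* All randomness flows through R's RNG; a single pipeline seed derives
  fixed per-stage sub-seeds, and identical configurations reproduce
  FASTA/FASTQ/SAM/TSV/JSON outputs byte for byte. Every output file
  embeds the seed and a configuration hash.
* Coordinates are 0-based half-open internally, 1-based in SAM and TSV
  files.
* Alignment ties are never broken; sites are emitted in genome order.

## Problem sizes used by the test suite

The package validates against scaled-down simulations chosen to keep the
statistics meaningful: the unmethylated-genome run uses a 200 kb genome
at depth 26 (~65,000 pairs, ~100,000 cytosine sites), the spike-in
mixture 120 kb / 48.5 kb / 30 kb components at depth 8, oracle
equivalence 500 random reads against a 5 kb genome, and the amplicon
checks 462 reads — the coverage reported for the emulated tRNA-Gly
experiment. At these sizes the binomial error bars used by the tests
(typically 3 SD) are a few per mille, tight enough to catch bookkeeping
errors while leaving honest room for sampling noise.

## Known limitations

* The aligner is ungapped and single-threaded; indels in genomic reads
  are not modelled or tolerated beyond the mismatch cap.
* No SNP-aware calling: a true C/T polymorphism is indistinguishable
  from conversion.
* The conversion correction assumes a homogeneous failure rate; real
  libraries can show context- or position-dependent failure.
* Adenine methylation is invisible to bisulfite chemistry and is out of
  scope throughout.

## A worked run

```{r demo, eval = FALSE}
cfg <- wgbs_config(
  spec = spike_in_design(main_length = 50000, human_length = 15000),
  model = spike_in_model(),
  params = bisulfite_params(depth = 8),
  negative_control = "lambda",
  seed = 1)
summary <- run_wgbs_pipeline(cfg)
tidy(summary)
autoplot(summary)

ref <- example_trna_references()[["tRNA-Gly-synthetic"]]
mat <- run_trna_pipeline(ref, site_probs = c("38" = 0.95), n_reads = 462,
                         indel_rate = 0.005, seed = 1)
glance(mat)
autoplot(mat)
```
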