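---
title: "Quantifying complex gene families with curated gene spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying complex gene families with curated gene spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genespace)
```

## The problem

One-reference-fits-all alignment is a poor model for three kinds of loci:
families of near-identical paralogs (a short read from the shared portion
of NKG2C/NKG2E can never be assigned uniquely), copy-number-variable
families whose gene content differs between subjects (KIR), and
hyper-polymorphic loci where single-base differences are the signal (MHC).
genespace treats each such family as its own *gene space*: a curated set
of reference sequences with its own alignment and calling configuration,
quantified independently of every other space, producing one count matrix
per library.

## Pipeline model and assumptions

The aligner is a two-phase pseudoaligner. Phase one builds, per library, a
k-mer membership index: every N-free k-mer occurring in a reference maps
to the sorted set of features containing it. This is the colour
information of the reference de Bruijn graph; explicit graph edges are not
stored, because candidate generation only ever needs per-k-mer feature
sets, and final calls are verified at base level anyway. Only the forward
orientation of the reference is indexed; querying the read and its reverse
complement covers both strands at half the index size.

Phase two verifies candidates by *ungapped, fully contained* placement:
the trimmed read is compared base-by-base at every offset at which it fits
inside the candidate feature, and the best placement per feature maximises
`score = matched_length − mismatches`. The ungapped model is an explicit
assumption: reference spaces here are mRNA/allele sequences, reads are
short, and indels are out of scope. Reads overhanging feature ends are
filtered (and accounted) rather than soft-clipped. Within a feature, an
offset tie resolves to the smallest offset and `+` strand before `−` —
only the feature identity matters downstream.

Two properties make this design testable end-to-end:

* For any placement with `m` mismatches and matched length `L`, if
  `m < floor(L / k)` then at least one k-block of the read is error-free
  (pigeonhole), so the candidate stage provably cannot miss that feature.
  The test suite constructs reads respecting this bound and asserts exact
  equality of the pipeline with a brute-force scanner (`oracle_align()`)
  that tries every offset, orientation and feature with no k-mer
  shortcuts.
* Mismatch counts are well-defined integers, so the maximum-mismatch
  filter and perfect-match mode are exact, not heuristic.

## Trimming

Reads are trimmed with the maximum-information criterion: the kept prefix
maximises the sum of a logistic length-threshold term
`log(1/(1+exp(target_length − l)))`, a coverage term
`(1 − strictness)·log(l)`, and an error term
`strictness · Σ log(1 − 10^−((q+0.5)/10))`. The `0.5` offset keeps the
error term finite at Phred 0. At `strictness = 0` the score is monotone in
length (no trimming); at `strictness = 1` only the length-threshold and
error terms act. On the measure-zero event of an exact score tie the
shortest maximising prefix is kept; the exhaustive-prefix oracle in the
test suite applies the same rule. Defaults: `trim_target_length = 40`,
`trim_strictness = 0.8`, the common working range for this trimmer.
Quality scores are used *only* here — mismatch counting is not
quality-weighted.

## Calling policies

* **Ambiguity** (`ambiguity_policy`): placements within `score_margin` of
  the best form the tied set. `discard` drops multi-feature ties;
  `report_set` emits the sorted, comma-joined set as a first-class matrix
  row (so "NKG2C,NKG2E" is one deterministic row name whatever the input
  order); `group_collapse` maps the tied set through a feature-to-group
  table (allele to gene) first. `score_margin` defaults to 0 — only exact
  score ties are ambiguous — as the most conservative choice.
* **Pairs** (`pair_policy`): `intersection` (empty intersection = a
  counted "discordant" drop), `union`, `r1_only` (literal), `best_score`
  (ties fall back to intersection). A mate with no call does not veto its
  partner under `intersection`/`union`/`best_score`.
* **Orientation** (`orientation_policy`): `fr` asserts R1 aligns forward
  and R2 reverse relative to the reference (`rf` mirrored). The assertion
  is applied to each mate's placements before calling; a mate whose every
  placement violates it makes the whole pair an "orientation" no-call. A
  pair in which only one mate aligned carries no orientation evidence and
  passes. This design was open: the alternative (treating the violating
  mate as merely unaligned) would let the surviving mate's call stand,
  which contradicts the purpose of asserting pair geometry.
* **Molecules**: reads sharing (cell barcode, UMI) are one molecule and
  contribute at most one count. No-calls are ignored; the remaining calls
  vote by identical call set; a vote tie takes the intersection of the
  tied sets; an empty intersection makes the molecule "irresolvable"
  (counted in QC). Majority-then-intersection is a declared design choice;
  it is conservative, deterministic, and reduces to the obvious answer
  whenever the reads agree.

Barcodes and UMIs are taken as given (the intended input is either raw
chemistry FASTQ or a tag-corrected alignment file); whitelist correction,
ambient RNA and doublets are upstream concerns. Reads lacking barcodes
inside a single-cell run are excluded from the cell matrix and tallied
under `no_barcode`.

## Accounting

`summarize_report()` asserts, exactly and on every run: each input
fragment (read or pair) lands in exactly one category — counted, or one of
trimmed / unaligned / length / mismatch / orientation / discordant /
ambiguous / no-barcode — and in single-cell mode each molecule group is
counted, unaligned or irresolvable, with the matrix total equal to the
number of counted molecules. A violation is an internal error, not a
warning.

## MHC post-processing

Allele names follow `locus*field1:field2:...`; the lineage (two-digit
typing) is `locus*field1` with a trailing "g" group marker stripped.
`aggregate_to_lineage()` sums allele rows into lineage rows; a joined
multi-allele row whose members share one lineage collapses into it (those
reads are unambiguous *at lineage resolution*), while a multi-lineage row
is kept joined or — under the discard policy — dropped and tallied.
`normalize_per_locus()` divides each allele's count by its cell's locus
total, giving within-locus fractions that sum to 1 per cell and locus
(cells with a zero locus total get zeros). `call_genotypes()` declares a
lineage present for a subject when its supporting molecules reach
`min_molecules` (default 5) and its expressing-cell fraction reaches
`min_cell_fraction` (default 0.01); both thresholds are explicit,
tunable parameters — no published defaults exist for this decision — and
the defaults are deliberately permissive for sorted-cell data. Lineages
whose only evidence sits in dropped multi-lineage rows are reported with
`dropped_ambiguous = TRUE`: an allele that short reads cannot separate
from another allele disappears *visibly*, not silently, and
`genotype_concordance()` reports such misses separately from plain
misses.

## The synthetic-data module

The generators define the study conditions for every test:

* `make_paralog_family()`: a random ancestor plus copies mutated at a
  per-base substitution rate, with an optional untouched shared block —
  the NKG2C/E situation (98% identity = divergence 0.02; the shared block
  makes a known fraction of reads unavoidably ambiguous).
* `make_allele_panel()`: a three-level hierarchy (locus ancestors at
  substitution rate 0.25 from a common root, lineages at 0.05, alleles at
  0.005) named in standard `locus*lineage:allele` nomenclature. The rates
  were chosen once so that across-locus divergence ≫ across-lineage ≫
  within-lineage, mirroring real MHC structure at a scaled-down panel
  size.
* `simulate_reads()`: per true molecule, a UMI (collision-free within its
  (cell, feature) pair; cross-feature collisions occur at natural random
  rates) and a uniform placement; substitution-only errors, matching the
  ungapped aligner's scope; constant Phred-40 qualities so that trimming
  stays neutral unless a test exercises it deliberately. Complete per-read
  provenance (source feature, offset, strand, error positions) is
  returned, which is what makes the perfect-match purity check possible.

What the simulations do *not* model: fragment-length and GC biases, PCR
duplication, indels, quality-correlated errors, ambient RNA. Passing tests
therefore demonstrate algorithmic correctness of alignment, calling,
deduplication and accounting under the stated error model — not robustness
to every artefact of real libraries.

Problem sizes used by the test suite and `scripts/acceptance.R`: 2,000
oracle-equivalence reads over 10 libraries (the script uses 4 libraries ×
125 fragments); 1,000-read retention runs over 20 seeds; an end-to-end
run of 100 cells × 50 features with Poisson(1) molecules per (cell,
feature) and 3 reads per molecule (~15,000 reads); genotyping of 4
subjects × 10 lineages from a 60-lineage panel at 40 cells per subject.
These sizes give stable statistics while keeping a full run in minutes on
one core.

## Numerical and degenerate-input choices

* Feature tables are stored sorted by name, so libraries, indexes and all
  outputs are independent of input record order.
* k-mers containing N are skipped at index and query time; N in a read
  simply counts as a mismatch during verification.
* Normalization uses exact division; the per-locus sum-to-one property is
  tested at 1e−9.
* Empty inputs are valid everywhere: an empty FASTQ yields an empty (0×0)
  matrix, a valid MatrixMarket artifact and a report with zero fragments.
* MatrixMarket output writes integer triplets directly (an all-ones
  matrix must re-read as integers, not as a pattern matrix) alongside
  gzipped features/barcodes files in the conventional single-cell layout.
* `library_config(require_perfect = TRUE)` forces the effective
  `max_mismatches` to 0 at construction, so the two settings can never
  disagree.

## Known limitations

Gapped or spliced alignment, indel tolerance and base-quality-weighted
scoring are out of scope by design. The aligner is optimised for panels of
tens to a few thousand features; genome-scale libraries work but are not
the target. Probabilistic redistribution of multi-mapped reads (EM-style)
is deliberately not offered: the calling model is keep-or-discard with
explicit multi-feature rows, which keeps counts integral and auditable.
Subject demultiplexing from MHC expression is supported only insofar as
the normalized per-cell allele matrix this package exports is what such a
workflow consumes.
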