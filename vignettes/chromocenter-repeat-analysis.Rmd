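---
title: "Dissecting chromocenter DNA from short reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting chromocenter DNA from short reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mouse chromocenters — the dense constitutive-heterochromatin bodies of
interphase nuclei — are built from pericentromeric and centromeric satellite
DNA (the 234-bp-monomer major satellite, MaSat, and the 120-bp-monomer minor
satellite, MiSat) together with transposable-element fragments. These regions
are missing from the reference assembly (the ~3-Mb "Golden Path Gap" at every
centromere), so their composition has to be measured directly from sequencing
reads rather than from genome annotation. chromoscan implements the
computational side of that measurement for short (37-bp) paired-end reads:

1. **Read cleaning** (`clean_readset()`): sliding-window quality trimming and
   a minimum-length filter define the denominator of every percentage the
   package reports.
2. **Read classification** (`classify_reads()`, `quantify()`): each read is
   assigned to at most one repeat family by best local alignment against a
   consensus library, and assignments are aggregated into hierarchical
   composition tables.
3. **Coverage profiling** (`profile_coverage()`,
   `detect_enriched_segments()`): per-nucleotide read coverage along a chosen
   consensus, used to ask whether a sub-element fragment — canonically the
   ~2-kb segment at the 3′ end of LINE-1 ORF2 plus the 3′ UTR — is
   over-represented relative to the full-length element.
4. **Tandem-array detection** (`find_monomer_hits()`, `chain_arrays()`):
   head-to-tail monomer runs in contigs, with the large-tandem-repeat rule
   (monomer < 2 kb, array span > 3 kb).
5. **Co-occurrence screen** (`screen_batch()`): contigs carrying both
   satellite monomers and an endogenous-retrovirus (ERV) fragment longer than
   400 bp are flagged as centromere-proximal candidates, with per-contig
   structure maps.

A seeded synthetic-data module (`generate_library()`, `generate_reads()`,
`generate_contigs()`) emulates the statistical structure of the real data so
that every stage is testable with known ground truth and no downloads.

## Read cleaning

`qc_params()` defaults to a 4-base window, a mean-quality floor of Q25 and a
30-base minimum length — the standard recipe for short MiSeq reads. The scan
is 5′→3′ with a leading-edge cut: the read is truncated immediately before
the start of the first window whose mean quality is *strictly* below the
floor. This mirrors the SLIDINGWINDOW semantics of the usual trimming tools;
the scan direction and the strictness of the comparison are pinned by
hand-enumerated oracle cases in the test suite. Reads shorter than the window
are left untouched (the length filter still applies), trimming is idempotent,
and outputs are always prefixes of inputs. Adapter handling is exact
substring matching on the untrimmed read with an empty default set: the
synthetic data contain no adapters, and no adapter list is assumed.

## Classification model

The classifier replaces an external local-sensitive mapper with an in-package
affine-gap Smith–Waterman aligner so that the whole analysis is
self-contained and auditable. The scoring scheme (`scoring_scheme()`) is
match +2, mismatch −3, gap open −5, gap extend −2 (a gap of length L costs
`open + L·extend`), with a reporting floor of score ≥ 40 and alignment
length ≥ 20 columns. For 37-bp reads the floor corresponds to at least ~20
matched bases net of penalties — conservative enough that random 37-mers
essentially never reach it against a ~35-kb library.

Design points:

* **Tandem references.** Tandem monomers are aligned against a head-to-tail
  expansion of the monomer covering at least one junction plus two read
  lengths (for monomers ≥ read length this is the classical duplicated
  consensus), so junction-spanning reads align contiguously. Reported
  coordinates are reduced modulo the monomer length.
* **Seeding.** A k-mer seed prefilter (k = 11) restricts alignment to
  seed-bounded windows of candidate references; it is lossless for any
  alignment containing one exact 11-mer. Reads whose best windowed alignment
  stays below the reporting floor are re-seeded at k = 8 before being
  declared unassigned — at ~5% divergence a read can lack a clean 11-mer but
  almost never lacks a clean 8-mer. `exhaustive = TRUE` disables seeding
  entirely; the seeded and exhaustive paths are checked against each other in
  the tests, and the aligner itself against an independent brute-force
  dynamic-programming oracle.
* **Single best assignment.** Each read counts once. Ties across families at
  the best score are broken by repeat-class priority (TR first, then LINE,
  SINE, ERV1–3, DNA, OTHER) and then by byte-order family name, and are
  always surfaced through the `ambiguous` flag rather than hidden. Percentages
  use *all* cleaned reads as denominator, so the "All repeats" total plus the
  unassigned remainder is exactly 100%.

## Coverage profiles and enrichment calling

`profile_coverage()` increments, for every read whose best alignment to the
chosen consensus passes the thresholds, the aligned reference span; the sum
of the raw profile equals the total number of aligned bases (checked as an
invariant). `normalize_profile()` rescales to reads-per-million of the
originating dataset — the simplest reading of "normalized on dataset size" —
with per-aligned-read normalization available as an option; double
normalization is an error.

The enrichment caller is this package's own design (the underlying
observation is visual in origin): the profile is smoothed with a centered
moving average (`smooth_window = 101` positions, shrinking at the edges),
positions at `fold_threshold = 3` times the profile median are marked, marked
runs closer than one smoothing window are merged, and merged runs of at
least `min_segment_len = 200` positions are reported with their mean fold.
All three knobs are exposed. Calls are invariant under global scaling and
mirror-symmetric under profile reversal; a zero-median profile yields no
calls. With the default generator conditions (80% of LINE copies truncated
to the 3′-terminal 2,000 bases), the single called segment recovers the
planted window to within a few smoothing half-widths, which is how the
~2-kb figure is recomputed by `scripts/acceptance.R`.

## Tandem arrays and the large-TR rule

`find_monomer_hits()` retrieves non-overlapping local alignments of a
monomer against a contig greedily by score (both strands, each hit's span
masked before the next search), keeping hits at ≥ 75% identity.
`chain_arrays()` joins consecutive same-strand hits whose gap is at most
`max_insert_gap = 50` bases — our operationalization of "tandemly arranged
without inserts", which no published tolerance pins down; the flag is
exposed. Complete monomers (hits spanning ≥ 90% of the monomer) are counted
in `n_monomers`; partial trailing hits extend the span only. The
`meets_large_TR` flag is true when the monomer is shorter than 2,000 bases
and the array span exceeds 3,000 bases — so 13 abutting MaSat monomers
(3,042 bp) qualify and 12 (2,808 bp) do not.

## The co-occurrence screen

A contig is positive when it carries at least `min_monomers` complete
monomers of the chosen tandem family (one for MaSat/MiSat, three for the
shorter TRPC-21A) *and* a retained ERV fragment strictly longer than 400
bases. TE fragments are retained unless their e-value exceeds 1e-10 *and*
their score is below 100 — the BLAST-style rule, approximated here with
ungapped Karlin–Altschul statistics: λ is solved from the scoring scheme
under a uniform base background at run time, K is fixed at the standard 0.1
ballpark, and the search space is record length × contig length. Both
thresholds are arguments and a score-only mode bypasses e-values. The
"fragment (LTR)" phrasing of the positivity rule is grammatically ambiguous;
the default counts any ERV-derived fragment (internal or LTR), and
`ltr_only = TRUE` implements the narrower reading.

One measurement subtlety: the length of a detected fragment carries a few
bases of alignment-edge noise (a local alignment can gain a couple of
chance-matching flank bases), so a planted window of exactly 400 bases from
a longer consensus may be measured at 400 ± ~5. The boundary behaviour of
the strict > 400 rule is therefore exercised with a full-length 400-bp LTR
record, whose alignment cannot exceed the pattern length.

Structure maps partition each contig into maximal annotated/unannotated
intervals; overlaps between arrays and TE fragments are resolved in favour
of the higher alignment score, which keeps maps deterministic and
score-consistent.

## The synthetic-data generator

The generator defines the study conditions, not a tuning dial:

* **Library** (`generate_library()`): random 41%-GC consensuses at the
  field's lengths — MaSat 234 bp, MiSat 120 bp, an 84-bp stand-in for the
  additional pericentromeric family TRPC-21A (its true monomer length is not
  printed anywhere we rely on; 84 bp keeps it shorter than the satellites
  but above the read length), (TTAGGG)₂₀, a 6.4-kb LINE, a 150-bp SINE,
  four ~6-kb ERV elements (LTR–internal–LTR; LTRs 400–500 bp so that both
  qualifying and boundary screen fragments are plantable) and an 800-bp DNA
  transposon. All pairwise identities are below 55% by construction
  (verified by alignment in the tests), so classification truth is
  unambiguous.
* **Reads** (`generate_reads()`): pairs are drawn from a seeded multinomial
  at the chromocenter composition (MaSat 0.662, MiSat 0.044, other TR 0.009,
  telomere 0.001, LINE 0.109, SINE 0.021, ERV 0.088 split IAP 0.022 / other
  ERV2 0.029 / ERV1 0.005 / ERV3 0.032, DNA 0.006, remainder unannotated
  background). Tandem reads come from long arrays of per-copy-mutated
  monomers (5% divergence by default), so junction-spanning reads occur at
  their natural rate; LINE reads from a 25-copy pool in which 80% of copies
  expose only the 3′-terminal 2,000 bases (a two-component mixture rather
  than a continuous 5′-truncation gradient — the simplest model that makes
  the 3′ enrichment detectable and tunable); ERV reads uniformly from whole
  elements; inserts are lognormal around a 100-bp median; sequencing errors
  are independent substitutions at 0.2% per base; qualities are Q33–Q40 so
  the cleaning stage keeps everything unless a test plants low-quality bases
  deliberately. Identical seeds reproduce identical FASTQ bytes.
* **Contigs** (`generate_contigs()`): declarative blueprints (arrays with
  copy counts, TE fragments with lengths and strands, random spacers) with a
  per-feature truth table; `blueprint_verdicts()` applies the screen's
  positivity rule directly to the blueprint, independent of any alignment.

What the generator does *not* emulate — real satellite higher-order
structure, CENP-B boxes, transduction, nested insertions, indel sequencing
errors, GC landscape beyond a single parameter — bounds what passing tests
show: they validate the algorithms against the stated statistical structure,
not the full complexity of real heterochromatin.

## Problem sizes and numerical choices

The shipped checks use 100,000 reads for composition recovery, 50,000
LINE-derived reads for fragment localization, a 50-contig blueprint set for
the screen, 200 random pairs for aligner–oracle equivalence and 1,000 random
reads for trimming idempotence; the near-flat-profile check uses 20,000
reads (~115× depth), where Poisson coverage fluctuation is comfortably below
the 1.5 max/median bound being asserted. Coordinates are 1-based inclusive
in every tibble and GFF3 report (the IRanges convention); bedGraph export
converts to 0-based half-open. Alignment tie-breaks are deterministic
(first-maximal cell in row-major order; byte-order names across families),
so identical inputs give identical outputs on any platform.

## Limitations

* Percentages are relative to cleaned reads of one dataset; no
  genome-assembly comparison column is produced (that requires a reference
  annotation outside this package's scope).
* The e-value model is ungapped and uses a fixed K; it is a thresholding
  approximation, not BLAST-identical statistics.
* Monomer discovery is library-driven: families absent from the consensus
  library are invisible (no de-novo tandem-repeat finder is included).
* The classifier's single-assignment rule makes family percentages
  conservative for families with genuine cross-homology; the `ambiguous`
  flag marks where that matters.

## A worked call

```{r, eval = FALSE}
library(chromoscan)

lib <- generate_library(1)
sim <- generate_reads(sim_config(seed = 42, n_reads = 20000), lib)

cleaned <- clean_readset(sim$reads)
composition <- quantify(cleaned, lib)
composition_summary(composition)

l1 <- lib[lib$name == "L1", ]
profile <- profile_coverage(sim$reads, l1)
detect_enriched_segments(profile)
autoplot(profile)
```
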