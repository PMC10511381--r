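---
title: "Models and methods behind ccrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrpipe)
```

`ccrpipe` re-implements, as a tested pipeline, the analysis of breakpoint
junctions from constitutional complex chromosomal rearrangements (CCRs):
junction-signature calling at nucleotide resolution, derivative-chromosome
reconstruction, windowed Poisson-regression enrichment of breakpoints in
chromatin-accessibility peaks, and parent-of-origin assignment from trio
genotypes. This vignette records the models, the parameter choices that
matter, and the boundaries of what the synthetic-data tests establish.

## Coordinates and interval semantics

All intervals are 0-based, half-open (`[start, end)`), the BED convention. A
**breakend** is one side of a double-strand break: chromosome, position, and
which flank is retained in the fusion. The position is the first base *not*
retained, so `left_retained` at position *p* means the derivative carries
`[.., p)`. Peak sets are merged with bedtools-merge semantics: overlapping
*and bookended* intervals coalesce (distance threshold 0). Chromosome names
are matched exactly — no `chr`-prefix or case normalization — because silent
renaming corrupts overlap counts; a case-only mismatch in a junction is
flagged with a warning.

## Junction signatures

A junction sequence is aligned exactly (no mismatches — the intended inputs
are Sanger-validated) against the reference context of each partner locus.
The **microhomology length is defined as the number of valid split positions
minus one**: a split assigns a prefix of the junction to locus A and the
suffix to locus B; within a shared homology tract every split is valid, so a
blunt join has exactly one split (signed length 0) and a homology of *h*
has *h* + 1. When no valid split exists, the maximal prefix/suffix matches
bracket a **microinsertion**, reported as a negative signed length. This is
the standard ambiguity-interval definition; it is derivable from sequence
alone and needs no arbitrary choice of "the" break position.

Numerical/degenerate choices:

* `min_anchor` (default 10 bp): the junction must match each context with at
  least this many bases, otherwise it is rejected as unmappable rather than
  guessed at. A junction fully contained in *both* contexts is reported as an
  ambiguity error, never silently resolved.
* `flank_len` (default 150 bp): reference context half-width. It comfortably
  covers observed signatures (|signed length| ≤ ~15 bp) plus anchors.
* Insertion origin (`classify_insertion`): an insertion is a
  `tandem_repeat`/`inverted_repeat` if an exact, full-length (same-strand /
  reverse-complement) copy lies within `search_radius` (default 50 bp) of
  either break — the fingerprint of backward or serial replication slippage.
  Partial matches never count. Otherwise it is `unknown_origin`. Genome-wide
  origin assignment of long insertions conventionally requires ≥ 20 bp of
  alignment; that threshold is exposed (`min_genome_hit`) but genome-wide
  search is out of scope, while *adjacent* short repeats are still classified
  as tandem/inverted because the adjacency itself is the evidence.
* Tandem is checked before inverted; an insertion with both copies nearby is
  reported tandem (deterministic tie-break).

Breakpoint interval statistics (fragment sizes between successive breaks on
a chromosome, pooled) collapse duplicate positions with a warning; medians
and quartiles use the standard type-7 quantile.

## Derivative-chromosome assembly

Fragments are the tiling of each involved chromosome at its break positions.
The assembly graph has a node per fragment end; each fragment contributes an
internal edge, each junction pairs two ends according to the retained-side
flags. Because one breakend side can carry at most one junction (violations
are a `conflicting junction` error), maximal telomere-to-telomere walks are
deterministic: we start at free p-telomere ends in chromosome order, then
remaining q-telomeres. Fragments on no walk are unplaced — i.e. deleted.
Copy number is an exact tally of fragment placements; losses and gains are
reported above `min_report_len` (default 50 kb, the usual SNP-microarray
reporting threshold), with the full accounting always available. The
assembler itself can never duplicate a fragment, matching the observation
that these constitutional events show losses but no gains.

`ambiguous` is set — never silently resolved — when a junction goes unused
(a cycle with no telomere, which would be a ring or a genuinely ambiguous
decomposition) or a walk dead-ends away from a telomere (an under-determined
input, e.g. a lost terminal fragment). Derivatives are named after the
chromosome contributing the first (p-terminal) fragment, mirroring der()
nomenclature.

## Windowed Poisson enrichment

The genome is tiled with fixed windows (defaults 1, 5 and 10 kb; the last
window of each chromosome is truncated). Per window we record the fraction
covered by the merged peak set and the breakpoint count, then fit

$$\log E[y_i] = \alpha + \beta x_i$$

by Poisson IRLS (relative tolerance 1e-10, ≤ 100 iterations; the reference
implementation is `stats::glm`, which is also what the original analysis
used, and the test suite checks it against an independent Newton/BFGS
maximizer). The **risk ratio** `exp(β)` compares a fully covered window with
an uncovered one; inference is Wald: `exp(β ± 1.96·se)` and a normal test of
`β/se` at 0.05.

Interpretation choices that were genuinely open:

* The source methods text describes recording "presence or absence" of
  breakpoints per window while fitting Poisson regression, and swaps the
  dependent/objective labels. We model the per-window breakpoint **count**
  as the response and coverage as the predictor — the only direction in
  which Poisson regression and risk ratios of the reported magnitude are
  coherent — and keep `response = "binary"` as a sensitivity option (with
  ~200 breaks over millions of windows the two nearly coincide).
* Coverage is a fraction in [0, 1], not a percent; reported RRs of order
  10–250 are only dimensionally sensible on this scale. `covariate_scale =
  "percent"` is available.
* Windows on chromosomes absent from a peak file get coverage 0 rather than
  being dropped; no multiple-testing correction is applied across assays or
  window sizes (univariate analyses, as in the source); 1.96 is fixed for
  the 95% CI with `z` configurable.
* Complete separation (all breaks at one extreme of coverage) is reported as
  `converged = FALSE` with a diverging-β diagnostic, never clipped.

A mechanical but important caveat: with peaks *shorter* than the window, the
per-window coverage fraction shrinks as windows grow while the break/no-break
contrast stays, so `exp(β)` grows with window size even at a fixed true
enrichment. This reproduces — and explains — the qualitative 1 kb → 10 kb
escalation of reported risk ratios; the acceptance suite checks exactly this
monotonicity with 300-bp peaks.

## Parental origin

Each trio site compares the derivative-haplotype allele with the parental
genotypes: paternal if present only in the father, maternal if only in the
mother, uninformative if in both, Mendelian error if in neither. Sites are
treated as independent (no haplotype model): the evidence in this design is
the *concordance of all informative sites*, so any disagreement yields
`inconsistent`, and Mendelian errors are excluded from the vote with a
warning but counted. The minimum number of informative sites for a verdict
defaults to 1 (the source reports no threshold) and is configurable. STR
length alleles flow through the same representation as SNV bases.

## The synthetic world

The generator's defaults describe a desk-scale analogue of the study system,
chosen once:

| parameter | default | why |
|---|---|---|
| `n_chroms`, `chrom_len` | 3 × 1 Mb | three-way translocations involve three chromosomes; 1 Mb is a ~100× linear scale-down of a human chromosome that keeps flank arithmetic realistic |
| `n_breaks` | 20 | observed cases carry 4–40 breakpoints; tests sweep that range |
| `peak_fraction` | 0.03 | ATAC peak sets cover a few percent of the genome |
| `peak_len_mean` | 600 bp | typical ATAC peak width |
| `true_rr` | 8 | the 1-kb window estimate in sperm open chromatin is ≈ 7.8 |
| `deletion_prob` | 0.1 | most shattered fragments are recovered; losses are the minority |
| `signature_dist` | mode at 0, P(homology 1–3) decreasing, 25% microinsertions of 1–10 bp | shaped like the observed signature histogram, whose exact counts are not published as numbers |
| `genotype_error` | 0 | error is a knob for the Mendelian-error tests |

Breakpoints follow a two-rate density: rate ∝ `true_rr` inside peaks, 1
outside, so the in-peak fraction has the closed form
`rr·f / (rr·f + 1 − f)`. The enrichment is planted *positionally*, not
mechanistically — the artifact tests the statistic, not sperm biology.
Rearrangement drops interstitial fragments with `deletion_prob`, permutes
and orients the rest into telomere-bounded derivatives, never duplicates a
fragment, and resamples arrangements that would religate two genomically
adjacent ends (such a join is invisible at the sequence level and its
signature would be degenerate). With a single involved chromosome at least
two breaks are required, since a one-break "rearrangement" can only
religate.

Signature planting edits the genome locally: homology *h* copies the last
*h* retained bases of partner A over the first *h* retained bases of partner
B; tandem insertions duplicate B's retained start; inverted insertions write
the reverse complement of the insertion into A's flank; unknown-origin
insertions are random sequences verified absent (both strands) within the
classification radius of both breaks. Single-base guards pin the alignment
ambiguity to exactly the planted tract; because flanks of different
junctions meet across shared break positions, the guards are iterated to a
fixed point over all junctions before sequences are emitted. Insertions
shorter than 5 bp are always planted as tandem copies — every 1–3-mer occurs
within 50 bp of any break, so a shorter "unknown-origin" insertion cannot
exist, and the generator refuses to plant untestable truth. Junction
sequences carry up to `junction_flank` = 80 bp of true flank per side
(clipped near neighbouring breaks so plants never collide).

Seeding: one stream per run; each stage derives its own seed from
`cfg$seed` by a fixed affine map, so every artifact is bit-reproducible and
stages can be re-run independently.

What a green test does **not** establish: real junctions carry sequencing
errors and mismatches (our matching is exact by design); real breakpoints
cluster and follow chromatin domains (ours are conditionally uniform given
the two-rate density); real peak coverage correlates with GC and mappability
(ours is independent of sequence); and real microhomology can be ambiguous
where flanks are repetitive (the generator deliberately plants unambiguous
tracts, and the oracle-equivalence tests cover the ambiguous cases
separately with random constructions).

## Acceptance-test worlds

The enrichment acceptance criteria run in a scaled-down world chosen for
*model faithfulness*, fixed before the tests were first run:

* one 10-Mb chromosome tiled at 1 kb — 10,000 windows per replicate;
* 193 breakpoints per replicate — the pooled cohort count, since the
  headline analysis pools all cases;
* for type-I error and CI coverage, peaks with mean length 100 kb
  (`peak_fraction` 0.1): coverage is then essentially binary per window, so
  `exp(β)` estimates the planted risk ratio without appreciable
  misspecification bias (measured pseudo-true-β bias ≤ 0.6% at RR 50; with
  300-bp peaks the same fit is biased by design — that regime is what the
  monotonicity criterion exercises, with `peak_fraction` 0.02 and mean peak
  300 bp);
* Wald coverage is evaluated at moderate counts; at much smaller event
  counts (a single 4-break case) Wald intervals undercover, which is the
  known small-sample behaviour of the method, not a defect of the
  implementation.

## Known limitations

* Exact-match homology calling only; no probabilistic or mismatch-tolerant
  model (out of scope by design: junctions are Sanger-confirmed).
* The assembler returns one canonical decomposition and an `ambiguous` flag;
  it does not enumerate alternative decompositions or handle ring
  chromosomes.
* Intragenic/intergenic annotation of breakpoints against a gene model, and
  ISCN karyotype strings, are not implemented.
* The CLI's plain-text outputs are the interface; no plotting is bundled
  beyond the circos arc table.
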