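---
title: "Methods: pileup consensus and variant detection for plasmid verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pileup consensus and variant detection for plasmid verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidcons)
```

## The problem

A linearized plasmid is sequenced to high depth on a nanopore device, and the
question is binary but safety-critical: is the molecule in the tube exactly
the sequence we designed? Individual nanopore reads carry percent-scale error,
so the answer has to come from a consensus over thousands of full-length
reads, with enough bookkeeping that every called base can be audited: how many
reads supported it, what the runner-up base was, and how confident the call
is. `plasmidcons` implements that workflow — filtering, strand classification
and pseudopairing, draft construction, pileup consensus under explicit calling
criteria, dual-pass verification against the expected sequence, and subclonal
mixture scanning — together with a read simulator so that every stage is
testable without sequencing data.

## The consensus model

Reads are aligned to a draft reference with a banded, ends-free global
alignment (affine gaps, match +2 / mismatch −4 / gap open −4 / gap extend −2;
indels left-aligned within homopolymers). Observations are tallied in a
position array with one *base column* per draft base and one *between column*
per junction, including the 5′ and 3′ terminals. Base columns count A/C/G/T
support and deletions (gaps); between columns count inserted bases by offset
and the *pass-through* reads that cross the junction without inserting
anything.

Each column is called under two criteria:

1. **Ratio**: the top base must be at least 5× as abundant as the second top
   base. If only this criterion fails, an `N` is emitted — a flag for manual
   inspection, not a call.
2. **Coverage**: the top base's count must be at least 10% of the maximum
   base-column depth. If this fails, no base is emitted at all.

Both thresholds are inclusive ("at least"). Gap counts are deliberately
excluded from the ratio contest at base columns: a deleted base competes only
through the coverage criterion. This is what preserves long homopolymers —
reads systematically under-report run length, so the terminal bases of a
17-mer may be supported by under 20% of reads, and a ratio contest against
the gap count would delete them. The flip side is low sensitivity to true
subclonal deletions: a deletion only manifests when the surviving base drops
below the 10% coverage floor, i.e. above 90% variant fraction. At between
columns pass-through *does* compete in the ratio, which places the insertion
(and SNV) detection floor at 20%: at 80/20 the ratio 4 < 5 produces an N,
at 85/15 the ratio 5.67 clears it and nothing is reported.

Per-base confidence is the percent of reads at a column supporting the called
base; the run passes QC only if the **median** confidence across called bases
exceeds 99.9%. The signal:noise ratio (top count / second count, `inf` when
the second count is zero) is reported per column for inspection.

### Dual passes

Because indels are left-aligned, a variant adjacent to a homopolymer can have
its support split between a base column and a between column in one alignment
frame but not in the other. The consensus is therefore computed twice — once
against the draft and once against its reverse complement (mapped back into
the draft frame) — and the verification reports the union of discrepancies
over both passes. Disagreement between passes is itself evidence that a
variant template may be present. A side effect worth knowing: the reverse
pass, viewed in the forward frame, is exactly the right-aligned display of
indel placement, which is the convention that makes homopolymer coverage
decay run left-to-right in plots (`autoplot()` on the reverse pass).

### The draft

The assembly step is internal: up to 500 reads are subsampled
deterministically, the read whose length is closest to the subsample median
seeds the draft, all subsampled reads are aligned to it, and one polish
iteration re-aligns against the updated draft. The draft caller is
deliberately more permissive than the final caller — it emits the top base
whenever it reaches 5% of max coverage (half the calling floor) and never
emits Ns, because the draft is a scaffold, not a result. Two draft-stage
choices matter and are worth their rationale:

* **Homopolymer extension.** A plain-majority draft can never recover a
  homopolymer run that the seed read under-reports: the insertion evidence at
  the run junction is a minority against pass-through whenever fewer than
  half the reads report more bases than the seed did. The draft caller
  therefore also accepts an insertion that *extends an adjacent run* when it
  clears the 5% coverage floor. Undercall only shortens runs, so this rule
  converges on the true run length and cannot overshoot.
* **5% rather than 10%.** The final 10% coverage decision must be made on the
  full read set, not pre-empted by the 500-read subsample: binomial noise in
  the subsample around a 10% draft threshold would randomly drop a base that
  the full data keeps (this is precisely the 90%-vs-95% deletion boundary).
  Halving the draft floor makes the subsample decision effectively
  noise-free at the boundary while still discarding sequencing artefacts,
  which sit two orders of magnitude lower.

The draft is finally oriented against the expected reference (the seed read
may come from either strand), so all reported coordinates live in the
expected frame.

## Pseudopairing and contamination

Reads are classified as sense or antisense by aligning them to the expected
reference; a read qualifies when it has a single alignment whose number of
matching bases is at least the reference length minus 500. Qualified strand
lists are sorted by read length and zipped into pseudopairs, preferring pairs
of similar length; the pairing rate is the percentage of quality- and
length-filtered reads that end up paired. Reads from an unrelated plasmid of
the same length align at random-DNA identity (~40–55% of bases) and never
reach the qualification bar, so the pairing rate doubles as a contamination
detector: below 90% is flagged, and a fully wrong reference yields exactly
0%. `collapse_pair()` offers a sequence-level stand-in for duplex
basecalling (agreeing columns kept, disagreements resolved by quality, ties
to N); the default "pre-collapsed" mode instead treats input reads as
already duplex-grade, which is the mode the bundled analyses use.

## The simulator

`simulate_reads()` emulates duplex-grade reads of a linearized plasmid:
full-template-length copies in both orientations with

* dispersed errors at 0.07% per base (70% substitutions, 15% insertions,
  15% deletions) — substitutions deliberately rare and scattered;
* homopolymer run-length undercall on runs of ≥ 5 bases, by default a
  per-base dropout of 0.098 (which makes the probability of reporting a full
  17-mer about 17.3%), or an explicit run-length distribution;
* optional strand-specific miscalls at fixed sites, to emulate systematic
  basecaller errors that only one strand exhibits;
* optional ragged ends, junk-length reads and all-low-quality reads for
  exercising the filters.

Together these land near the ~0.5% aggregate error of pseudopaired basecalls
on templates with long homopolymers, with the indel error concentrated in
homopolymers — which is what makes a median per-base confidence above 99.9%
attainable at depth 1000, as it is for real duplex data. Base qualities
default to q20, with simulator-flagged error bases at q14: above the q12
filter threshold (a per-read *minimum* filter would otherwise reject nearly
every read carrying any error) yet below correct bases, so quality
arbitration in `collapse_pair()` has signal to work with. The simulator is
not a basecaller model: quality scores are schematic, errors are independent
given the systematic components, and chimeric or fragmented reads are not
generated (junk reads stand in for them at the filter stage). Passing tests
on simulated data therefore validate the *logic* of the pipeline — criteria,
thresholds, coordinate handling — not basecaller-specific error structure.

`simulate_mixture()` apportions reads among templates with exact
largest-remainder counts, shuffles deterministically, and keeps per-read
provenance in an attribute for tests only.

## Detection limits by construction

With error-free reads and the default criteria, the detection limits of the
mixture scan are arithmetic consequences of the thresholds, and the scan
reproduces them on the 5% grid:

| variant class | minimum detected fraction | why |
|---|---|---|
| SNV | 20% | 80/20 gives ratio 4 < 5 → N; 85/15 gives 5.67 → called |
| insertion | 20% | same contest against pass-through |
| deletion | 95% | surviving base holds ≥ 10% coverage until 90%; 5% < 10% at 95% |

Under the default noisy model the SNV/insertion limits stay at 20–25%
(observed thresholds 25–30% are expected when mixed pairs are duplex-called
upstream, a step outside this package's scope in pre-collapsed mode). A
"detected" mutation means its site shows an N, a changed base, a novel
insertion signal or a dropped base in either pass, matched within a ±3 base
window to absorb indel placement shifts.

## Numerical and implementation choices

* **Banding.** The aligner's band grows adaptively (doubling from 32 columns
  up to the configured `band_width`, default 600) and re-runs whenever the
  optimal path touches the band edge; problems small enough to be cheap are
  given the full band at once, making the banded aligner exact there (this
  is the regime the unbanded-oracle property tests cover). A band narrower
  than the read/reference length difference is an explicit error. For
  unrelated sequences at full length the capped band can underestimate the
  optimal score; qualification only requires that such scores stay far below
  the bar, which they do by construction.
* **Orientation.** A shared k-mer prescreen picks the orientation to align;
  both orientations are fully aligned whenever the prescreen is ambiguous,
  and exact template copies bypass the dynamic program entirely.
* **Ties.** A top-count tie at a base column cannot satisfy the 5× ratio and
  yields N; the second base is reported with an A<C<G<T tie-break; equal
  scores between orientations prefer the forward strand; length ties in
  pairing sort by read id. All stochastic steps take explicit seeds, so
  identical configuration and seed reproduce byte-identical outputs.
* **Degenerate inputs.** Empty pileups, empty consensus sequences, zero reads
  after filtering, bands too narrow to connect endpoints, and mismatched
  FASTQ records are explicit classed errors, not silent results.
* **Terminal columns.** Coverage decays at the extreme 5′/3′ ends (ragged
  ends, leading/trailing overhangs); the standard criteria are applied there
  unchanged, so terminal Ns or dropped terminal bases can occur on shallow
  runs and are visible in the position report.

## Problem sizes in the bundled analyses

The package's tests and the acceptance script run everything at desk scale:
3 kb templates, 1,000–2,000 reads per run, mixture grids of 21 fractions at
1,000 reads each. Detection thresholds depend on variant *fractions*, not
absolute depth, once depth is well above 100, so these sizes measure the same
quantities as a full flow cell at 100,000× depth; what they cannot exercise
is the multi-gigabyte raw-signal and basecalling layer, which is outside the
package's scope from the start.

## Known limitations

* Deletion sensitivity is intrinsically poor (95% fraction) as long as a
  single global coverage floor protects homopolymers; a two-tier floor
  (strict outside homopolymers, 10% inside) would bring deletions in line
  with SNVs and is a natural extension.
* Insertions that extend an existing homopolymer are harder to detect than
  the 20% floor suggests, because their evidence dilutes into the run's
  undercall noise.
* The package verifies a *single* expected template; deconvolving a mixture
  into multiple consensus sequences is out of scope.
* PAF input is supported for interoperability, but external aligners may
  split reads into multiple local hits, in which case the single-alignment
  qualification rule does real work that the internal global aligner (one
  alignment per read, always) makes vacuous.

## A worked call, by hand

```{r worked}
# a column where 500 of 1000 reads support C and 100 support T:
call_column(c(C = 500, T = 100), max_coverage = 1000)

# 800 vs 200 fails the 5x ratio: N
call_column(c(C = 800, T = 200), max_coverage = 1000)$status

# a homopolymer-terminal base at exactly the 10% floor survives a 90% gap
call_column(c(A = 100, gap = 900), max_coverage = 1000)$status
```
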