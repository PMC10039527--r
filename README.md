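# plasmidcons

Sequence verification of linearized plasmids from Oxford-Nanopore-style long
reads, for labs that need a clinical-grade answer to one question: *is the
plasmid in the tube exactly the sequence we designed?*

Single nanopore reads carry percent-scale error, but a full flow cell of a
3–10 kb plasmid yields thousands of full-length reads of the same molecule.
`plasmidcons` turns that redundancy into an auditable consensus:

1. **Filter** — keep reads whose every base has quality ≥ 12 and whose length
   is within 250 bases of the expected template.
2. **Pseudopair** — classify reads as sense/antisense by alignment to the
   expected reference (a read qualifies with a single alignment of at least
   `L − 500` matching bases) and pair the strands by similar length. The
   pairing rate doubles as a contamination alarm: < 90% is flagged, and an
   unrelated plasmid of the same length pairs at exactly 0%.
3. **Pileup consensus** — build a draft from the reads themselves, align all
   reads to it, and tally every draft base and every between-base junction.
   A base is called only if the top base is at least **5×** the second
   (otherwise `N`, flagged for inspection) and reaches at least **10% of max
   coverage** (otherwise dropped — the permissive floor that keeps long
   homopolymers, whose terminal bases may be supported by < 20% of reads).
   Every position carries counts, per-base confidence (% of reads supporting
   the call) and signal:noise; the run passes QC only if the *median*
   confidence exceeds **99.9%**.
4. **Dual pass** — the consensus is computed against the draft *and* its
   reverse complement, because left-aligned indels can hide a variant next to
   a homopolymer in one frame but not the other; discrepancies are unioned
   over both passes.
5. **Verdict** — `verified`, `variant_detected`, `inspect_required` (only N
   calls), `contaminated`, or `qc_fail`.

These thresholds fix the subclonal detection limits by arithmetic: SNVs and
insertions become detectable at a **20%** variant fraction (80/20 fails the
5× ratio; 85/15 passes) and single-base deletions only at **95%** (the
surviving base holds the 10% coverage floor until then). The bundled
`mixture_scan()` measures these limits empirically, and a synthetic read
simulator (strand-specific errors, homopolymer run-length undercall, template
mixtures) makes the whole pipeline testable without sequencing data.

## Worked example

```r
library(plasmidcons)

# a 3 kb synthetic plasmid with a 17-mer homopolymer, and 1,000
# duplex-grade reads (~0.5% error, run-length undercall)
plasmid <- make_reference(3000, seed = 421,
                          homopolymer_runs = list(list(1500, "A", 17)))
reads <- simulate_reads(plasmid, 1000, model = error_model(), seed = 422)

report <- verify_plasmid(reads, plasmid, pipeline_config(seed = 423))
report
#> <verification_report> verdict: verified
#>   pairing rate: 100.0% (contamination not flagged)
#>   median confidence: forward 100%, reverse 100%
#>   passes agree: TRUE
#>   discrepancies: 0

glance(report)           # one-row summary
tidy(report)             # discrepancy table (empty here)
autoplot(report$consensus$forward, from = 1480, to = 1540)
#> coverage decaying across the 17-mer, dashed line at the 10% calling floor
```

The consensus is identical to the template — including the full 17-mer, whose
terminal bases are supported by only ~17% of reads but clear the 10% floor —
and the verdict is `verified`. Swap in the wrong reference and the pairing
rate collapses to 0% with verdict `contaminated`; mix in 20% of reads from a
variant template and its SNV site turns into an `N` with verdict
`inspect_required`.

A thin command-line wrapper covers the same workflow:

```sh
plasmidverify simulate --out reads.fastq --length 3000 --n-reads 1000 --seed 7
plasmidverify verify   --reads reads.fastq --expected plasmid.fasta --out run1
plasmidverify mixscan  --wildtype wt.fasta --variant var.fasta --out scan.tsv
```

`verify` writes the consensus FASTA, a per-position TSV (counts, confidence,
signal:noise and status for all 2L+1 columns) and a JSON run summary with the
resolved configuration, the read-count funnel, pairing rate, QC and verdict.

## The methods vignette

`vignettes/plasmid-verification-methods.Rmd` documents the consensus model
and its assumptions, the draft-construction choices, what the simulator does
and does not emulate, every tunable threshold with its default, and the known
limitations (deletion sensitivity above all).
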