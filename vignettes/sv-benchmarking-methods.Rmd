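---
title: "Methods: SV benchmarking in and outside tandem repeat regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV benchmarking in and outside tandem repeat regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svtrr)
library(dplyr)
```

## The evaluation model

`svtrr` treats SV benchmarking as a pipeline of five well-defined stages:
filter, regionalize, match, count, stratify. Each stage is a pure function
over tibbles, and every downstream number is traceable to a matching
decision made in stage three.

### Record normalization and filtering

An SV record is a chromosome, a 1-based start breakpoint `pos`, an end
breakpoint `end`, a type (`INS` or `DEL`), and a positive size `svlen`.
Insertions are points (`end == pos`); deletions span `(pos, end]` and their
size is defined as `end − pos`. When a VCF record carries both `END` and
`SVLEN`, `END − POS` is authoritative, because the coordinates — not the
declared length — are what the overlap computation consumes; a relative
discrepancy above 10% triggers a warning. Negative `SVLEN` values (the
common deletion convention) are folded to their absolute value, multi-allelic
rows are split per ALT allele, and records without `SVTYPE` are classified
by REF/ALT allele-length difference when the alleles are sequence-resolved.

The default filter keeps insertions and deletions of at least 50 bp — the
conventional lower bound for calling a variant "structural" — on the
autosomes and sex chromosomes, excludes `BND` breakend records (which
encode adjacencies, not resolved alleles), and, for truth sets, keeps
`PASS` records only. The PBHoney Spots dialect additionally drops records
whose `szCount / coverage` support ratio is below 0.2 (kept at exactly
0.2); the two tags are accepted from INFO or from the first sample's
FORMAT fields, since different versions of that caller emit either.
Chromosome names are stripped of any `chr` prefix on ingest so GRCh37
callsets and hg19 annotation tables interoperate.

### Regions and the coordinate convention

TRRs are the union of the `Simple_repeat` (short-pattern) and `Satellite`
(medium/long-pattern) classes of a UCSC RepeatMasker table; benchmark
regions arrive as BED. Both are kept in their native 0-based half-open
coordinates. Region comparison asks only whether *breakpoints* overlap the
regions: the 1-based breakpoint `p` maps to the 0-based point `p − 1`, so a
region `[100, 200)` contains breakpoints 101 through 200 and excludes 100
and 201 — a convention tested on both sides of both edges. A deletion is
"in" a region when *any* of its two breakpoints is (configurable to `all`
or `start` for sensitivity analysis); this is the most literal reading of
requiring breakpoints to overlap the regions, and it matters for long
deletions that start outside a repeat and end inside one. Adjacent or
overlapping regions are deliberately not merged: membership is unaffected
and merging would silently change region counts in reports.

Before any benchmark comparison, *both* the callset and the truth set are
restricted to the benchmark regions, so records outside them contribute to
neither TP, FP, nor FN.

### Matching

Two same-type records are candidate matches when

* **insertions**: breakpoint distance ≤ 200 bp (inclusive), or
* **deletions**: reciprocal overlap ≥ 50% (inclusive), where the
  reciprocal overlap of spans `a` and `b` is `min(o/len_a, o/len_b)` with
  `o` the overlap length — both deletions must be mostly covered by the
  shared stretch.

Candidates must then be assembled into a one-to-one assignment (a call may
not consume two truth records, which would double-count TP). The package
selects the assignment that first maximizes the number of pairs and then
optimizes the total score (minimum summed distance for insertions, maximum
summed overlap for deletions), with ties broken by (reference chromosome,
reference position, call position). A purely greedy best-score sweep is
*not* sufficient here: with two calls and two references sharing a window,
greedily taking the single best-scoring pair can orphan both remaining
records and lose a pair. The implementation therefore decomposes the
candidate graph into connected components and solves each component exactly
by dynamic programming over (reference index × used-call bitmask) — cheap
because genomic candidate graphs decompose into tiny components — and the
test suite verifies equality with a brute-force enumeration oracle on
hundreds of random fixtures. Components larger than 12 records per side
(never observed at the scales this package targets) fall back to the
deterministic greedy sweep.

### Metrics and stratification

`precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F1 = 2PR/(P+R)`.
A metric whose denominator is empty is `NA`, and `NA` propagates into F1 —
an empty stratum must never masquerade as zero performance.

Stratified tables are produced by **matching once, globally**, inside the
benchmark regions, and then distributing TP pairs, FP calls and FN truth
records into the strata `{INS, DEL} × {in TRR, outside TRR} × ({all} ∪
size bins)`. Matching first prevents a call in a TRR from going unmatched
merely because its partner's breakpoint falls 1 bp outside the TRR; the
alternative (partition first, then match per stratum) is available via
`stratify_first = TRUE` for sensitivity analysis, and the two agree
whenever jitter does not carry breakpoints across stratum boundaries. A TP
pair takes the stratum of its *reference* record, because the benchmark's
composition is what defines the strata; FP calls can only use their own
coordinates and size. Per-stratum counts must tile the global counts, and
this conservation identity is asserted on every run, not just in tests.

The size bins 50–100, 100–300, 300–1,000 and > 1,000 bp are half-open on
the right, so the four bins tile `[50, ∞)` with a 1,000 bp SV falling in
the top bin; the side of that boundary is a convention, fixed and tested
here. Pooled per-TRR-stratum summaries are emitted both micro-averaged
(pool counts, then compute) and macro-averaged (average the per-type
metrics), labeled, since pooled headline figures can be read either way.

### Concordance and trios

Multi-caller overlap uses the same matching criteria, with the larger
callset playing the reference role (first argument on ties —
deterministic). For three callsets, a true simultaneous three-way
assignment is ill-defined under pairwise one-to-one criteria, so each
record is labeled with the set of *other* callsets in which its pairwise
comparison found it a partner, and the seven-region overlap decomposition
is reported per set; each set's four regions sum to its record count by
construction. Where the three pairwise assignments disagree the shared
regions seen from different sets can differ slightly — the per-set reading
("fraction of X's calls also detected by Y") is exactly what stacked
overlap figures report, and `overlap_rate()` recomputes such a figure from
its printed counts.

The trio "de novo" rate counts a son record as de novo when it matches no
father record and no mother record under the *same* criteria used for
benchmarking, divided by all son records, overall and per TRR stratum.
These are callset-level rates: they absorb false positives in the son and
false negatives in the parents, which is precisely why observed rates far
exceed biologically plausible de novo rates and why the quantity is worth
monitoring.

## The synthetic-data generator

The generator emulates the *structure* the analysis assumes, with every
random choice recorded as a provenance label so that expected outcomes are
integer identities, not tolerances.

* **Genome**: two 20 Mb chromosomes. Small enough to generate in seconds,
  large enough to hold 1,000+ well-separated records.
* **Truth set**: 1,000 records by default; insertions with probability
  7281/12745 (the composition of the PASS-only insertion/deletion truth
  set the benchmark field works with); sizes drawn from the four bins with
  mix (0.50, 0.30, 0.15, 0.05), reflecting how fast SV counts fall with
  size; the top bin is capped at 5 kb.
* **TRRs**: non-overlapping intervals of 500–3,000 bp laid out by an
  exponential-gap walk covering 10% of the genome — the genome fraction
  tandem repeats occupy. Each truth SV is placed inside a TRR with
  probability `fraction × enrichment`; the default enrichment of 3.5
  yields ~35% of SVs in TRRs, matching the share observed in long-read
  trio callsets.
* **Separation**: planted extents keep a 6 kb minimum gap. This single
  constraint guarantees that distinct planted records can never satisfy
  the matching criteria against each other, which is what turns measured
  TP/FP/FN into exact consequences of the plant.
* **Benchmark regions**: merged truth extents padded by 3 kb, so every
  truth breakpoint sits well inside and false positives have admissible
  space.
* **Derived callsets**: each truth record is dropped with probability
  `fn_rate`; survivors get breakpoint jitter from a rounded normal
  *truncated to recoverable bounds* — insertion breakpoints move at most
  100 bp (half the window, so two independently jittered copies still
  match each other), deletion endpoints at most `len/6` (which keeps
  reciprocal overlap ≥ 0.5 against the source and against any other
  jittered copy) while never shrinking below 50 bp. An optional
  `unrecoverable_rate` displaces calls just beyond the criteria
  (insertions by 201–400 bp, deletions by a 0.6·len span shift), turning
  them into labeled false positives. `fp_rate × n` additional false
  positives are planted inside the benchmark regions at least 1.5 kb from
  every truth extent. The design choice to *plant recoverability* rather
  than rely on jitter distributions is what makes the recovery tests exact
  rather than flaky.
* **Trios**: a pooled site set is split into de novo sites (son only),
  inherited sites (father only / mother only / both, 0.45/0.45/0.10 — a
  rough het-transmission split) and untransmitted parental extras, so the
  planted de novo rate is exactly recoverable by `denovo_rate()`.

What the generator does **not** emulate: read-level errors, aligner-induced
breakpoint biases, realistic insertion sequence content, overlapping truth
deletions, or genotypes. Passing recovery tests therefore demonstrates that
the evaluation machinery is exact, not that any particular caller performs
well on real data; real-data conclusions still require real callsets and a
curated benchmark.

## Numerical and degenerate-input choices

* All coordinates are integer arithmetic; determinism under a fixed seed
  holds across platforms.
* Assignment-score comparisons use a 1e-9 tolerance; scores are small
  rationals (distances, overlap fractions) far apart relative to it.
* Empty callsets, empty region sets, header-only VCFs, and chromosomes
  absent from a region set are all defined inputs with documented results;
  an rmsk table yielding *zero* TRR rows is a hard error, because it
  almost certainly indicates a schema mismatch rather than a repeat-free
  genome.
* Problem sizes: tests run bundles of 120–1,000 truth records and a
  500-fixture matching-oracle sweep at ≤ 8 records per side; the full
  suite completes in under two minutes on a single core.

## Known limitations

* Insertion matching is positional only; inserted sequence similarity is
  not evaluated, so two different insertions at nearby positions can
  match.
* Genotype concordance, phasing and Mendelian-error analysis are out of
  scope; the de novo rate is a callset-overlap quantity.
* The three-way overlap is assembled from pairwise assignments and is an
  approximation wherever those assignments disagree.
* Confidence intervals on precision/recall/F1 are not provided; the
  recovery framework reports exact counts instead.
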