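---
title: "Three-letter bisulfite alignment: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-letter bisulfite alignment: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bisulfite treatment converts unmethylated cytosine to uracil (read as T)
while methylated cytosine is protected. Mapping such reads naively biases
methylation estimates: methylated reads retain more Cs, carry more
information, and map preferentially. The standard remedy is *three-letter*
alignment: both the reads and the genome are C→T (and G→A) converted in
silico before alignment, so mapping is blind to methylation state. The cost
is that the two DNA strands are no longer complementary and must be treated
as separate alignment targets; PCR additionally creates two more strands
(CTOT, CTOB) in non-directional libraries. `methalign` implements the full
desk-scale machinery around this idea: conversion, per-strand candidate
alignment, cross-strand arbitration with recalculated mapping qualities,
methylation-call assignment and extraction, M-bias quality control,
methylation-aware duplicate marking, and a read simulator with a ground-truth
evaluator.

## Strand dispatch

A directional library yields reads from the original top (OT) and original
bottom (OB) strands; a non-directional one adds their PCR complements (CTOT,
CTOB). Read 1 is C→T converted and compared against the C→T genome in
forward orientation (OT) and the G→A genome in reverse-complement
orientation (OB); the G→A-converted copy of read 1 covers CTOT/CTOB. Mate 2
always receives the opposite conversion and orientation of mate 1. These
constraints follow the established three-letter convention; each emitted
record carries `XG` (genome conversion), `XR` (read conversion) and the
winning strand.

## Candidate alignment and scoring

The built-in backend scores reads *ungapped* at every permissible offset of
the converted reference, end to end. The scoring scheme mirrors the
conventions of bowtie2-class aligners so scores are comparable across
backends:

* mismatch penalty interpolated by base quality:
  `penalty(q) = min + (max − min)·min(q, 40)/40`, rounded half away from
  zero; defaults `min = 2`, `max = 6`,
* N in read or reference costs 1,
* a perfect end-to-end alignment scores 0; an alignment is valid when its
  score is at least `−0.6 − 0.6·L` for read length `L`.

The best-scoring offset becomes `AS`, the second best `XS`; ties between
offsets are broken by smallest coordinate, then lexicographic contig name.
Paired candidates require both mates on one strand and contig, forward mate
left of reverse mate, insert at most 1000 bp; the pair score is the summed
mate score. Gapped alignment is deliberately out of the built-in backend:
it adds nothing to the arbitration logic, and the external
bowtie2-compatible backend covers gapped CIGARs, which the extractor and
duplicate marker handle in full (I/D/S/N operations).

Although the contract is "score every offset", the implementation prunes
exactly: with a score budget `B = −score_min(L)`, a valid placement has at
most `maxMM` mismatches, where `maxMM` counts the cheapest per-base mismatch
penalties fitting in `B`. Splitting the read into `floor(L/k)` disjoint
k-mers with `k ≤ L/(maxMM+1)` guarantees (pigeonhole) that every valid
placement contains an exact seed, so scoring only exact-seed hits returns
the same best and second-best as the full scan. Genomes containing N, and
reads too short for the guarantee, automatically take the full scan; the
test suite checks both paths against an independent brute-force oracle.
References above 10 Mb are refused with a pointer to the external backend —
the built-in aligner is a correctness instrument, not a production mapper.

## Arbitration and MAPQ

Each read (or pair) has up to four strand candidates. If exactly one strand
attains the maximum (summed) score it wins; if two or more tie at the
maximum the read is reported unmapped, because such alignments are highly
unreliable. The winner's `XS` is rewritten to the best score among the other
strands' candidates unless its own `XS` is already higher — after this, `XS`
reflects the best alternative *anywhere*, which is what makes the
recalculated MAPQ meaningful for bisulfite data.

MAPQ is a heuristic on two normalised quantities, with
`diff = max(1, −score_min)`:

* `bestOver/diff`, the percentile of `AS` between the minimum valid and the
  perfect score — thresholds 0.8/0.7/0.6/0.5/0.4/0.3 give 42/40/24/23/8/3/0
  when no valid `XS` exists;
* `(AS − XS)/diff` when `XS` is present — graded from 3 (at `AS == XS`)
  through 23, 25, …, 40 to 42 (at a full score-range separation), capped by
  the unique-branch value so MAPQ is non-increasing in `XS` and
  non-decreasing in `AS`.

The published description of this family of heuristics fixes its shape (a
percentile of AS after normalising by the minimum valid and maximum possible
score, lowered as AS−XS shrinks) and its value set {0, 3, 8, 23–42}, not its
constants; the table above is this package's own calibration of that shape,
frozen in the unit tests. 42 is attainable only without a meaningful
alternative; `AS == XS` yields at most 3, so the default `MAPQ ≥ 10`
extraction filter removes everything that mapped equally well twice.

## Methylation calls

For each aligned base the call is made against the *unconverted* genome on
the record's strand: at a top-strand C (for `XG:CT`) a read C is a
methylated call, a read T an unmethylated one, anything else a mismatch with
no call (`.`); at a top-strand G (for `XG:GA`) the roles are played by G/A.
Context is `Z/z` (CpG), `X/x` (CHG), `H/h` (CHH) with CpG precedence,
read 5'→3' on the originating strand; a context window that runs off the
contig or into an N yields no call, since the context is undefined.
Insertions and soft clips get `.`; deletions advance the genome.

## Extraction

Records that are unmapped, duplicate-flagged, secondary, or below
`min_mapq = 10` are skipped, as are calls below `min_phred = 5` and read
positions outside the per-(strand, mate) trim bounds. Overlapping mate
segments are processed as a unit on *reference* coordinates (CIGAR-aware, so
indels cannot misalign the comparison): one surviving call is used; two
agreeing calls count once; two surviving calls that disagree disqualify the
position. "Surviving" means above the Phred floor — a below-floor call is
treated as absent, which makes the read-with-N rule and the low-quality rule
one rule.

Counts are keyed by (contig, 0-based position, strand of the cytosine,
context) and written per context as bedGraph
(`chrom start end percent n_meth n_unmeth`, integer-rounded percent — the
common 6-column methylation dialect). `merge_cpg()` folds the bottom-strand
C of each CpG into its top-strand partner; `merge_replicates()` adds counts
across runs; `export_format()` writes methylKit and BSseq per-site dialects.
Converters for further downstream formats are deliberately out of scope to
bound the format-maintenance surface.

## M-bias

Apparent methylation should not depend on position within the read; end
repair and 3' quality decay violate this at the read ends. `compute_mbias()`
tallies CpG calls per read position, stratified by strand and mate, under
the same MAPQ/Phred filters as extraction. `suggest_bounds()` takes the
median percentage over the central 50% of covered positions as the plateau
and suggests the longest contiguous run of positions within
`tolerance_pct = 2` points of it; everything outside is the region to
ignore. The heuristic is this package's own (tolerance and the minimum
number of covered positions are tunable); it is deliberately simple and is
checked against an exhaustive longest-run search. Two practical notes:

* the per-position percentage is a binomial estimate; with fewer than a few
  thousand calls per position its sampling noise approaches the 2-point
  tolerance and the suggested run can fragment. The bundled checks therefore
  use CpG-dense genomes at ≥50× so each position has enough calls;
* suggestions are per (strand, mate) independently, and are *not* applied
  automatically — extraction takes them as an explicit `trims` argument.

## Duplicate marking

Two units (reads, or pairs as ordered units) are duplicate candidates when
they share contig, strand and soft-clip-adjusted 5' coordinates (leading
clip subtracted for forward records; rightmost aligned base plus trailing
clip for reverse ones). Candidates must additionally *match on methylation*:
calls from bases with Phred ≥ 5 must agree wherever both units have one; a
call present in only one unit does not make them differ. Within a bucket,
units join the first group whose representative they match (greedy — the
match relation is not transitive, so grouping semantics must be fixed
explicitly; processing order is deterministic by coordinate then name), and
in each group the unit with the highest sum of base Phred scores is kept
unmarked. This marks a subset of what position-only marking would — the gap
is exactly the position-identical, methylation-discordant units, which are
biologically distinguishable molecules rather than PCR copies.

The tibble API sorts internally (contig, position, name) so grouping is
reproducible regardless of input order; the file-based path requires a
coordinate-sorted BAM and rejects anything else. One desk-scale caveat,
found while validating the pipeline: on a very small genome at high
coverage, unrelated single-end reads collide on (strand, 5' coordinate) by
chance, and marking then removes genuinely independent fragments —
preferentially the methylation-concordant ones — biasing recovered
methylation slightly low. Paired-end signatures (both coordinates) make such
collisions negligible; on genome-scale references the effect is irrelevant
for either design.

## The simulator

`simulate_reads()` emulates a bisulfite library on a known genome: fragments
uniform over positions and strands (length Normal(200, 40) clamped to the
read length for pairs), per-cytosine methylation Bernoulli by context
(defaults CpG 0.7, CHG/CHH 0.01 — mammal-like), unmethylated Cs converted
with probability 1.0, per-base substitution errors at 0.1%, constant Q40
qualities with an optional linear 3' decay, non-directional libraries
emitting PCR-complement copies with probability 0.5, and an optional forced
unmethylated stretch at the fragment 5' end (`bias_5p`) to emulate an
end-repair artifact. The truth — contig, 1-based fragment start, strand and
the methylation mask of the fragment's cytosines — travels in the read name
(`sim0000001:chr1:1234:+:0110…`), so evaluation needs no sidecar file. Runs
are byte-reproducible given the seed.

What the simulator does *not* emulate: PCR amplification families (duplicate
marking true positives must be injected explicitly), incomplete bisulfite
conversion spike-ins, quality-dependent error profiles, adapter
read-through (trimming is assumed upstream), and repeat structure beyond
what the supplied genome contains. Passing recovery tests on this generator
therefore demonstrates the correctness of the conversion/alignment/
extraction chain, not robustness to every artifact of real libraries.

`evaluate_accuracy()` classifies each unit as correct (mapped, chromosome
and leftmost coordinate equal to truth; both mates for pairs), incorrect
(mapped elsewhere) or discarded (unmapped), overall and after the
`MAPQ ≥ 10` filter a default extraction would apply. `concordance()`
compares two runs of the same reads by name: concordant means same
chromosome and start coordinate.

## Numerical and design choices

* Rounding: penalty interpolation rounds half away from zero.
* Tie-breaks: offsets by smallest coordinate then contig name; duplicate
  groups by coordinate then read name; `which.max` semantics avoided in
  favour of explicit rules.
* Contig edges: methylation context that needs a base beyond the end is no
  call.
* RRBS reduction defaults to MspI (`C^CGG`, cut offset 1) with a 40–600 bp
  size window — common RRBS practice; both are arguments.
* Paired records carry the pair-level `AS`/`XS` (the quantities arbitration
  used) and the pair MAPQ on both mates.
* The seeded scan uses `k = 8`; the index is engaged for contigs ≥ 4096 bp
  without N.
* Problem sizes in the bundled checks were chosen to make binomial sampling
  error small relative to the tolerances: 100 kb genome with 50 000 pairs
  (≈50×) for parameter recovery, a 5 kb duplicated segment in 35 kb at ≈20×
  for the MAPQ-filter check, and a CpG-dense 50 kb genome at ≈60× for
  M-bias suggestion stability.

## Limitations

* The built-in aligner is ungapped and capped at 10 Mb of reference; it
  exists to make arbitration, extraction and QC fully testable without
  external downloads. Production-scale gapped alignment is delegated to an
  external bowtie2-compatible backend (`align_external()`, `build_index()`).
* Color-space reads, local alignment, targeted-capture strand-bias
  optimisation and cluster distribution are out of scope.
* Differential-methylation statistics are downstream concerns; the exporters
  hand counts to the packages that do that well.
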