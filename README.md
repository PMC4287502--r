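# methalign

Strand-aware bisulfite sequencing (BS-seq) alignment and methylation
extraction as a desk-scale R toolkit.

Bisulfite conversion turns unmethylated cytosine into uracil (sequenced as
T) and leaves methylated cytosine intact — the gold standard for single-base
methylation measurement. Mapping converted reads directly biases methylation
estimates, because methylated reads keep more Cs and map better. The
standard fix is *three-letter* alignment: C→T (and G→A) convert both reads
and genome, align blind to methylation, and recover the methylation calls
afterwards from the unconverted sequences. The price is up to four
non-complementary alignment targets per read — the original top and bottom
strands (OT, OB) and, for non-directional libraries, their PCR complements
(CTOT, CTOB) — which ordinary aligners cannot arbitrate between.

`methalign` is for people building, validating, or teaching BS-seq
processing pipelines: it implements every step between trimmed FASTQ and
statistics-ready methylation tables as inspectable, tested R functions with
tibbles in and out.

## What it computes

For a read with per-strand alignment scores (the `AS` tag, 0 for a perfect
end-to-end alignment, at least `−0.6 − 0.6·L` to be valid):

* **Arbitration** — the strand with the unique maximum (for pairs, summed)
  `AS` wins; ties across strands are emitted *unmapped*. The winner's `XS`
  (second-best score) is rewritten to `max(XS_own, best AS of the other
  strands)`, so it reflects the best alternative anywhere.
* **MAPQ recalculation** — a heuristic on `(AS − scoremin)/|scoremin|` and
  `(AS − XS)/|scoremin|` mapping into {0, 3, 8, 23–42}; 42 needs a perfect,
  alternative-free alignment, and `AS = XS` gives ≤ 3, so the default
  `MAPQ ≥ 10` filter removes everything ambiguous.
* **Methylation calls** — per base against the unconverted genome:
  `Z/z` CpG, `X/x` CHG, `H/h` CHH (upper = methylated), `.` = no call;
  extraction honours MAPQ ≥ 10, Phred ≥ 5, per-stratum trim bounds, and
  processes overlapping mates as a unit (agree → once, one-sided → used,
  conflict → dropped).
* **M-bias** — per-position CpG methylation by strand and mate, with
  suggested inclusion bounds (longest run within ±2 points of the central
  median).
* **Duplicates** — units sharing strand and soft-clip-adjusted 5'
  coordinates *and* matching methylation calls (Phred ≥ 5) are marked,
  keeping the copy with the highest Phred sum.
* **Simulation & evaluation** — a bisulfite read simulator with truth in the
  read names, plus accuracy (correct/incorrect/discarded, with and without
  the MAPQ filter) and run-to-run concordance summaries.

## Worked example

```r
library(methalign)

set.seed(10)
genome <- bs_genome(c(chr1 = paste(
  sample(c("A", "C", "G", "T"), 50000, TRUE, prob = c(.3, .2, .2, .3)),
  collapse = "")))

reads <- simulate_reads(genome, sim_config(n_fragments = 5000,
                                           pairing = "paired", seed = 100))
aln <- align_bs(reads, genome, protocol("directional", "paired"))
evaluate_accuracy(aln)
#> <bs_accuracy>
#>   all        correct 100.00%  incorrect  0.00%  discarded  0.00%  (n=5000)
#>   mapq>=10   correct 100.00%  incorrect  0.00%  discarded  0.00%  (n=5000)

counts <- extract_methylation(mark_duplicates(aln), genome)
head(counts, 5)
#> # A tibble: 5 × 6
#>   chrom   pos strand context n_meth n_unmeth
#>   <chr> <int> <chr>  <chr>    <int>    <int>
#> 1 chr1     10 -      CHH          0        1
#> 2 chr1     21 -      CpG          1        0
#> 3 chr1     22 -      CHG          0        1
#> 4 chr1     25 -      CHH          0        2
#> 5 chr1     26 +      CHG          0        1

cp <- counts[counts$context == "CpG", ]
100 * sum(cp$n_meth) / sum(cp$n_meth + cp$n_unmeth)
#> [1] 69.96
```

Every simulated read was placed exactly where it came from, and the
extracted genome-wide CpG methylation (69.96%) recovers the simulated 0.7:
per-site counts are keyed by contig, 0-based position, the strand carrying
the cytosine, and context, so `pos 21, strand -` is the G of the CpG whose C
sits at 20. `write_bedgraph()`, `merge_cpg()`, `coverage_metrics()` and
`export_format(..., "methylKit" | "BSseq")` take it from there, and
`compute_mbias()` / `suggest_bounds()` provide the QC trim bounds that
`extract_methylation()` accepts via `filter_config(trims = ...)`.

Alignments carry the usual tags, e.g.:

```
qname                                       chrom   pos mapq strand XM
sim0000002:chr1:26889:+:0000110010001010    chr1  26889   42 OT     hh.......h...xZ.......Z.x.....…
```

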