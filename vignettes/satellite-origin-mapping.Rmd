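---
title: "Mapping the genomic origins of satellite RNA by mate-pair anchoring"
author: "satanchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the genomic origins of satellite RNA by mate-pair anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satanchor)
```

## The problem

Satellite DNAs are megabase-scale arrays of short tandem repeats (AAGAG,
AATAT, ...) concentrated in pericentromeric heterochromatin. When such
arrays are transcribed, the resulting RNA is essentially unmappable: a read
consisting of `AAGAGAAGAG...` aligns equally well to every AAGAG array in
the genome, so standard RNA-seq pipelines discard it and the *locus of
origin* of the transcript remains unknown.

Paired-end libraries offer a way out. If a sequenced fragment straddles the
junction between a satellite array and its flanking unique sequence, one
read of the pair is repeat-filled (the *anchor*) while its mate carries
unique flanking sequence. The mate can be mapped; the anchor tells us the
fragment came from a satellite transcript. `satanchor` implements this
mate-pair anchoring strategy end to end:

1. **scan** reads for maximal perfect tandem runs of a motif
   (`find_tandem_runs()`);
2. **classify** pairs in which exactly one read carries a run of at least
   three complete motif copies and extract the other read
   (`classify_and_extract()`);
3. **assemble** the extracted mates into contigs with a greedy
   overlap-layout-consensus assembler (`assemble()`);
4. **map** contigs onto the genome with an exact-seed, ungapped-extension
   aligner filtered by a chance-expectation e-value (`map_contig()`);
5. **call** an origin locus wherever a uniquely mapped contig lies adjacent
   to an annotated satellite block (`annotate_blocks()`, `call_origins()`).

`run_pipeline()` chains the five steps per sample and writes a locus table
with one row per merged locus and one column per sample, a BED track, and a
JSON run report with counts at every stage.

## The tandem-run model

A *run* is a maximal interval of the sequence that is a substring of the
infinite repetition of the motif unit, starting at any cyclic phase.
Internally, a window of unit width matches when it equals some cyclic
rotation of the unit; a run is a maximal stretch of consecutive matching
windows. Two conventions matter and are fixed package-wide:

* **Complete copies only.** `copies = floor(run length / unit length)`.
  Partial leading or trailing copies extend the interval but never the
  count, which makes the "at least three consecutive repeats" anchoring
  rule unambiguous: a 14-base AAGAG stretch is two copies, a 15-base
  stretch is three.
* **Canonical motif.** Units are stored as their lexicographically smallest
  rotation, so `AGAGA` and `AAGAG` are one motif. The reverse-complement
  unit is scanned separately and reported with strand `-`; total-RNA
  libraries are not assumed stranded, and the anchor strand is recorded so
  a stranded analysis can filter on it.

`N` and any non-ACGT character terminate runs (conservative behaviour on
masked genomes). Note that two maximal runs may legitimately overlap by up
to one unit length minus one base (a phase break such as
`GGCGGCGGC|GCG`); the scanner reports both, and the test suite checks exact
agreement with an independently written regular-expression oracle over
thousands of seeded random strings.

## Trimming

The trimmer is intentionally minimal and deterministic: a read is cut at
the first occurrence of an exact eight-base prefix of the adapter, then 3'
bases below Q20 are stripped, and a pair is dropped when either mate falls
below 20 bases. It replaces an external trimming tool in spirit only; it is
not a reimplementation of that tool's algorithm. Trimming precedes
classification, so anchor detection always sees quality-clipped sequence.

## Assembly

Anchored mates from one locus tile its unique flank at high depth, so a
simple greedy assembler suffices — and a simple assembler is an *exactly
testable* one. Parameters mirror a conventional assembler configuration:

| parameter | default | meaning |
|---|---|---|
| `min_seed` | 10 | exact-match stretch an overlap must contain (minimum match length) |
| `min_score` | 30 | minimum ungapped overlap score, match +1 / mismatch −2 |
| `max_mismatch_frac` | 0.05 | stringency: tolerated mismatch fraction per overlap |

The implementation is the classic layout-based greedy OLC: all qualifying
pairwise **read** overlaps (found via shared 10-mers, evaluated ungapped in
both orientations) are ranked by score and consumed best-first; each
accepted overlap merges the two reads' contigs by transplanting one layout
into the other's coordinate frame. Consensus is voted per column at the
end, majority rule, ties resolved toward the member earliest in input
order. An earlier design re-evaluated contig-consensus against
contig-consensus overlaps after each merge; it was abandoned because
depth-1 errors at a contig junction can inflate the consensus mismatch
fraction past 0.05 and veto a join that the underlying read overlaps
support — the layout formulation uses the reads as the evidence, as
assemblers of this family do.

Scoring is ungapped by design: the simulation and the intended data carry
substitution errors, mates are short, and ungapped scores make every test
assertion computable by hand. Indel tolerance is out of scope. The
`min_score = 30` floor is also what prevents chimeras: two mates from
different loci can share at most a short satellite tail (under 15 bases,
else the mate would itself be an anchor), which can never reach a score of
30.

Singleton mates are emitted as single-member contigs and proceed to
mapping flagged as such (`n_members = 1`): downstream, a genuine locus is
typically supported by a multi-member contig, but singletons merging into
the same interval do no harm because loci are unioned.

## Genome annotation

`annotate_blocks()` applies the same scanner to the genome and keeps
maximal runs **strictly longer** than `min_block_len = 50` bases, reading
the "greater than 50 bp" convention literally (an inclusive mode exists).
Perfect runs only: an interrupted array appears as several blocks, and an
optional `gap_merge` pass (default off, recorded in the metadata when
used) can join same-strand blocks separated by short interruptions.
Blocks are GRanges and export as 6-column BED.

## Mapping and the e-value model

Contigs are placed by exact 12-mer seeds (both strands) extended ungapped
in both directions under an X-drop of 10, deduplicated to the best hit per
(chromosome, strand, diagonal). Each hit is scored by a deliberately simple
chance-expectation model:

$$E = 2 \cdot N \cdot L \cdot 4^{-s}, \qquad s = \text{matches} - 2\cdot\text{mismatches}$$

that is, two strands times genome length times contig length times the
probability of a chance exact match of the hit's *effective length* (its
score). This is not the full Karlin–Altschul statistic; it is a desk-scale
model chosen because it can be calibrated directly by Monte-Carlo: the
acceptance suite maps dinucleotide-shuffled 80-mers against a 500-kb
random genome and requires that at most 1 in 100 passes the $10^{-5}$
threshold, while verbatim genomic 80-mers always pass. The threshold
$10^{-5}$ itself is the conventional stringent cutoff for this kind of
screen. With $k_{\text{eff}} \gtrsim 21$ required to pass at this genome
size, seeds alone (12 exact bases) never suffice — an extension over
genuinely homologous sequence is needed.

**Uniqueness** is defined here (no external definition exists): a contig is
uniquely mapped when a single hit passes the filter, or when the runner-up
score is below 0.9 of the best. **Adjacency** uses a 1,000-base window,
the scale of a short-insert fragment plus a mate: a mate maps at most
roughly one fragment length away from the array junction. Both are
configurable.

Origin loci from overlapping contigs are merged by interval union, contig
ids concatenated. Locus ids are rendered `chrom.start.end`, 1-based
inclusive — the field's display convention — while BED output is 0-based
half-open; GRanges (1-based, closed) is the internal representation
throughout, and the BED round-trip is covered by a test against an
independent reader.

## The synthetic-data generator

`default_scenario()` is the package's study condition, fixed once:

* one 500-kb chromosome of i.i.d. uniform ACGT background;
* six planted perfect AAGAG arrays: three transcribed arrays with adjacent
  500-nt unique flanks (the expected loci, 200 nt of satellite each), one
  transcribed array whose transcript flank is a copy of a distal region
  more than 5 kb from every block (expected negative: its mates map
  uniquely but not adjacent to any block), and two silent arrays of 150 nt
  (expected negatives);
* forty background transcripts of 1,500 nt of unique sequence — ten times
  the satellite transcript count — so stage-conservation statistics are
  non-trivial;
* 50,000 pairs of 75-nt reads, fragment lengths Normal(300, 30) truncated
  to [read length, transcript length], uniform fragment starts,
  substitution errors at 1% per base, constant Q30 qualities.

Every random choice derives from one seed; identical seeds give
byte-identical FASTA/FASTQ/manifest outputs, which is itself under test.

Ground truth is computed by the generator, not the pipeline: each
simulated pair records its transcript coordinates, and `expected_loci()`
projects the flank-side mates of anchored pairs (exactly one read covering
at least three complete copies, by fragment geometry) onto the genome. The
truth ignores the possibility that a substitution error breaks an anchor
run, or that a flank base extends one by chance; at several hundred
anchored pairs per locus the coverage extremes are always represented by
error-free anchors, so locus endpoints are compared at ±100 bases.

What the generator does **not** emulate — and therefore what passing tests
do *not* establish about real libraries: GC and hexamer-priming bias,
quality-score decay, indels, PCR duplicates, spliced transcripts,
interrupted or higher-order repeat structure, and collapsed or
mis-assembled satellite arrays in real genome assemblies. On real data the
adjacency window and the uniqueness margin are the two knobs most worth
revisiting.

## Quantification statistics

The package ships the two per-testis sperm-morphology count tables as TSV
fixtures (`defect_table_fixture("table7")`, `"table8"`) and reproduces the
pooled-percent convention: category counts are summed over testes within a
genotype and expressed relative to that genotype's total scored bundles.
Pooling is associative and order-invariant, which the tests exercise, and
an all-zero genotype is an error rather than a silent `NaN`.

`welch_t_test()` is the spreadsheet "type 3" test — two-sample, unequal
variance, two-tailed — implemented from the Welch statistic and
Welch–Satterthwaite degrees of freedom, and cross-checked against the
reference implementation in the `stats` package to $10^{-10}$ over seeded
random cases. It reduces to the pooled test's degrees of freedom when
variances and sample sizes coincide. Viability ratios (RNAi / Tubby pupae
per vial; vials without Tubby pupae are excluded with a warning) and
fertility summaries (per-parental-set percent fertile; males failing the
survival condition leave the denominator; cross-set mean ± sample SD)
reuse it for group comparisons. No multiple-testing correction is applied
by default, matching the raw pairwise reporting convention; sample
standard deviation (n − 1) is used throughout. A power property is kept
under test: with 11 vials per group of ~25 pupae and true ratios 1.0
versus 0.5, the Welch comparison rejects at α = 0.05 in at least 90% of
500 seeded replicates.

## Numerical and degenerate-input choices

* Deterministic tie-breaks everywhere: overlaps prefer higher score, then
  longer overlap, then `+` orientation, then smaller offset; anchor runs
  prefer more copies, then `+` strand; consensus ties go to the earliest
  member.
* All generators save and restore the caller's RNG state; the pipeline
  itself draws no random numbers (the seed in a config is recorded in the
  report for provenance only).
* Empty inputs: an empty genome annotates to an empty GRanges; a dataset
  with zero anchored pairs produces an empty locus table and a report whose
  classification stage reads 0; an empty hit list is an error in
  `uniqueness_filter()` (callers check first); a screen over zero pairs is
  an error because per-million normalization is undefined.
* Problem sizes in the test and acceptance suites (500-kb genome, 50,000
  pairs, 1,000 oracle strings per motif, 100 Monte-Carlo mapping trials,
  20 assembler replicates) were chosen as the smallest sizes at which the
  statistical checks have comfortable margins; all complete in a few
  minutes on one CPU.

## Known limitations

Perfect-repeat detection only (no approximate or interrupted repeat
model); ungapped assembly and mapping; no mapping-quality model beyond the
uniqueness margin; the orientation consistency between an anchor's strand
and its mate's placement is recorded but not enforced; and the e-value
model treats the genome as i.i.d. uniform — on real heterochromatin-rich
genomes, low-complexity flanks will produce more near-threshold hits than
the calibration suggests.
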