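# satanchor

Satellite-anchored mate-pair localization of tandem-repeat RNA from
paired-end RNA-seq.

## The problem

Satellite DNAs — long arrays of short tandem repeats such as AAGAG(n),
abundant in *Drosophila* pericentromeric heterochromatin — are transcribed,
but satellite RNA reads cannot be mapped: a read of pure `AAGAGAAGAG...`
matches every AAGAG array in the genome. `satanchor` localizes the genomic
origins of such transcripts with a mate-pair anchoring strategy. For each
read pair in which exactly one read carries a tandem run of at least
**3 complete motif copies** (either strand), the other read — the uniquely
mappable *mate* — is extracted. Mates are assembled into contigs with a
greedy overlap-layout-consensus assembler (ungapped score: match +1,
mismatch −2; minimum exact seed 10; minimum overlap score 30; mismatch
fraction ≤ 0.05), placed on the genome by exact 12-mer seed-and-extend
alignment, filtered at a chance-expectation e-value

> E = 2 · N · L · 4^(−s),  s = matches − 2·mismatches,  keep E ≤ 10⁻⁵

and tested for uniqueness (runner-up score < 0.9 × best). An **origin
locus** is called wherever a uniquely mapped contig overlaps or lies
within 1,000 bases of a **satellite block** — a maximal genomic motif run
strictly longer than 50 bp. Loci are reported as `chrom.start.end`
(1-based, inclusive), one row per merged locus and one column per sample.

The package also provides a per-motif satellite expression screen over
FASTQ (counts per million pairs), a fully seeded synthetic-data generator
with ground-truth manifests, and the small quantification statistics used
alongside the screen: pooled sperm-defect proportions (with the printed
per-testis count tables as fixtures), Welch "type 3" t tests, viability
ratios and fertility summaries.

## Worked example

Generate the default synthetic scenario — a 500-kb chromosome with six
planted AAGAG arrays (three transcribed with adjacent unique flanks, one
transcribed with a distal flank, two silent) and paired 75-nt reads with
1% substitution error — then run the pipeline:

```r
library(satanchor)

sc <- default_scenario("scenario", seed = 42, n_pairs = 20000)
res <- run_pipeline(pipeline_config(
  fastq1 = sc$files$fastq1, fastq2 = sc$files$fastq2,
  genome = sc$files$genome, motif = "AAGAG", sample = "e16-20hr",
  out_dir = "out", seed = 42))
res$loci[["e16-20hr"]]
#> GRanges object with 3 ranges and 5 metadata columns:
#>       seqnames        ranges strand |           locus_id      sample
#>   [1]     chr1   49672-50010      * |   chr1.49672.50010    e16-20hr
#>   [2]     chr1 149676-149996      * | chr1.149676.149996    e16-20hr
#>   [3]     chr1 249679-249987      * | chr1.249679.249987    e16-20hr
#>             contigs n_contigs  distance
#>   [1] ctg004,ctg005         2         0
#>   [2]        ctg003         1         2
#>   [3]        ctg002         1        12
```

Exactly the three planted transcribed-adjacent arrays are recovered: each
locus is the flank interval covered by anchored mates, ends at the array
junction (distance to the nearest >50-bp AAGAG block: 0–12 bases), and the
distal-flank and silent arrays are correctly absent. The run report counts
every stage (here 20,000 pairs in, 426 anchored mates, 5 contigs, all
uniquely mapped, 3 loci); `out/loci.tsv` holds the locus-by-sample table,
`out/loci.bed` and `out/blocks.bed` the tracks.

The expression screen on the same reads:

```r
pairs <- read_fastq_pairs(sc$files$fastq1, sc$files$fastq2, "e16-20hr")
motif_expression_screen(pairs, c("AAGAG", "AATAT"), min_copies = 3)
#>     sample motif pairs_total anchored_pairs anchored_per_million
#> 1 e16-20hr AAGAG       20000            429                21450
#> 2 e16-20hr AATAT       20000              0                    0
```

and the pooled sperm-defect proportions from the packaged control rows:

```r
pp <- pooled_proportions(defect_table_fixture("table7"))
subset(pp, genotype == "Scrambled RNAi")
#>         genotype       category count total percent
#> 1 Scrambled RNAi  normal_bundle    72   100      72
#> 2 Scrambled RNAi lagging_bundle    18   100      18
#> 3 Scrambled RNAi         kinked    10   100      10
#> 4 Scrambled RNAi        knotted     0   100       0
#> 5 Scrambled RNAi    needle_eyed     0   100       0
#> 6 Scrambled RNAi    decondensed     0   100       0
```

72% of the 100 pooled control bundles are morphologically normal.

A thin command-line wrapper with `run`, `scan`, `screen`, `annotate`,
`assemble`, `map`, `simulate` and `quantify` subcommands ships at
`inst/cli/satanchor.R` (installed under `system.file("cli", package =
"satanchor")`).

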