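small_arrays <- function() {
  data.frame(chrom = "chr1", start = c(10000L, 20000L),
             motif = "AAGAG", copies = c(40L, 30L),
             transcribed = c(TRUE, FALSE), stringsAsFactors = FALSE)
}

test_that("genome generation is deterministic and plants exact arrays", {
  d <- withr::local_tempdir()
  g1 <- generate_genome(seed = 42, chrom_len = 50000L,
                        arrays = small_arrays(),
                        out_fasta = file.path(d, "a.fa"))
  g2 <- generate_genome(seed = 42, chrom_len = 50000L,
                        arrays = small_arrays(),
                        out_fasta = file.path(d, "b.fa"))
  expect_identical(unname(tools::md5sum(file.path(d, "a.fa"))),
                   unname(tools::md5sum(file.path(d, "b.fa"))))
  # each planted array produces exactly one block containing it (a chance
  # background base may extend a maximal run by a few bases at either end)
  b <- annotate_blocks(g1$genome, motif("AAGAG"))
  expect_equal(length(b), 2L)
  expect_true(all(GenomicRanges::start(b) <= c(10000L, 20000L)))
  expect_true(all(GenomicRanges::end(b) >= c(10199L, 20149L)))
  expect_true(all(GenomicRanges::width(b) <= c(200L, 150L) + 8L))
  # no arrays -> no blocks
  g0 <- generate_genome(seed = 1, chrom_len = 30000L)
  expect_equal(length(annotate_blocks(g0$genome, motif("AAGAG"))), 0L)
  # overlap and spacing validation
  bad <- small_arrays()
  bad$start <- c(10000L, 10100L)
  expect_error(generate_genome(seed = 1, chrom_len = 50000L, arrays = bad),
               "2 kb")
})

test_that("transcripts span flank + array; silent arrays yield none", {
  g <- generate_genome(seed = 5, chrom_len = 50000L, arrays = small_arrays())
  t <- generate_transcripts(g$genome, g$manifest, flank_len = 500L,
                            n_background = 3L, background_len = 1000L)
  tx <- t$manifest$transcripts
  sat <- tx[tx$type == "satellite", ]
  expect_equal(nrow(sat), 1L)          # only the transcribed array
  expect_equal(sat$length, 500L + 200L)
  expect_true(sat$adjacent)
  gseq <- as.character(g$genome[[1]])
  expect_equal(as.character(t$transcripts[[sat$name]]),
               substr(gseq, 10000L - 500L, 10199L))
  # minus-strand spec gives the reverse complement
  arr <- small_arrays()
  arr$strand <- c("-", "+")
  gm <- generate_genome(seed = 5, chrom_len = 50000L, arrays = arr)
  tm <- generate_transcripts(gm$genome, gm$manifest, flank_len = 500L,
                             n_background = 0L)
  expect_equal(as.character(tm$transcripts[[1]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(gseq, 9500L, 10199L)))))
  # background transcripts avoid arrays and are pure unique sequence
  bg <- tx[tx$type == "background", ]
  expect_equal(nrow(bg), 3L)
  for (i in seq_len(nrow(bg)))
    expect_true(bg$flank_end[i] < 10000L || bg$flank_start[i] > 10199L ||
                bg$flank_end[i] < 20000L || bg$flank_start[i] > 20149L)
})

test_that("read simulation geometry, error model and determinism", {
  set.seed(1)
  tx <- c(t1 = random_dna_str(1200), t2 = random_dna_str(600))
  sim <- simulate_read_pairs(tx, n_pairs = 3000, read_len = 75,
                             frag_mean = 300, frag_sd = 30,
                             error_rate = 0, seed = 9)
  # error-free reads are exact substrings of a transcript / its revcomp
  idx <- sample(3000, 50)
  for (i in idx) {
    t <- tx[[sim$truth$transcript[i]]]
    expect_equal(sim$pairs$seq1[i],
                 substr(t, sim$truth$frag_start[i],
                        sim$truth$frag_start[i] + 74L))
    expect_equal(sim$pairs$seq2[i],
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(substr(t, sim$truth$frag_end[i] - 74L,
                                                sim$truth$frag_end[i])))))
  }
  # fragment length mean within 3 standard errors of 300
  fl <- sim$truth$frag_end - sim$truth$frag_start + 1
  expect_lt(abs(mean(fl) - 300), 3 * 30 / sqrt(3000) + 0.5)
  # sampling proportional to transcript length
  expect_gt(mean(sim$truth$transcript == "t1"), 0.6)

  # determinism: same seed, byte-identical FASTQ
  d <- withr::local_tempdir()
  for (run in c("x", "y")) {
    simulate_read_pairs(tx, n_pairs = 500, error_rate = 0.01, seed = 11,
                        fastq1 = file.path(d, paste0(run, "_1.fastq")),
                        fastq2 = file.path(d, paste0(run, "_2.fastq")))
  }
  expect_identical(unname(tools::md5sum(file.path(d, "x_1.fastq"))),
                   unname(tools::md5sum(file.path(d, "y_1.fastq"))))
  expect_identical(unname(tools::md5sum(file.path(d, "x_2.fastq"))),
                   unname(tools::md5sum(file.path(d, "y_2.fastq"))))

  # error model: fragments identical per seed, ~1% of bases substituted
  sim1 <- simulate_read_pairs(tx, n_pairs = 3000, error_rate = 0.01,
                              seed = 9)
  expect_identical(sim1$truth, sim$truth)
  nerr <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim1$pairs$seq1[idx], sim$pairs$seq1[idx]))
  rate <- nerr / (50 * 75)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / (50 * 75)) + 1e-9)

  # round-tripping through FASTQ preserves the pairs
  f1 <- file.path(d, "rt_1.fastq")
  f2 <- file.path(d, "rt_2.fastq")
  s <- simulate_read_pairs(tx, n_pairs = 100, error_rate = 0, seed = 3,
                           sample = "s", fastq1 = f1, fastq2 = f2)
  back <- read_fastq_pairs(f1, f2, sample = "s")
  expect_equal(back, s$pairs)
})

test_that("anchored-pair yield matches the geometric expectation", {
  # one adjacent transcribed array; compare observed anchoring against the
  # fraction of fragments whose reads straddle the array/flank boundary
  d <- withr::local_tempdir()
  arr <- data.frame(chrom = "chr1", start = 10000L, motif = "AAGAG",
                    copies = 40L, transcribed = TRUE)
  g <- generate_genome(seed = 20, chrom_len = 50000L, arrays = arr)
  t <- generate_transcripts(g$genome, g$manifest, flank_len = 500L,
                            n_background = 0L)
  sim <- simulate_read_pairs(t$transcripts, n_pairs = 4000, error_rate = 0,
                             seed = 21, sample = "s")
  mates <- classify_and_extract(sim$pairs, motif("AAGAG"), min_copies = 3)
  exp_gr <- expected_loci(
    within(t$manifest, read_params <- sim$params), sim$truth)
  # the geometric count ignores chance phase extension of a run into the
  # flank, so the two counts agree within binomial noise, not exactly
  p <- exp_gr$n_anchored / 4000
  expect_lt(abs(nrow(mates) - exp_gr$n_anchored),
            3 * sqrt(4000 * p * (1 - p)) + 1e-9)
})

test_that("manifests serialize losslessly enough to re-derive the truth", {
  d <- withr::local_tempdir()
  sc <- default_scenario(file.path(d, "sc"), seed = 7, n_pairs = 1500)
  m <- read_manifest(sc$files$manifest)
  expect_equal(m$seed, 7)
  expect_equal(nrow(m$arrays), 6L)
  expect_equal(m$read_params$n_pairs, 1500)
  truth <- read.delim(sc$files$truth_pairs, stringsAsFactors = FALSE)
  redo <- expected_loci(m, truth)
  expect_equal(GenomicRanges::start(redo), GenomicRanges::start(sc$expected))
  expect_equal(GenomicRanges::end(redo), GenomicRanges::end(sc$expected))
})
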