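make_fastq <- function(ids, seqs, path, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

test_that("paired FASTQ files are read in sync, gzip-transparently", {
  d <- withr::local_tempdir()
  ids <- c("p1/1", "p2/1", "p3/1")
  s1 <- c("ACGTACGTAC", "TTTTTTTTTT", "AAGAGAAGAG")
  s2 <- c("GGGGGGGGGG", "CCCCCCCCCC", "ACGTACGTAA")
  f1 <- make_fastq(ids, s1, file.path(d, "r1.fastq"))
  f2 <- make_fastq(sub("/1", "/2", ids), s2, file.path(d, "r2.fastq"))
  p <- read_fastq_pairs(f1, f2, sample = "s")
  expect_equal(nrow(p), 3L)
  expect_equal(p$pair_id, c("p1", "p2", "p3"))
  expect_equal(p$seq1, s1)
  expect_equal(p$seq2, s2)

  # gzipped input gives identical output
  g1 <- file.path(d, "r1.fastq.gz")
  con <- gzfile(g1, "wb"); writeLines(readLines(f1), con); close(con)
  pg <- read_fastq_pairs(g1, f2, sample = "s")
  expect_identical(pg, p)

  # unequal record counts
  f3 <- make_fastq(ids[1:2], s2[1:2], file.path(d, "r3.fastq"))
  expect_error(read_fastq_pairs(f1, f3), "desynchronized")
  # desynchronized ids
  f4 <- make_fastq(c("p1/2", "pX/2", "p3/2"), s2, file.path(d, "r4.fastq"))
  expect_error(read_fastq_pairs(f1, f4), "mismatch at record 2")
})

test_that("trimming removes adapters and low-quality tails, drops short pairs", {
  adapter <- "AGATCGGAAGAGC"
  base <- strrep("ACGT", 10)                   # 40 nt
  pairs <- data.frame(
    pair_id = c("a", "b", "c"),
    seq1 = c(paste0(base, substr(adapter, 1, 10)),  # adapter prefix at 3'
             base,
             paste0(base, "TTTT")),
    qual1 = c(strrep("I", 50), strrep("I", 40),
              paste0(strrep("I", 40), strrep("#", 4))),  # low-quality tail
    seq2 = rep(base, 3),
    qual2 = rep(strrep("I", 40), 3),
    sample = "s", stringsAsFactors = FALSE)

  t <- trim_pairs(pairs, adapter = adapter, min_quality = 20, min_length = 20)
  expect_equal(t$seq1[t$pair_id == "a"], base)           # 10 adapter bases cut
  expect_equal(t$seq1[t$pair_id == "b"], base)           # identity case
  expect_equal(t$seq1[t$pair_id == "c"], base)           # Q2 tail stripped
  expect_equal(nchar(t$qual1), nchar(t$seq1))

  # pair dropped when a mate falls below min_length
  short <- pairs[2, ]
  short$qual1 <- paste0(strrep("I", 5), strrep("#", 35))
  expect_equal(nrow(trim_pairs(short, min_quality = 20, min_length = 20)), 0L)

  # trimming never lengthens; min_quality 0 + no adapter = identity
  t0 <- trim_pairs(pairs, adapter = NULL, min_quality = 0, min_length = 1)
  expect_identical(t0, pairs)
  t1 <- trim_pairs(pairs, adapter = adapter, min_quality = 30, min_length = 1)
  expect_true(all(nchar(t1$seq1) <= nchar(pairs$seq1)))
})

test_that("exactly-one-anchored pairs emit the mate; both/neither emit nothing", {
  uniqueish <- strrep("ACGTTGCA", 9)
  pairs <- data.frame(
    pair_id = c("one1", "rc2", "none", "both", "two_copies"),
    seq1 = c(paste0("CC", strrep("AAGAG", 4), "CC"),  # anchor in read 1
             uniqueish,
             uniqueish,
             strrep("AAGAG", 8),
             paste0("CC", strrep("AAGAG", 2), "CC")),
    seq2 = c(uniqueish,
             paste0("GG", strrep("CTCTT", 3), "GG"),  # minus-strand anchor
             strrep("TGCA", 10),
             strrep("CTCTT", 8),
             uniqueish),
    qual1 = "", qual2 = "", sample = "s", stringsAsFactors = FALSE)
  pairs$qual1 <- strrep("I", nchar(pairs$seq1))
  pairs$qual2 <- strrep("I", nchar(pairs$seq2))

  am <- classify_and_extract(pairs, motif("AAGAG"), min_copies = 3)
  expect_equal(sort(am$pair_id), c("one1", "rc2"))
  a1 <- am[am$pair_id == "one1", ]
  expect_equal(a1$anchor_read, 1L)
  expect_equal(a1$anchor_copies, 4L)
  expect_equal(a1$anchor_strand, "+")
  expect_equal(a1$mate_seq, uniqueish)
  a2 <- am[am$pair_id == "rc2", ]
  expect_equal(a2$anchor_read, 2L)
  expect_equal(a2$anchor_strand, "-")
  expect_equal(a2$mate_seq, uniqueish)

  # at most one record per pair; ids a subset of inputs
  expect_lte(nrow(am), nrow(pairs))
  expect_true(all(am$pair_id %in% pairs$pair_id))
  expect_false(anyDuplicated(am$pair_id) > 0)
})

test_that("expression screen counts and normalizes per million pairs", {
  uniqueish <- strrep("ACGTTGCA", 9)
  pairs <- data.frame(
    pair_id = sprintf("p%d", 1:10),
    seq1 = c(rep(paste0("CC", strrep("AATAT", 3), "CC"), 2),
             rep(uniqueish, 8)),
    seq2 = rep(uniqueish, 10),
    qual1 = "I", qual2 = "I", sample = "s", stringsAsFactors = FALSE)
  sc <- motif_expression_screen(pairs, c("AATAT", "AAGAG"), min_copies = 3)
  expect_equal(sc$anchored_pairs[sc$motif == "AATAT"], 2L)
  expect_equal(sc$anchored_per_million[sc$motif == "AATAT"], 200000)
  expect_equal(sc$anchored_pairs[sc$motif == "AAGAG"], 0L)
  expect_equal(unique(sc$pairs_total), 10L)
  expect_error(motif_expression_screen(pairs[0, ], "AAGAG"), "empty")

  # invariant to read order and to swapping mates within pairs
  perm <- pairs[sample(nrow(pairs)), ]
  swapped <- perm
  swapped[, c("seq1", "seq2")] <- swapped[, c("seq2", "seq1")]
  for (alt in list(perm, swapped)) {
    sa <- motif_expression_screen(alt, c("AATAT", "AAGAG"), min_copies = 3)
    expect_equal(sa[order(sa$motif), -1], sc[order(sc$motif), -1],
                 ignore_attr = TRUE)
  }
})

test_that("screen counts match planted multinomial proportions", {
  # simulate reads with planted per-motif abundances and check the screen
  # recovers the proportions within 3 binomial standard errors
  set.seed(33)
  motifs <- c("AAGAG", "AATAT", "AACAC")
  prob <- c(0.05, 0.1, 0.02)
  n <- 4000
  mk_read <- function(m) {
    if (is.na(m)) return(random_dna_str(75))
    paste0(random_dna_str(20), strrep(m, 4), random_dna_str(35))
  }
  lab <- sample(c(motifs, NA), n, replace = TRUE,
                prob = c(prob, 1 - sum(prob)))
  pairs <- data.frame(pair_id = sprintf("p%d", 1:n),
                      seq1 = vapply(lab, mk_read, character(1)),
                      seq2 = vapply(rep(NA_character_, n), mk_read,
                                    character(1)),
                      qual1 = "I", qual2 = "I", sample = "s",
                      stringsAsFactors = FALSE)
  sc <- motif_expression_screen(pairs, motifs, min_copies = 3)
  for (i in seq_along(motifs)) {
    phat <- sc$anchored_pairs[sc$motif == motifs[i]] / n
    se <- sqrt(prob[i] * (1 - prob[i]) / n)
    expect_lt(abs(phat - prob[i]), 3 * se + 1e-9,
              label = paste("screen proportion for", motifs[i]))
  }
})
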