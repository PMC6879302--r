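# Seeded generators for genomes with planted satellite arrays, transcripts
# spanning array + unique flank, and paired-end reads with substitution
# errors. All randomness is drawn from a locally seeded RNG so identical
# seeds give byte-identical outputs without touching the caller's RNG state.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a genome with planted satellite arrays
#'
#' Chromosomes are i.i.d. uniform ACGT background with perfect motif arrays
#' planted at the specified coordinates. Deterministic per seed. Array specs
#' must fit within their chromosome, not overlap, and be separated by at
#' least 2 kb of unique sequence.
#'
#' @param seed integer seed
#' @param n_chroms number of chromosomes (named \code{chr1}, \code{chr2}, ...)
#' @param chrom_len chromosome length(s), recycled to \code{n_chroms}
#' @param arrays data.frame with columns \code{chrom} (name or index),
#'   \code{start} (1-based), \code{motif}, \code{copies}, \code{transcribed}
#'   (logical); optional \code{flank_start} (NA = transcript flank adjacent
#'   to the array) and \code{strand}
#' @param out_fasta optional FASTA path to write
#' @return list with \code{genome} (DNAStringSet) and \code{manifest} (the
#'   ground-truth record: seed, chromosomes, arrays with computed ends)
#' @export
generate_genome <- function(seed, n_chroms = 1L, chrom_len = 500000L,
                            arrays = NULL, out_fasta = NULL) {
  chrom_len <- rep_len(as.integer(chrom_len), n_chroms)
  chroms <- paste0("chr", seq_len(n_chroms))
  if (is.null(arrays))
    arrays <- data.frame(chrom = character(), start = integer(),
                         motif = character(), copies = integer(),
                         transcribed = logical(), stringsAsFactors = FALSE)
  if (nrow(arrays)) {
    if (is.numeric(arrays$chrom)) arrays$chrom <- chroms[arrays$chrom]
    if (is.null(arrays$flank_start)) arrays$flank_start <- NA_integer_
    if (is.null(arrays$strand)) arrays$strand <- "+"
    arrays$motif <- vapply(arrays$motif,
                           function(u) as.character(motif(u)), character(1))
    arrays$end <- arrays$start +
      nchar(arrays$motif) * as.integer(arrays$copies) - 1L
    arrays$array_id <- sprintf("array%02d", seq_len(nrow(arrays)))
    for (i in seq_len(nrow(arrays))) {
      ci <- match(arrays$chrom[i], chroms)
      if (is.na(ci)) stop("unknown chromosome in array spec: ",
                          arrays$chrom[i])
      if (arrays$start[i] < 1L || arrays$end[i] > chrom_len[ci])
        stop("array ", arrays$array_id[i], " does not fit in ",
             arrays$chrom[i])
    }
    for (cc in unique(arrays$chrom)) {
      a <- arrays[arrays$chrom == cc, , drop = FALSE]
      a <- a[order(a$start), , drop = FALSE]
      if (nrow(a) > 1L) {
        gaps <- a$start[-1] - a$end[-nrow(a)] - 1L
        if (any(gaps < 2000L))
          stop("planted arrays on ", cc, " must be separated by >= 2 kb ",
               "of unique sequence")
      }
    }
  }
  seqs <- with_seed(seed, vapply(chrom_len, random_dna, character(1)))
  names(seqs) <- chroms
  for (i in seq_len(nrow(arrays))) {
    arr <- strrep(arrays$motif[i], arrays$copies[i])
    substr(seqs[arrays$chrom[i]], arrays$start[i], arrays$end[i]) <- arr
  }
  genome <- Biostrings::DNAStringSet(seqs)
  manifest <- list(seed = seed,
                   chroms = data.frame(chrom = chroms, length = chrom_len,
                                       stringsAsFactors = FALSE),
                   arrays = arrays)
  if (!is.null(out_fasta)) {
    Biostrings::writeXStringSet(genome, out_fasta)
    manifest$genome_fasta <- out_fasta
  }
  list(genome = genome, manifest = manifest)
}

#' Generate transcripts for transcribed arrays (plus background transcripts)
#'
#' Each transcribed array yields one transcript: a unique flank (default
#' 500 nt) followed by the satellite array. The flank is the genomic
#' sequence immediately 5' of the array, or, when the array spec carries a
#' \code{flank_start}, a copy of a distal genomic region (modelling a
#' satellite transcript whose mappable end lies far from any satellite
#' block). Minus-strand specs yield the reverse complement. Background
#' transcripts of pure unique sequence are drawn from array-free genomic
#' regions to supply unanchored read pairs.
#'
#' @param genome DNAStringSet from [generate_genome()]
#' @param manifest matching manifest
#' @param flank_len flank length in bases (default 500)
#' @param n_background number of background transcripts (default 10x the
#'   number of satellite transcripts)
#' @param background_len background transcript length (default 1500)
#' @param seed seed for background placement (default: manifest seed + 1)
#' @param out_fasta optional FASTA path
#' @return list with \code{transcripts} (DNAStringSet) and the updated
#'   \code{manifest} (gains a \code{transcripts} data.frame)
#' @export
generate_transcripts <- function(genome, manifest, flank_len = 500L,
                                 n_background = NULL, background_len = 1500L,
                                 seed = NULL, out_fasta = NULL) {
  arrays <- manifest$arrays
  tx <- arrays[arrays$transcribed, , drop = FALSE]
  if (is.null(n_background)) n_background <- 10L * nrow(tx)
  if (is.null(seed)) seed <- manifest$seed + 1L

  recs <- list()
  seqs <- character(0)
  gseq <- setNames(as.character(genome), names(genome))
  for (i in seq_len(nrow(tx))) {
    fs <- tx$flank_start[i]
    if (is.na(fs)) fs <- tx$start[i] - flank_len
    fe <- fs + flank_len - 1L
    if (fs < 1L) stop("flank of ", tx$array_id[i], " out of range")
    flank <- substr(gseq[tx$chrom[i]], fs, fe)
    arr <- substr(gseq[tx$chrom[i]], tx$start[i], tx$end[i])
    s <- paste0(flank, arr)
    if (tx$strand[i] == "-") s <- revcomp_chr(s)
    nm <- paste0("tx_", tx$array_id[i])
    seqs[nm] <- s
    recs[[length(recs) + 1L]] <- data.frame(
      name = nm, type = "satellite", chrom = tx$chrom[i], flank_start = fs,
      flank_end = fe, array_id = tx$array_id[i], array_start = tx$start[i],
      array_end = tx$end[i], strand = tx$strand[i], length = nchar(s),
      adjacent = (fe + 1L == tx$start[i]), stringsAsFactors = FALSE)
  }

  if (n_background > 0L) {
    # keep background clear of arrays and transcript flanks
    excl <- GenomicRanges::GRanges()
    if (nrow(arrays))
      excl <- GenomicRanges::GRanges(
        arrays$chrom, IRanges::IRanges(arrays$start, arrays$end))
    if (length(recs)) {
      fl <- do.call(rbind, recs)
      excl <- c(excl, GenomicRanges::GRanges(
        fl$chrom, IRanges::IRanges(fl$flank_start, fl$flank_end)))
    }
    bg <- with_seed(seed, {
      out <- list()
      tries <- 0L
      while (length(out) < n_background && tries < 50L * n_background) {
        tries <- tries + 1L
        ci <- sample.int(nrow(manifest$chroms), 1L)
        maxs <- manifest$chroms$length[ci] - background_len + 1L
        if (maxs < 1L) next
        st <- sample.int(maxs, 1L)
        cand <- GenomicRanges::GRanges(
          manifest$chroms$chrom[ci],
          IRanges::IRanges(st, st + background_len - 1L))
        if (length(excl) &&
            length(GenomicRanges::findOverlaps(cand, excl)) > 0L) next
        out[[length(out) + 1L]] <- cand
      }
      if (length(out) < n_background)
        stop("could not place ", n_background, " background transcripts")
      out
    })
    for (j in seq_along(bg)) {
      g <- bg[[j]]
      nm <- sprintf("bg%03d", j)
      seqs[nm] <- substr(gseq[as.character(GenomicRanges::seqnames(g))],
                         GenomicRanges::start(g), GenomicRanges::end(g))
      recs[[length(recs) + 1L]] <- data.frame(
        name = nm, type = "background",
        chrom = as.character(GenomicRanges::seqnames(g)),
        flank_start = GenomicRanges::start(g),
        flank_end = GenomicRanges::end(g), array_id = NA_character_,
        array_start = NA_integer_, array_end = NA_integer_, strand = "+",
        length = background_len, adjacent = NA, stringsAsFactors = FALSE)
    }
  }

  manifest$transcripts <- if (length(recs)) do.call(rbind, recs) else NULL
  manifest$flank_len <- flank_len
  transcripts <- Biostrings::DNAStringSet(seqs)
  if (!is.null(out_fasta)) {
    Biostrings::writeXStringSet(transcripts, out_fasta)
    manifest$transcripts_fasta <- out_fasta
  }
  list(transcripts = transcripts, manifest = manifest)
}

mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  v <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  hit <- which(runif(length(v)) < rate)
  hit <- hit[v[hit] %in% c("A", "C", "G", "T")]
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T",
                    "A", "G", "T",
                    "A", "C", "T",
                    "A", "C", "G"), nrow = 3)
    pick <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- alt[cbind(pick, match(v[hit], c("A", "C", "G", "T")))]
  }
  m <- matrix(v, nrow = L)
  do.call(paste0, lapply(seq_len(L), function(i) m[i, ]))
}

#' Simulate paired-end reads from transcripts
#'
#' Fragments are drawn per transcript proportional to length, with uniform
#' start and Normal(\code{frag_mean}, \code{frag_sd}) length truncated to
#' \code{[read_len, transcript length]}. Read 1 is the fragment 5' end; read
#' 2 the reverse complement of the 3' end. Substitution errors are applied
#' per base at \code{error_rate}; qualities are constant Q30. Deterministic
#' per seed.
#'
#' @param transcripts DNAStringSet or named character vector
#' @param n_pairs number of pairs
#' @param read_len read length (default 75)
#' @param frag_mean,frag_sd fragment length distribution (default 300, 30)
#' @param error_rate per-base substitution rate (default 0.01)
#' @param seed integer seed
#' @param sample sample label
#' @param fastq1,fastq2 optional FASTQ output paths (gzipped when ending in
#'   \code{.gz})
#' @return list with \code{pairs} (data.frame as from [read_fastq_pairs()]),
#'   \code{truth} (per-pair fragment provenance: \code{pair_id},
#'   \code{transcript}, \code{frag_start}, \code{frag_end}) and
#'   \code{params}
#' @export
simulate_read_pairs <- function(transcripts, n_pairs, read_len = 75L,
                                frag_mean = 300, frag_sd = 30,
                                error_rate = 0.01, seed = 1L,
                                sample = "sim", fastq1 = NULL, fastq2 = NULL) {
  if (is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  stopifnot(length(transcripts) >= 1L, n_pairs >= 1L,
            frag_mean >= read_len)
  tlen <- nchar(transcripts)
  if (any(tlen < read_len)) stop("all transcripts must be >= read_len")

  res <- with_seed(seed, {
    ti <- sample.int(length(transcripts), n_pairs, replace = TRUE,
                     prob = tlen)
    flen <- pmin(tlen[ti], pmax(read_len, round(rnorm(n_pairs, frag_mean,
                                                      frag_sd))))
    fstart <- floor(runif(n_pairs) * (tlen[ti] - flen + 1L)) + 1L
    fend <- fstart + flen - 1L
    r1 <- substr(transcripts[ti], fstart, fstart + read_len - 1L)
    r2 <- revcomp_chr(substr(transcripts[ti], fend - read_len + 1L, fend))
    r1 <- mutate_seqs(r1, error_rate)
    r2 <- mutate_seqs(r2, error_rate)
    list(ti = ti, fstart = fstart, fend = fend, r1 = r1, r2 = r2)
  })

  qual <- strrep(rawToChar(as.raw(33L + 30L)), read_len)
  pid <- sprintf("p%07d", seq_len(n_pairs))
  pairs <- data.frame(pair_id = pid, seq1 = unname(res$r1), qual1 = qual,
                      seq2 = unname(res$r2), qual2 = qual, sample = sample,
                      stringsAsFactors = FALSE)
  truth <- data.frame(pair_id = pid,
                      transcript = names(transcripts)[res$ti],
                      frag_start = unname(res$fstart),
                      frag_end = unname(res$fend), stringsAsFactors = FALSE)
  params <- list(n_pairs = n_pairs, read_len = read_len,
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 error_rate = error_rate, seed = seed, sample = sample)
  if (!is.null(fastq1)) {
    write_fastq <- function(seqs, ids, path) {
      x <- Biostrings::DNAStringSet(seqs)
      names(x) <- ids
      Biostrings::writeXStringSet(
        x, path, format = "fastq",
        qualities = Biostrings::BStringSet(rep(qual, length(seqs))),
        compress = grepl("\\.gz$", path))
    }
    write_fastq(pairs$seq1, paste0(pid, "/1"), fastq1)
    write_fastq(pairs$seq2, paste0(pid, "/2"), fastq2)
  }
  list(pairs = pairs, truth = truth, params = params)
}

#' Default end-to-end synthetic scenario
#'
#' One 500-kb chromosome with six planted AAGAG arrays: three transcribed
#' arrays with adjacent unique flanks (the expected origin loci), one
#' transcribed array whose transcript flank is a copy of a distal region far
#' (> 5 kb) from every satellite block (expected negative: its mates map
#' uniquely but not adjacent to a block), and two silent arrays (expected
#' negatives). Forty background transcripts supply unanchored pairs. Reads:
#' 50,000 pairs, 75 nt, fragments Normal(300, 30), 1% substitution error,
#' constant Q30.
#'
#' @param dir output directory for genome.fa, transcripts.fa,
#'   reads_1.fastq, reads_2.fastq, manifest.json, truth_pairs.tsv
#' @param seed master seed (genome uses \code{seed}, background placement
#'   \code{seed + 1}, reads \code{seed + 2})
#' @param n_pairs number of read pairs (default 50000)
#' @param error_rate per-base substitution rate (default 0.01)
#' @param sample sample label (default "e16-20hr")
#' @return list with \code{manifest}, \code{truth}, \code{expected}
#'   (GRanges of expected origin loci from [expected_loci()]) and
#'   \code{files}
#' @export
default_scenario <- function(dir, seed = 42L, n_pairs = 50000L,
                             error_rate = 0.01, sample = "e16-20hr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arrays <- data.frame(
    chrom = "chr1",
    start = c(50000L, 150000L, 250000L, 350000L, 200000L, 300000L),
    motif = "AAGAG",
    copies = c(40L, 40L, 40L, 40L, 30L, 30L),
    transcribed = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    flank_start = c(NA, NA, NA, 400000L, NA, NA),
    stringsAsFactors = FALSE)
  files <- list(genome = file.path(dir, "genome.fa"),
                transcripts = file.path(dir, "transcripts.fa"),
                fastq1 = file.path(dir, "reads_1.fastq"),
                fastq2 = file.path(dir, "reads_2.fastq"),
                manifest = file.path(dir, "manifest.json"),
                truth_pairs = file.path(dir, "truth_pairs.tsv"))
  g <- generate_genome(seed, n_chroms = 1L, chrom_len = 500000L,
                       arrays = arrays, out_fasta = files$genome)
  t <- generate_transcripts(g$genome, g$manifest, flank_len = 500L,
                            n_background = 40L, background_len = 1500L,
                            seed = seed + 1L, out_fasta = files$transcripts)
  sim <- simulate_read_pairs(t$transcripts, n_pairs = n_pairs,
                             read_len = 75L, frag_mean = 300, frag_sd = 30,
                             error_rate = error_rate, seed = seed + 2L,
                             sample = sample, fastq1 = files$fastq1,
                             fastq2 = files$fastq2)
  manifest <- t$manifest
  manifest$read_params <- sim$params
  # record file names only, so reruns into different directories are
  # byte-identical
  manifest$genome_fasta <- basename(manifest$genome_fasta)
  manifest$transcripts_fasta <- basename(manifest$transcripts_fasta)
  manifest$files <- lapply(files, basename)
  write_manifest(manifest, files$manifest)
  write.table(sim$truth, files$truth_pairs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expected <- expected_loci(manifest, sim$truth)
  list(manifest = manifest, truth = sim$truth, expected = expected,
       files = files)
}

#' Expected origin loci from simulation ground truth
#'
#' Generator-side oracle for end-to-end tests: for every satellite
#' transcript whose flank is adjacent to its array, computes the genomic
#' interval covered by the mates of anchored pairs -- pairs in which exactly
#' one read covers at least \code{min_copies} complete motif copies of the
#' array portion (by fragment geometry, ignoring substitution errors). This
#' is the locus the pipeline should report.
#'
#' @param manifest manifest with \code{transcripts}, \code{arrays} and
#'   \code{read_params}
#' @param truth per-pair truth data.frame from [simulate_read_pairs()]
#' @param min_copies anchoring threshold (default 3)
#' @return GRanges with one expected locus per adjacent transcribed array
#'   (metadata: \code{transcript}, \code{n_anchored})
#' @export
expected_loci <- function(manifest, truth, min_copies = 3L) {
  tx <- manifest$transcripts
  tx <- tx[tx$type == "satellite" & tx$adjacent %in% TRUE, , drop = FALSE]
  rl <- manifest$read_params$read_len
  out <- list()
  for (i in seq_len(nrow(tx))) {
    if (tx$strand[i] != "+")
      stop("expected_loci supports plus-strand transcripts")
    flank_len <- tx$flank_end[i] - tx$flank_start[i] + 1L
    tlen <- tx$length[i]
    u <- nchar(manifest$arrays$motif[match(tx$array_id[i],
                                           manifest$arrays$array_id)])
    tr <- truth[truth$transcript == tx$name[i], , drop = FALSE]
    if (nrow(tr) == 0L) next
    s <- tr$frag_start; e <- tr$frag_end
    ov <- function(a, b) pmax(0L, pmin(b, tlen) - pmax(a, flank_len + 1L) + 1L)
    c1 <- ov(s, s + rl - 1L) %/% u
    c2 <- ov(e - rl + 1L, e) %/% u
    anch <- xor(c1 >= min_copies, c2 >= min_copies)
    if (!any(anch)) next
    mate_a <- ifelse(c1[anch] >= min_copies, e[anch] - rl + 1L, s[anch])
    mate_b <- mate_a + rl - 1L
    # adjacent flank: transcript coords project linearly onto the genome
    gstart <- tx$flank_start[i] + min(mate_a) - 1L
    gend <- tx$flank_start[i] + max(mate_b) - 1L
    gr <- GenomicRanges::GRanges(tx$chrom[i],
                                 IRanges::IRanges(gstart, gend))
    gr$transcript <- tx$name[i]
    gr$n_anchored <- sum(anch)
    out[[length(out) + 1L]] <- gr
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::sort(suppressWarnings(do.call(c, out)),
                      ignore.strand = TRUE)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest manifest list
#' @param path JSON path
#' @return invisibly, \code{path} (write) or the manifest (read)
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m
}

#' Dinucleotide-preserving shuffle
#'
#' Random Eulerian-walk shuffle that preserves the exact dinucleotide
#' composition (and therefore mono-nucleotide composition, first and last
#' base) of the input. Used to calibrate the mapping e-value filter: a
#' shuffled sequence keeps local composition but loses its genomic identity.
#' Uses the caller's RNG state.
#'
#' @param seq a DNA string
#' @return a shuffled string with identical dinucleotide counts
#' @export
shuffle_dinucleotide <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n <= 3L || length(unique(ch)) == 1L) return(seq)
  verts <- unique(ch)
  f <- ch[n]
  out_edges <- split(ch[-1], factor(ch[-n], levels = verts))
  nonfinal <- setdiff(names(which(lengths(out_edges) > 0L)), f)
  last <- character(0)
  if (length(nonfinal)) {
    repeat {
      last <- vapply(nonfinal, function(v) {
        e <- out_edges[[v]]
        e[sample.int(length(e), 1L)]
      }, character(1))
      ok <- all(vapply(nonfinal, function(v) {
        seen <- character(0)
        cur <- v
        repeat {
          if (cur == f) return(TRUE)
          if (cur %in% seen || !(cur %in% names(last))) return(FALSE)
          seen <- c(seen, cur)
          cur <- last[[cur]]
        }
      }, logical(1)))
      if (ok) break
    }
  }
  arranged <- setNames(lapply(verts, function(v) {
    e <- out_edges[[v]]
    if (length(e) == 0L) return(character(0))
    if (v %in% names(last)) {
      e <- e[-match(last[[v]], e)]
      c(if (length(e)) e[sample.int(length(e))] else character(0),
        last[[v]])
    } else {
      e[sample.int(length(e))]
    }
  }), verts)
  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- arranged[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}
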