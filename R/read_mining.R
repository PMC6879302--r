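#' Read synchronized paired-end FASTQ files
#'
#' Reads two FASTQ files (plain or gzipped, Phred+33) holding the two mates
#' of each pair in the same order. Record ids are compared after stripping a
#' trailing \code{/1} or \code{/2} and anything after the first whitespace;
#' unequal record counts or desynchronized ids raise an error with the
#' offending record index.
#'
#' @param path1,path2 FASTQ files for read 1 and read 2
#' @param sample sample label attached to every pair (e.g. a developmental
#'   stage)
#' @return data.frame with columns \code{pair_id}, \code{seq1}, \code{qual1},
#'   \code{seq2}, \code{qual2}, \code{sample}; sequences are uppercased
#' @export
read_fastq_pairs <- function(path1, path2, sample = "sample1") {
  rd <- function(p) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ in '", p, "': ",
                               conditionMessage(e), call. = FALSE))
    x
  }
  r1 <- rd(path1)
  r2 <- rd(path2)
  if (length(r1) != length(r2))
    stop("desynchronized pair files: ", length(r1), " records in '", path1,
         "' vs ", length(r2), " in '", path2, "'")
  strip <- function(nm) sub("/[12]$", "", sub("[ \t].*$", "", nm))
  id1 <- strip(names(r1))
  id2 <- strip(names(r2))
  bad <- which(id1 != id2)
  if (length(bad))
    stop("pair id mismatch at record ", bad[1], ": '", id1[bad[1]], "' vs '",
         id2[bad[1]], "'")
  if (anyDuplicated(id1))
    warning("duplicated pair ids in '", path1, "'")
  data.frame(pair_id = id1,
             seq1 = toupper(as.character(r1)),
             qual1 = as.character(S4Vectors::mcols(r1)$qualities),
             seq2 = toupper(as.character(r2)),
             qual2 = as.character(S4Vectors::mcols(r2)$qualities),
             sample = sample, stringsAsFactors = FALSE, row.names = NULL)
}

trim_one_end <- function(seqs, quals, adapter, min_quality) {
  # 3' adapter: cut at the first occurrence of a >=8-base exact adapter
  # prefix (the whole adapter when shorter than 8)
  if (!is.null(adapter) && nzchar(adapter)) {
    probe <- substr(toupper(adapter), 1L, min(8L, nchar(adapter)))
    pos <- regexpr(probe, seqs, fixed = TRUE)
    cut <- as.integer(pos) - 1L
    hit <- pos > 0L
    seqs[hit] <- substr(seqs[hit], 1L, cut[hit])
    quals[hit] <- substr(quals[hit], 1L, cut[hit])
  }
  # 3' quality: strip the trailing stretch of bases below min_quality
  if (min_quality > 0L) {
    hi <- 33L + min_quality - 1L
    pat <- sprintf("[\\x21-\\x%02X]+$", hi)
    newq <- sub(pat, "", quals, perl = TRUE)
    keep <- nchar(newq)
    seqs <- substr(seqs, 1L, keep)
    quals <- newq
  }
  list(seq = seqs, qual = quals)
}

#' Adapter and quality trimming of read pairs
#'
#' A deliberately small 3'-trimmer: the read is cut at the first occurrence
#' of an exact >= 8-base prefix of the adapter, then 3' bases with quality
#' below \code{min_quality} are stripped. Pairs where either mate falls below
#' \code{min_length} are dropped. With \code{min_quality = 0} and no adapter
#' occurrence the input is returned unchanged; trimming never lengthens a
#' read.
#'
#' @param pairs data.frame from [read_fastq_pairs()]
#' @param adapter adapter sequence, or \code{NULL} to skip adapter trimming
#' @param min_quality Phred threshold in \code{[0, 41]} for 3' quality
#'   trimming
#' @param min_length minimum surviving mate length
#' @return the trimmed pairs data.frame (possibly with rows dropped)
#' @export
trim_pairs <- function(pairs, adapter = NULL, min_quality = 20L,
                       min_length = 20L) {
  stopifnot(min_quality >= 0L, min_quality <= 41L, min_length >= 1L)
  if (nrow(pairs) == 0L) return(pairs)
  t1 <- trim_one_end(pairs$seq1, pairs$qual1, adapter, min_quality)
  t2 <- trim_one_end(pairs$seq2, pairs$qual2, adapter, min_quality)
  pairs$seq1 <- t1$seq; pairs$qual1 <- t1$qual
  pairs$seq2 <- t2$seq; pairs$qual2 <- t2$qual
  keep <- nchar(pairs$seq1) >= min_length & nchar(pairs$seq2) >= min_length
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-read maximum complete-copy count on either strand (0 when no run)
max_copies <- function(seqs, motif, both_strands = TRUE) {
  runs <- find_tandem_runs(seqs = setNames(seqs, seq_along(seqs)),
                           motif = motif, min_copies = 1L,
                           both_strands = both_strands)
  cp <- integer(length(seqs))
  st <- character(length(seqs))
  if (nrow(runs)) {
    idx <- as.integer(runs$seq_id)
    # prefer higher copy count; on ties prefer '+'
    runs <- runs[order(idx, -runs$copies, runs$strand), , drop = FALSE]
    first <- !duplicated(as.integer(runs$seq_id))
    cp[as.integer(runs$seq_id)[first]] <- runs$copies[first]
    st[as.integer(runs$seq_id)[first]] <- runs$strand[first]
  }
  list(copies = cp, strand = st)
}

#' Classify satellite-anchored pairs and extract their mates
#'
#' For each pair in which exactly one read carries a tandem run of at least
#' \code{min_copies} complete motif copies (on either strand), emits the
#' other read -- the "anchored mate" that can be mapped uniquely. Pairs with
#' no qualifying read, or where both reads qualify (no usable mappable end),
#' emit nothing.
#'
#' @param pairs (trimmed) pairs data.frame
#' @param motif a [motif()]
#' @param min_copies anchoring threshold in complete copies (default 3)
#' @return data.frame with columns \code{pair_id}, \code{mate_seq},
#'   \code{mate_qual}, \code{anchor_read} (1 or 2), \code{anchor_copies},
#'   \code{anchor_strand}, \code{sample}
#' @export
classify_and_extract <- function(pairs, motif, min_copies = 3L) {
  motif <- as_motif(motif)
  empty <- data.frame(pair_id = character(), mate_seq = character(),
                      mate_qual = character(), anchor_read = integer(),
                      anchor_copies = integer(), anchor_strand = character(),
                      sample = character(), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  m1 <- max_copies(pairs$seq1, motif)
  m2 <- max_copies(pairs$seq2, motif)
  a1 <- m1$copies >= min_copies
  a2 <- m2$copies >= min_copies
  sel <- xor(a1, a2)
  if (!any(sel)) return(empty)
  anchor1 <- a1[sel]
  data.frame(
    pair_id = pairs$pair_id[sel],
    mate_seq = ifelse(anchor1, pairs$seq2[sel], pairs$seq1[sel]),
    mate_qual = ifelse(anchor1, pairs$qual2[sel], pairs$qual1[sel]),
    anchor_read = ifelse(anchor1, 1L, 2L),
    anchor_copies = ifelse(anchor1, m1$copies[sel], m2$copies[sel]),
    anchor_strand = ifelse(anchor1, m1$strand[sel], m2$strand[sel]),
    sample = pairs$sample[sel],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Satellite expression screen over read pairs
#'
#' Counts, per motif and sample, the pairs in which at least one read carries
#' a tandem run of \code{min_copies} or more complete copies on either
#' strand, and normalizes per million pairs. This generalizes per-motif
#' repeat-read counting across a panel of satellites.
#'
#' @param pairs pairs data.frame (one or more samples)
#' @param motifs list of [motif()] objects or character vector of units
#' @param min_copies threshold in complete copies (default 3)
#' @return data.frame with columns \code{sample}, \code{motif},
#'   \code{pairs_total}, \code{anchored_pairs}, \code{anchored_per_million}
#' @export
motif_expression_screen <- function(pairs, motifs, min_copies = 3L) {
  if (nrow(pairs) == 0L)
    stop("empty input: per-million normalization undefined")
  if (is.character(motifs)) motifs <- lapply(motifs, motif)
  motifs <- lapply(motifs, as_motif)
  samples <- unique(pairs$sample)
  out <- list()
  for (s in samples) {
    p <- pairs[pairs$sample == s, , drop = FALSE]
    n <- nrow(p)
    for (m in motifs) {
      c1 <- max_copies(p$seq1, m)$copies >= min_copies
      c2 <- max_copies(p$seq2, m)$copies >= min_copies
      k <- sum(c1 | c2)
      out[[length(out) + 1L]] <- data.frame(
        sample = s, motif = m$unit, pairs_total = n, anchored_pairs = k,
        anchored_per_million = k / n * 1e6, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write anchored mates as FASTA
#'
#' Headers carry the pair id and anchoring metadata
#' (\code{pair_id anchor_read=.. copies=.. strand=.. sample=..}).
#'
#' @param mates data.frame from [classify_and_extract()]
#' @param path output FASTA path
#' @return invisibly, \code{path}
#' @export
write_anchored_fasta <- function(mates, path) {
  x <- Biostrings::DNAStringSet(mates$mate_seq)
  names(x) <- sprintf("%s anchor_read=%d copies=%d strand=%s sample=%s",
                      mates$pair_id, mates$anchor_read, mates$anchor_copies,
                      mates$anchor_strand, mates$sample)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
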