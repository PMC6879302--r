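#' Annotate satellite blocks in a genome
#'
#' Finds all maximal perfect tandem runs of the motif (both strands) and
#' keeps those whose length exceeds \code{min_block_len} bases (strictly
#' greater by default, matching the ">50 bp" convention; set
#' \code{inclusive = TRUE} for >=). An optional merging pass joins
#' same-strand blocks separated by at most \code{gap_merge} bases before the
#' length filter, absorbing short interruptions in otherwise contiguous
#' arrays; when used it is recorded in the metadata of the result.
#'
#' @param genome a FASTA path, a [Biostrings::DNAStringSet], or a named
#'   character vector of chromosome sequences
#' @param motif a [motif()]
#' @param min_block_len block length threshold in bases (default 50,
#'   strict >)
#' @param inclusive use >= instead of > for the length threshold
#' @param gap_merge merge same-strand runs separated by at most this many
#'   bases (0 = off); merging considers runs of at least 2 complete copies
#' @return a [GenomicRanges::GRanges] sorted by (chrom, start) with metadata
#'   columns \code{motif} and \code{copies}; strand \code{"-"} means the run
#'   matches the reverse complement of the motif unit
#' @examples
#' g <- c(chr1 = paste0(strrep("A", 100), strrep("AAGAG", 12),
#'                      strrep("C", 100)))
#' annotate_blocks(g, motif("AAGAG"))
#' @export
annotate_blocks <- function(genome, motif, min_block_len = 50L,
                            inclusive = FALSE, gap_merge = 0L) {
  motif <- as_motif(motif)
  if (min_block_len < nchar(motif$unit))
    stop("min_block_len must be >= motif unit length")
  genome <- load_genome(genome)
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  u <- nchar(motif$unit)

  runs <- find_tandem_runs(genome, motif,
                           min_copies = if (gap_merge > 0L) 2L else 1L,
                           both_strands = TRUE)
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(runs)) runs$seq_id else character(),
    ranges = IRanges::IRanges(start = runs$start, end = runs$end),
    strand = runs$strand, seqlengths = chrlen)
  if (gap_merge > 0L && length(gr)) {
    gr <- GenomicRanges::reduce(gr, min.gapwidth = gap_merge + 1L)
  }
  w <- GenomicRanges::width(gr)
  keep <- if (inclusive) w >= min_block_len else w > min_block_len
  gr <- gr[keep]
  gr$motif <- rep(motif$unit, length(gr))
  gr$copies <- GenomicRanges::width(gr) %/% u
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr) <- list(min_block_len = min_block_len,
                                  inclusive = inclusive,
                                  gap_merge = gap_merge)
  gr
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
    # keep only the id part of FASTA headers
    names(genome) <- sub("[ \t].*$", "", names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome)))
      stop("character genome must be named by chromosome")
    genome <- Biostrings::DNAStringSet(toupper(genome))
  } else if (!is(genome, "DNAStringSet")) {
    stop("genome must be a FASTA path, DNAStringSet or named character")
  }
  genome
}

#' Write satellite blocks (or loci) as BED
#'
#' Standard 6-column BED (0-based half-open) via \pkg{rtracklayer}; the name
#' column is the motif (or locus id), the score the copy number (capped at
#' 1000 for BED compliance).
#'
#' @param blocks a GRanges from [annotate_blocks()]
#' @param path output BED path
#' @return invisibly, \code{path}
#' @export
write_blocks_bed <- function(blocks, path) {
  gr <- blocks
  nm <- if (!is.null(gr$motif)) gr$motif else
    if (!is.null(gr$locus_id)) gr$locus_id else rep(".", length(gr))
  sc <- if (!is.null(gr$copies)) pmin(gr$copies, 1000L) else
    rep(0L, length(gr))
  out <- GenomicRanges::granges(gr)
  out$name <- nm
  out$score <- sc
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
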