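#' Build an exact k-mer index over a genome
#'
#' Indexes every k-mer of the forward strand (k-mers containing non-ACGT
#' characters are skipped). Reverse-strand placements are found at mapping
#' time by aligning the reverse complement of the query.
#'
#' @param genome FASTA path, DNAStringSet or named character vector
#' @param k seed length, in \code{[8, 16]} (default 12)
#' @return an object of class \code{"genome_index"}
#' @export
build_index <- function(genome, k = 12L) {
  k <- as.integer(k)
  if (k < 8L || k > 16L) stop("k must be in [8, 16]")
  genome <- load_genome(genome)
  if (length(genome) == 0L) stop("empty genome")
  if (min(Biostrings::width(genome)) < k)
    stop("k (", k, ") larger than the shortest chromosome (",
         min(Biostrings::width(genome)), ")")
  ptr <- build_index_cpp(as.character(genome), names(genome), k)
  info <- index_info_cpp(ptr)
  structure(list(ptr = ptr, k = k,
                 chroms = data.frame(chrom = info$chrom,
                                     length = info$length,
                                     stringsAsFactors = FALSE),
                 total_len = info$total_len,
                 n_positions = info$n_positions),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> k =", x$k, "|", nrow(x$chroms), "chromosome(s),",
      format(x$total_len, big.mark = ","), "bases,",
      format(x$n_positions, big.mark = ","), "indexed positions\n")
  invisible(x)
}

#' Look up a k-mer in a genome index
#'
#' @param index a [build_index()] object
#' @param kmer a string of exactly \code{k} bases
#' @return data.frame of forward-strand positions (\code{chrom}, \code{pos}
#'   1-based); zero rows for an absent k-mer
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(is(index, "genome_index"))
  index_lookup_cpp(index$ptr, toupper(kmer))
}

#' Map a contig onto the genome by seed-and-extend
#'
#' Exact k-mer seeds on both strands are extended ungapped in both directions
#' under an X-drop rule (match +1, mismatch -2), deduplicated to the best hit
#' per (chrom, strand, diagonal), scored with a chance-expectation e-value
#' and filtered at \code{max_evalue}. The e-value is
#' \code{2 * N * L * 4^(-score)}: two strands times genome length \code{N}
#' times contig length \code{L} times the chance probability of an exact
#' match of the hit's effective length (its score: matches minus twice
#' mismatches).
#'
#' @param contig a DNA string (a contig consensus), or a one-row slice of a
#'   \code{contig_set} \code{contigs} data.frame
#' @param index a [build_index()] object
#' @param max_evalue e-value threshold; hits above it are removed
#'   (default 1e-5)
#' @param xdrop X-drop extension parameter (default 10)
#' @return data.frame of hits sorted by ascending e-value: \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive), \code{strand},
#'   \code{matches}, \code{mismatches}, \code{score}, \code{identity},
#'   \code{evalue}, \code{qstart}, \code{qend}
#' @export
map_contig <- function(contig, index, max_evalue = 1e-5, xdrop = 10L) {
  stopifnot(is(index, "genome_index"))
  if (is.data.frame(contig)) contig <- contig$consensus[1]
  contig <- toupper(contig)
  L <- nchar(contig)
  if (L < index$k) {
    warning("contig shorter than k (", index$k, "); no hits")
    return(empty_hits())
  }
  h <- map_seed_extend_cpp(index$ptr, contig, as.integer(xdrop))
  if (nrow(h) == 0L) return(empty_hits())
  h$identity <- h$matches / (h$matches + h$mismatches)
  h$evalue <- 2 * index$total_len * L * 4^(-pmax(h$score, 0L))
  h <- h[h$evalue <= max_evalue, , drop = FALSE]
  h <- h[order(h$evalue, -h$score, h$chrom, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

empty_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), matches = integer(),
             mismatches = integer(), score = integer(), qstart = integer(),
             qend = integer(), identity = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Uniqueness test over a contig's filtered hits
#'
#' A contig is "uniquely mapped" when a single hit passes the e-value filter,
#' or when the best score exceeds the runner-up by the uniqueness margin
#' (runner-up score strictly below \code{margin * best}, default 0.9).
#'
#' @param hits data.frame from [map_contig()] (already e-value filtered)
#' @param margin uniqueness margin (default 0.9)
#' @return list with \code{best} (one-row data.frame) and \code{unique}
#'   (logical flag)
#' @export
uniqueness_filter <- function(hits, margin = 0.9) {
  if (nrow(hits) == 0L) stop("uniqueness_filter: empty hit list")
  hits <- hits[order(-hits$score, hits$chrom, hits$start, hits$strand), ,
               drop = FALSE]
  uni <- nrow(hits) == 1L || hits$score[2] < margin * hits$score[1]
  list(best = hits[1, , drop = FALSE], unique = uni)
}

#' Call origin loci from mapped contigs and satellite blocks
#'
#' Each uniquely mapped contig whose hit interval overlaps or lies within
#' \code{window} bases of a satellite block becomes an origin-locus
#' candidate; candidates overlapping each other are merged (interval union,
#' contig ids concatenated). Locus ids are rendered 1-based inclusive as
#' \code{chrom.start.end}.
#'
#' @param hits data.frame of e-value-filtered hits for all contigs, with a
#'   \code{contig_id} column (rbind of [map_contig()] outputs)
#' @param blocks GRanges from [annotate_blocks()] for the same genome
#' @param window adjacency window in bases (default 1000)
#' @param sample sample label stored on the loci
#' @param margin uniqueness margin, passed to [uniqueness_filter()]
#' @return GRanges of loci with metadata columns \code{locus_id},
#'   \code{sample}, \code{contigs}, \code{n_contigs}, \code{distance}
#'   (minimum distance to a block; 0 if overlapping)
#' @export
call_origins <- function(hits, blocks, window = 1000L, sample = NA_character_,
                         margin = 0.9) {
  empty <- GenomicRanges::GRanges()
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  stopifnot(!is.null(hits$contig_id))
  cand <- list()
  for (cid in unique(hits$contig_id)) {
    hh <- hits[hits$contig_id == cid, , drop = FALSE]
    uf <- uniqueness_filter(hh, margin = margin)
    if (!uf$unique) next
    b <- uf$best
    gr <- GenomicRanges::GRanges(b$chrom,
                                 IRanges::IRanges(b$start, b$end),
                                 strand = b$strand)
    if (length(blocks) == 0L) next
    dtn <- GenomicRanges::distanceToNearest(gr, blocks, ignore.strand = TRUE)
    if (length(dtn) == 0L) next
    d <- S4Vectors::mcols(dtn)$distance
    if (d > window) next
    gr$contig_id <- cid
    gr$distance <- d
    cand[[length(cand) + 1L]] <- gr
  }
  if (length(cand) == 0L) return(empty)
  cand <- suppressWarnings(do.call(c, cand))
  merged <- GenomicRanges::reduce(cand, with.revmap = TRUE,
                                  ignore.strand = TRUE)
  rv <- S4Vectors::mcols(merged)$revmap
  merged$locus_id <- sprintf("%s.%d.%d",
                             as.character(GenomicRanges::seqnames(merged)),
                             GenomicRanges::start(merged),
                             GenomicRanges::end(merged))
  merged$sample <- rep(sample, length(merged))
  merged$contigs <- vapply(rv, function(i)
    paste(sort(cand$contig_id[i]), collapse = ","), character(1))
  merged$n_contigs <- lengths(rv)
  merged$distance <- vapply(rv, function(i) min(cand$distance[i]), numeric(1))
  merged$revmap <- NULL
  GenomicRanges::sort(merged, ignore.strand = TRUE)
}
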