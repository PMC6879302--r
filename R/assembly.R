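#' Overlap / assembly parameters
#'
#' Scoring is fixed at match +1, mismatch -2, ungapped. \code{min_seed} is
#' the exact-match seed an overlap must contain (the assembler analog of a
#' minimum match length), \code{min_score} the minimum overlap alignment
#' score, and \code{max_mismatch_frac} the tolerated mismatch fraction over
#' the overlap (assembler stringency).
#'
#' @param min_seed minimum exact seed length (>= 4; default 10)
#' @param min_score minimum overlap score (>= min_seed; default 30)
#' @param max_mismatch_frac maximum mismatch fraction in an overlap
#'   (default 0.05)
#' @return an object of class \code{"overlap_params"}
#' @export
overlap_params <- function(min_seed = 10L, min_score = 30L,
                           max_mismatch_frac = 0.05) {
  min_seed <- as.integer(min_seed)
  min_score <- as.integer(min_score)
  if (min_seed < 4L) stop("min_seed must be >= 4")
  if (min_score < min_seed) stop("min_score must be >= min_seed")
  if (max_mismatch_frac < 0 || max_mismatch_frac > 1)
    stop("max_mismatch_frac must be in [0, 1]")
  structure(list(min_seed = min_seed, min_score = min_score,
                 max_mismatch_frac = max_mismatch_frac),
            class = "overlap_params")
}

#' Best ungapped overlap between two sequences
#'
#' Scans every suffix--prefix (and containment) offset of \code{b} against
#' \code{a}, in both orientations of \code{b}, and returns the
#' highest-scoring qualifying overlap: it must contain an exact stretch of at
#' least \code{min_seed} bases, score at least \code{min_score} (match +1,
#' mismatch -2) and have a mismatch fraction of at most
#' \code{max_mismatch_frac}. Deterministic tie-break: larger overlap, then
#' \code{"+"} orientation, then smaller offset.
#'
#' @param a,b DNA strings
#' @param params an [overlap_params()]
#' @return \code{NULL} when no overlap qualifies, otherwise a list with
#'   \code{offset} (0-based start of oriented \code{b} relative to \code{a};
#'   may be negative), \code{orientation}, \code{score}, \code{overlap_len},
#'   \code{matches}, \code{mismatches}
#' @export
best_overlap <- function(a, b, params = overlap_params()) {
  stopifnot(is(params, "overlap_params"))
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) < params$min_seed || nchar(b) < params$min_seed)
    stop("sequences must be at least min_seed (", params$min_seed,
         ") bases long")
  best_overlap_cpp(a, b, params$min_seed, params$min_score,
                   params$max_mismatch_frac)
}

#' Greedy overlap-layout-consensus assembly of anchored mates
#'
#' Repeatedly merges the pair of current sequences with the best qualifying
#' overlap (see [best_overlap()]) until none remains. The consensus is a
#' per-column majority vote over member reads; ties go to the base of the
#' earliest-merged member. Singleton reads are emitted as single-member
#' contigs. Deterministic for a fixed input order and parameters.
#'
#' @param mates a data.frame from [classify_and_extract()] (columns
#'   \code{mate_seq}, \code{pair_id}), or a character vector of sequences
#'   (names used as ids)
#' @param params an [overlap_params()]
#' @param sample sample label stored on the contigs (taken from \code{mates}
#'   when present)
#' @return an object of class \code{"contig_set"}: list with \code{contigs}
#'   (data.frame: \code{contig_id}, \code{consensus}, \code{length},
#'   \code{n_members}, \code{mean_depth}, \code{sample}), \code{members}
#'   (data.frame: \code{contig_id}, \code{pair_id}, \code{offset} 1-based,
#'   \code{orientation}) and \code{depth} (named list of per-base coverage)
#' @export
assemble <- function(mates, params = overlap_params(), sample = NULL) {
  stopifnot(is(params, "overlap_params"))
  if (is.data.frame(mates)) {
    seqs <- mates$mate_seq
    ids <- mates$pair_id
    if (is.null(sample) && !is.null(mates$sample) && nrow(mates))
      sample <- mates$sample[1]
  } else {
    seqs <- as.character(mates)
    ids <- names(mates)
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(seqs))
  }
  if (is.null(sample)) sample <- NA_character_
  if (length(seqs) == 0L)
    return(structure(list(
      contigs = data.frame(contig_id = character(), consensus = character(),
                           length = integer(), n_members = integer(),
                           mean_depth = numeric(), sample = character(),
                           stringsAsFactors = FALSE),
      members = data.frame(contig_id = character(), pair_id = character(),
                           offset = integer(), orientation = character(),
                           stringsAsFactors = FALSE),
      depth = list()), class = "contig_set"))
  seqs <- toupper(seqs)
  res <- assemble_cpp(seqs, params$min_seed, params$min_score,
                      params$max_mismatch_frac)
  ndig <- max(3L, nchar(as.character(length(res))))
  cid <- sprintf(paste0("ctg%0", ndig, "d"), seq_along(res))
  contigs <- data.frame(
    contig_id = cid,
    consensus = vapply(res, `[[`, character(1), "consensus"),
    length = vapply(res, function(x) nchar(x$consensus), integer(1)),
    n_members = vapply(res, function(x) length(x$read), integer(1)),
    mean_depth = vapply(res, function(x) mean(x$depth), numeric(1)),
    sample = sample, stringsAsFactors = FALSE)
  members <- do.call(rbind, lapply(seq_along(res), function(i) {
    data.frame(contig_id = cid[i], pair_id = ids[res[[i]]$read],
               offset = res[[i]]$offset,
               orientation = ifelse(res[[i]]$rc, "-", "+"),
               stringsAsFactors = FALSE)
  }))
  depth <- setNames(lapply(res, `[[`, "depth"), cid)
  structure(list(contigs = contigs, members = members, depth = depth),
            class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat("<contig_set>", nrow(x$contigs), "contigs,", nrow(x$members),
      "member reads\n")
  if (nrow(x$contigs))
    print(head(x$contigs[, c("contig_id", "length", "n_members",
                             "mean_depth")], 10))
  invisible(x)
}

#' Write contigs as FASTA plus a membership table
#'
#' FASTA headers carry \code{contig_id sample=.. n_members=.. mean_depth=..};
#' the optional TSV lists one member read per row.
#'
#' @param x a \code{contig_set}
#' @param fasta_path output FASTA path
#' @param members_path optional output TSV path for the membership table
#' @return invisibly, \code{fasta_path}
#' @export
write_contigs <- function(x, fasta_path, members_path = NULL) {
  stopifnot(is(x, "contig_set"))
  s <- Biostrings::DNAStringSet(x$contigs$consensus)
  names(s) <- sprintf("%s sample=%s n_members=%d mean_depth=%.2f",
                      x$contigs$contig_id, x$contigs$sample,
                      x$contigs$n_members, x$contigs$mean_depth)
  Biostrings::writeXStringSet(s, fasta_path)
  if (!is.null(members_path))
    write.table(x$members, members_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fasta_path)
}
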