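#' Construct a satellite motif
#'
#' A motif is a short tandem-repeat unit (1--10 bases, ACGT). The unit is
#' stored in canonical form -- the lexicographically smallest cyclic rotation
#' -- so that e.g. \code{AAGAG} and \code{AGAGA} denote the same satellite.
#'
#' @param unit repeat unit, a single DNA string (case-insensitive, ACGT only)
#' @param name optional label; defaults to the canonical unit
#' @return an object of class \code{"motif"} with fields \code{unit}
#'   (canonical) and \code{name}
#' @examples
#' motif("AGAGA")  # canonicalizes to AAGAG
#' @export
motif <- function(unit, name = NULL) {
  stopifnot(is.character(unit), length(unit) == 1L)
  unit <- toupper(unit)
  if (!nzchar(unit) || nchar(unit) > 10L)
    stop("motif unit must be 1-10 bases, got ", nchar(unit))
  if (grepl("[^ACGT]", unit))
    stop("invalid alphabet in motif unit '", unit, "': ACGT only")
  canon <- canonical_rotation(unit)
  structure(list(unit = canon, name = if (is.null(name)) canon else name),
            class = "motif")
}

#' @rdname motif
#' @export
canonicalize <- function(unit, name = NULL) motif(unit, name)

canonical_rotation <- function(unit) {
  u <- nchar(unit)
  rots <- vapply(seq_len(u) - 1L, function(r) {
    paste0(substr(unit, r + 1L, u), substr(unit, 1L, r))
  }, character(1))
  min(rots)
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif>", x$name, "unit:", x$unit, "\n")
  invisible(x)
}

#' @export
as.character.motif <- function(x, ...) x$unit

as_motif <- function(x) {
  if (is(x, "motif")) x else motif(as.character(x))
}

#' Reverse complement
#'
#' For a motif, returns the canonicalized reverse-complement motif (the unit
#' on the opposite strand); for plain character vectors, the reverse
#' complement string(s). \code{revcomp(revcomp(m))} is \code{m}.
#'
#' @param x a \code{motif} or a character vector of DNA strings
#' @return same type as the input
#' @examples
#' revcomp(motif("AAGAG"))  # CTCTT
#' @export
revcomp <- function(x) {
  if (is(x, "motif")) return(motif(revcomp_chr(x$unit), name = NULL))
  revcomp_chr(x)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Find maximal perfect tandem runs of a motif
#'
#' Scans sequences for maximal runs of consecutive copies of the motif unit.
#' Runs may start at any cyclic phase of the unit and include partial leading
#' or trailing copies in their interval, but \code{copies} counts complete
#' unit copies only (\code{floor(run length / unit length)}). \code{N} and
#' any non-ACGT character terminate runs. With \code{both_strands = TRUE},
#' runs of the reverse-complement unit are also reported with strand
#' \code{"-"}; a self-complementary unit is reported once per strand.
#'
#' @param seqs character vector of DNA sequences (uppercased on ingest), a
#'   named vector, or a [Biostrings::DNAStringSet]
#' @param motif a [motif()] (or string coerced to one)
#' @param min_copies minimum complete copies for a run to be reported
#' @param both_strands also scan for the reverse-complement unit
#' @return data.frame with columns \code{seq_id}, \code{start}, \code{end}
#'   (1-based, inclusive), \code{copies}, \code{strand}, \code{motif},
#'   sorted by sequence then start
#' @examples
#' find_tandem_runs(strrep("AAGAG", 3), motif("AAGAG"), min_copies = 3)
#' @export
find_tandem_runs <- function(seqs, motif, min_copies = 1L,
                             both_strands = TRUE) {
  stopifnot(min_copies >= 1L)
  motif <- as_motif(motif)
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  seqs <- toupper(unname(seqs))

  scan1 <- function(unit, strand) {
    d <- scan_runs_cpp(seqs, unit, as.integer(min_copies))
    if (nrow(d) == 0L) return(NULL)
    data.frame(seq_id = ids[d$seq], start = d$start, end = d$end,
               copies = d$copies, strand = strand, motif = motif$unit,
               stringsAsFactors = FALSE)
  }
  out <- list(scan1(motif$unit, "+"))
  if (isTRUE(both_strands)) out <- c(out, list(scan1(revcomp_chr(motif$unit), "-")))
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), copies = integer(),
                      strand = character(), motif = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(match(out$seq_id, ids), out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
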