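# Brute-force regex oracle for maximal tandem runs, built independently of
# the package scanner: for every cyclic rotation r of the unit, locate
# maximal (r)+ stretches with a regex, extend each end over partial copies
# by direct character comparison, drop intervals contained in another, and
# count complete copies as floor(length / unit length).

rotations_of <- function(unit) {
  u <- nchar(unit)
  unique(vapply(seq_len(u) - 1L, function(r)
    paste0(substr(unit, r + 1L, u), substr(unit, 1L, r)), character(1)))
}

oracle_runs_one_strand <- function(seq, unit, min_copies) {
  u <- nchar(unit)
  n <- nchar(seq)
  iv <- list()
  for (r in rotations_of(unit)) {
    # lookahead so that overlapping repeat stretches are all seen (two
    # maximal runs may share up to u - 1 bases); containment filtering
    # below keeps only the maximal ones
    m <- gregexpr(sprintf("(?=((?:%s)+))", r), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    cst <- attr(m, "capture.start")[, 1]
    cln <- attr(m, "capture.length")[, 1]
    for (j in seq_along(m)) {
      st <- cst[j]
      en <- st + cln[j] - 1L
      k <- 0L
      while (en + k + 1L <= n && k < u - 1L &&
             substr(seq, en + k + 1L, en + k + 1L) ==
             substr(r, k + 1L, k + 1L)) k <- k + 1L
      en <- en + k
      k <- 0L
      while (st - k - 1L >= 1L && k < u - 1L &&
             substr(seq, st - k - 1L, st - k - 1L) ==
             substr(r, u - k, u - k)) k <- k + 1L
      st <- st - k
      iv[[length(iv) + 1L]] <- c(st, en)
    }
  }
  if (length(iv) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      copies = integer()))
  iv <- unique(do.call(rbind, iv))
  # keep maximal intervals only
  keep <- vapply(seq_len(nrow(iv)), function(i) {
    !any(iv[, 1] <= iv[i, 1] & iv[, 2] >= iv[i, 2] &
         (iv[, 1] != iv[i, 1] | iv[, 2] != iv[i, 2]))
  }, logical(1))
  iv <- iv[keep, , drop = FALSE]
  cp <- (iv[, 2] - iv[, 1] + 1L) %/% u
  ok <- cp >= min_copies
  out <- data.frame(start = iv[ok, 1], end = iv[ok, 2], copies = cp[ok])
  out[order(out$start), , drop = FALSE]
}

oracle_runs <- function(seq, unit, min_copies, both_strands = TRUE) {
  fwd <- oracle_runs_one_strand(seq, unit, min_copies)
  if (nrow(fwd)) fwd$strand <- "+"
  else fwd$strand <- character(0)
  if (!both_strands) return(fwd)
  rcu <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  rev <- oracle_runs_one_strand(seq, rcu, min_copies)
  if (nrow(rev)) rev$strand <- "-"
  else rev$strand <- character(0)
  out <- rbind(fwd, rev)
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# compare the package scanner with the oracle on one sequence
expect_scanner_matches_oracle <- function(seq, unit, min_copies = 1L) {
  got <- find_tandem_runs(seq, motif(unit), min_copies = min_copies,
                          both_strands = TRUE)
  want <- oracle_runs(seq, unit, min_copies)
  got <- got[order(got$start, got$strand),
             c("start", "end", "copies", "strand")]
  rownames(got) <- NULL
  rownames(want) <- NULL
  expect_equal(got, want, ignore_attr = TRUE)
}
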