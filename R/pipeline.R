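#' Pipeline configuration
#'
#' Collects all inputs and thresholds of the origin-mapping pipeline, with
#' defaults matching the mining procedure (anchoring at >= 3 complete copies,
#' assembler min_score 30 / min_seed 10, e-value < 1e-5, satellite blocks
#' > 50 bp, adjacency window 1000 bases). Can be loaded from a YAML file with
#' the same field names.
#'
#' @param fastq1,fastq2 character vectors of paired FASTQ paths (one entry
#'   per sample)
#' @param genome genome FASTA path
#' @param motif motif unit (string) or [motif()]
#' @param sample sample labels (same length as \code{fastq1})
#' @param out_dir output directory (created if missing)
#' @param min_copies anchoring threshold in complete copies
#' @param adapter optional adapter for trimming
#' @param min_quality,min_length trimming parameters
#' @param min_seed,min_score,max_mismatch_frac assembler parameters
#' @param min_block_len satellite block length threshold (strict >)
#' @param gap_merge block merging gap (0 = off)
#' @param k index seed length
#' @param xdrop extension X-drop
#' @param max_evalue mapping e-value threshold
#' @param uniqueness_margin runner-up score margin defining "uniquely mapped"
#' @param window block adjacency window in bases
#' @param seed recorded in the run report (the pipeline itself is
#'   deterministic)
#' @return a list of class \code{"satanchor_config"}
#' @export
pipeline_config <- function(fastq1, fastq2, genome, motif,
                            sample = paste0("sample", seq_along(fastq1)),
                            out_dir = ".", min_copies = 3L, adapter = NULL,
                            min_quality = 20L, min_length = 20L,
                            min_seed = 10L, min_score = 30L,
                            max_mismatch_frac = 0.05, min_block_len = 50L,
                            gap_merge = 0L, k = 12L, xdrop = 10L,
                            max_evalue = 1e-5, uniqueness_margin = 0.9,
                            window = 1000L, seed = NULL) {
  cfg <- list(fastq1 = fastq1, fastq2 = fastq2, genome = genome,
              motif = as.character(as_motif(motif)), sample = sample,
              out_dir = out_dir, min_copies = min_copies, adapter = adapter,
              min_quality = min_quality, min_length = min_length,
              min_seed = min_seed, min_score = min_score,
              max_mismatch_frac = max_mismatch_frac,
              min_block_len = min_block_len, gap_merge = gap_merge, k = k,
              xdrop = xdrop, max_evalue = max_evalue,
              uniqueness_margin = uniqueness_margin, window = window,
              seed = seed)
  class(cfg) <- "satanchor_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$fastq1) != length(cfg$fastq2) ||
      length(cfg$fastq1) != length(cfg$sample))
    stop("configuration error: fastq1, fastq2 and sample must have equal ",
         "lengths")
  miss <- c(cfg$fastq1, cfg$fastq2, cfg$genome)
  miss <- miss[!file.exists(miss)]
  if (length(miss))
    stop("configuration error: missing input file(s): ",
         paste(miss, collapse = ", "))
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#' @return a \code{"satanchor_config"}
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the satellite origin-mapping pipeline end to end
#'
#' Per sample: trim, classify satellite-anchored pairs and extract mates,
#' assemble mates into contigs, map contigs, and call origin loci adjacent to
#' satellite blocks annotated from the genome. Writes, under
#' \code{out_dir}: per-sample anchored-mate FASTA, contig FASTA and
#' membership TSV, a blocks BED, a loci BED, a locus table with one row per
#' merged locus and one column per sample (locus ids rendered 1-based
#' inclusive), and a JSON run report with counts at every stage and all
#' parameters. Rerunning with the same configuration produces byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()], a list of its arguments, or a YAML
#'   path
#' @return invisibly, a list with \code{loci} (named list of per-sample
#'   GRanges), \code{report} and \code{files}
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  if (!is(config, "satanchor_config"))
    config <- do.call(pipeline_config, config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  m <- motif(cfg$motif)
  genome <- load_genome(cfg$genome)
  blocks <- annotate_blocks(genome, m, min_block_len = cfg$min_block_len,
                            gap_merge = cfg$gap_merge)
  index <- build_index(genome, k = cfg$k)
  params <- overlap_params(cfg$min_seed, cfg$min_score, cfg$max_mismatch_frac)

  files <- list(blocks_bed = file.path(cfg$out_dir, "blocks.bed"))
  write_blocks_bed(blocks, files$blocks_bed)

  report <- list(parameters = cfg[setdiff(names(cfg), "out_dir")],
                 n_blocks = length(blocks), samples = list())
  loci_by_sample <- list()

  for (i in seq_along(cfg$sample)) {
    s <- cfg$sample[i]
    pairs <- read_fastq_pairs(cfg$fastq1[i], cfg$fastq2[i], sample = s)
    n_in <- nrow(pairs)
    pairs <- trim_pairs(pairs, adapter = cfg$adapter,
                        min_quality = cfg$min_quality,
                        min_length = cfg$min_length)
    n_trim <- nrow(pairs)
    mates <- classify_and_extract(pairs, m, min_copies = cfg$min_copies)
    cs <- assemble(mates, params = params, sample = s)

    fa <- file.path(cfg$out_dir, sprintf("anchored_%s.fa", s))
    write_anchored_fasta(mates, fa)
    cf <- file.path(cfg$out_dir, sprintf("contigs_%s.fa", s))
    mf <- file.path(cfg$out_dir, sprintf("members_%s.tsv", s))
    write_contigs(cs, cf, mf)
    files[[paste0("anchored_", s)]] <- fa
    files[[paste0("contigs_", s)]] <- cf

    hits <- do.call(rbind, lapply(seq_len(nrow(cs$contigs)), function(j) {
      h <- map_contig(cs$contigs$consensus[j], index,
                      max_evalue = cfg$max_evalue, xdrop = cfg$xdrop)
      if (nrow(h)) h$contig_id <- cs$contigs$contig_id[j]
      h
    }))
    n_mapped <- if (is.null(hits) || nrow(hits) == 0L) 0L else
      length(unique(hits$contig_id))
    n_unique <- 0L
    if (!is.null(hits) && nrow(hits)) {
      n_unique <- sum(vapply(unique(hits$contig_id), function(cid) {
        uniqueness_filter(hits[hits$contig_id == cid, , drop = FALSE],
                          margin = cfg$uniqueness_margin)$unique
      }, logical(1)))
    }
    loci <- call_origins(hits, blocks, window = cfg$window, sample = s,
                         margin = cfg$uniqueness_margin)
    loci_by_sample[[s]] <- loci

    report$samples[[s]] <- list(
      pairs_in = n_in, pairs_after_trim = n_trim,
      anchored_mates = nrow(mates), contigs = nrow(cs$contigs),
      contig_members = nrow(cs$members), contigs_mapped = n_mapped,
      contigs_unique = n_unique, loci = length(loci))
  }

  # Table-style locus matrix: rows = merged loci across samples,
  # one column per sample carrying that sample's locus id
  all_loci <- suppressWarnings(do.call(
    c, unname(loci_by_sample[lengths(loci_by_sample) > 0])))
  files$loci_tsv <- file.path(cfg$out_dir, "loci.tsv")
  files$loci_bed <- file.path(cfg$out_dir, "loci.bed")
  if (!is.null(all_loci) && length(all_loci)) {
    rows <- GenomicRanges::reduce(all_loci, ignore.strand = TRUE)
    tab <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rows)),
      start = GenomicRanges::start(rows), end = GenomicRanges::end(rows),
      stringsAsFactors = FALSE)
    for (s in cfg$sample) {
      ls <- loci_by_sample[[s]]
      col <- rep(NA_character_, length(rows))
      if (length(ls)) {
        ov <- GenomicRanges::findOverlaps(rows, ls, ignore.strand = TRUE)
        col[S4Vectors::queryHits(ov)] <- ls$locus_id[S4Vectors::subjectHits(ov)]
      }
      tab[[s]] <- col
    }
    write.table(tab, files$loci_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    bed <- all_loci
    bed$motif <- paste0(bed$locus_id, "_", bed$sample)
    bed$copies <- bed$n_contigs
    write_blocks_bed(bed, files$loci_bed)
  } else {
    write.table(data.frame(chrom = character(), start = integer(),
                           end = integer()),
                files$loci_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    file.create(files$loci_bed)
  }

  files$report <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, files$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(list(loci = loci_by_sample, report = report, files = files))
}
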