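#' Read and write FASTQ read sets
#'
#' Thin wrappers over Biostrings. Reads are represented throughout the
#' package as a data.frame with columns `id`, `seq`, `qual` (Phred+33).
#'
#' @param path FASTQ path (`.gz` accepted on read; written plain or gzip
#'   by extension).
#' @return `read_fastq`: the reads data.frame.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @param reads data.frame with `id`, `seq`, `qual` (or a `sim_reads`).
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "sim_reads")) reads <- reads$reads
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  q <- Biostrings::PhredQuality(reads$qual)
  qs <- Biostrings::QualityScaledDNAStringSet(s, q)
  Biostrings::writeQualityScaledXStringSet(
    qs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' @param path FASTA path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  s <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write a ground-truth manifest
#'
#' Serializes a simulator truth table as TSV; [read_truth_manifest()]
#' round-trips it losslessly.
#'
#' @param truth a truth data.frame (e.g. `sim_reads$truth`).
#' @param path output TSV path.
#' @export
write_truth_manifest <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA", colClasses = NA)
}

#' Read a site declaration from a YAML config
#'
#' The config names the amplicon FASTA and the guide: `amplicon_fasta`,
#' optional `amplicon_id`, `spacer`, `pam`, optional `strand`,
#' `cut_offset`, `window_width`.
#'
#' @param path YAML file path.
#' @param base_dir directory against which relative paths resolve
#'   (defaults to the config's directory).
#' @return a [target_site()].
#' @export
read_site_config <- function(path, base_dir = dirname(path)) {
  cfg <- yaml::read_yaml(path)
  s <- if (!is.null(cfg$site)) cfg$site else cfg
  fa <- s$amplicon_fasta
  if (is.null(fa)) stop("site config lacks 'amplicon_fasta'")
  if (!file.exists(fa)) fa <- file.path(base_dir, fa)
  if (!file.exists(fa)) stop("amplicon FASTA not found: ", s$amplicon_fasta)
  amps <- read_fasta(fa)
  id <- if (!is.null(s$amplicon_id)) s$amplicon_id else names(amps)[1]
  target_site(amps[[id]], s$spacer, s$pam, amplicon_id = id,
              strand = s$strand,
              cut_offset = if (!is.null(s$cut_offset)) s$cut_offset else 23L,
              window_width = if (!is.null(s$window_width)) s$window_width
                             else 12L)
}

#' Read a bedGraph coverage track
#'
#' Expands a bedGraph into a per-position depth vector for one contig
#' (positions without a record get depth 0). Requires rtracklayer.
#'
#' @param path bedGraph path.
#' @param contig contig name; defaults to the first seen.
#' @param length track length; defaults to the largest end coordinate.
#' @return integer vector of per-position depths.
#' @export
read_coverage_bedgraph <- function(path, contig = NULL, length = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read bedGraph files")
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  if (is.null(contig)) contig <- chroms[1]
  gr <- gr[chroms == contig]
  n <- if (is.null(length)) max(BiocGenerics::end(gr)) else length
  cov <- integer(n)
  st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
  sc <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) cov[st[i]:en[i]] <- sc[i]
  cov
}

#' Write enriched intervals as BED
#'
#' 0-based half-open intervals from [call_enriched_species()].
#'
#' @param intervals data.frame with `start`, `end` (and optionally
#'   `mean_depth`, written as score).
#' @param path output path.
#' @param contig contig name for the BED chrom column.
#' @export
write_enriched_bed <- function(intervals, path, contig = "track") {
  out <- data.frame(chrom = rep(contig, nrow(intervals)),
                    start = intervals$start, end = intervals$end,
                    name = sprintf("enriched_%d", seq_len(nrow(intervals))),
                    score = if ("mean_depth" %in% names(intervals))
                      round(intervals$mean_depth) else 0L,
                    strand = ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
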