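#' Quality-trim the 3' end of a read
#'
#' BWA-style running-sum trimming: with per-base Phred qualities `q`, the
#' read is cut before the position `i` that maximises
#' `sum(threshold - q[j])` over `j = i..L` accumulated from the 3' end,
#' provided that maximum is positive; ties cut at the leftmost maximum.
#' Reads with uniformly high quality are untouched.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string of the same length.
#' @param threshold Phred threshold (default 13).
#' @return list with trimmed `seq`, `qual` and `length`.
#' @examples
#' quality_trim("ACGT", "II$$")  # qualities 40,40,3,3 -> first 2 bases kept
#' @export
quality_trim <- function(seq, qual, threshold = 13L) {
  if (!is.character(seq) || !is.character(qual) || length(seq) != 1L ||
      length(qual) != 1L || is.na(seq) || is.na(qual) ||
      nchar(seq) != nchar(qual))
    stop("malformed read: sequence and quality must be equal-length strings")
  q <- utf8ToInt(qual) - 33L
  if (any(q < 0))
    stop("malformed quality string (characters below Phred+33 '!')")
  s <- rev(cumsum(rev(threshold - q)))
  keep <- if (max(s) > 0) which.max(s) - 1L else nchar(seq)
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep),
       length = keep)
}

#' Quality-trim a batch of reads
#'
#' Applies [quality_trim()] to every read and discards reads shorter than
#' `min_length` after trimming (discarded reads are counted, not returned).
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param threshold Phred threshold (default 13).
#' @param min_length minimum post-trim length retained (default 30).
#' @return list with `reads` (trimmed, surviving) and `n_discarded`.
#' @export
trim_reads <- function(reads, threshold = 13L, min_length = 30L) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  n <- nrow(reads)
  if (!n) return(list(reads = reads, n_discarded = 0L))
  bad <- which(nchar(reads$seq) != nchar(reads$qual) | is.na(reads$seq))
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1])
  seqs <- reads$seq; quals <- reads$qual
  # a read can only be trimmed if it has at least one base below threshold
  low <- grepl(sprintf("[\\x21-\\x%x]", 32L + threshold), quals, perl = TRUE)
  if (any(low)) {
    trimmed <- mapply(function(s, q) {
      t <- quality_trim(s, q, threshold)
      c(t$seq, t$qual)
    }, seqs[low], quals[low], USE.NAMES = FALSE)
    seqs[low] <- trimmed[1, ]; quals[low] <- trimmed[2, ]
  }
  keep <- nchar(seqs) >= min_length
  out <- data.frame(id = reads$id[keep], seq = seqs[keep],
                    qual = quals[keep], stringsAsFactors = FALSE)
  list(reads = out, n_discarded = sum(!keep))
}
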