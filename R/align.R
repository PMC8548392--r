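#' Default alignment scoring parameters
#'
#' Semi-global affine-gap scoring used throughout the package: the read is
#' aligned end-to-end, amplicon overhangs are free. A gap of length `k`
#' scores `-(gap_open + k * gap_ext)`.
#'
#' @param match,mismatch,gap_open,gap_ext scoring values.
#' @param min_identity reads whose fraction of matching bases (over read
#'   length) falls below this floor are counted unaligned (default 0.6).
#' @return list of scoring parameters.
#' @export
align_params <- function(match = 2L, mismatch = -3L, gap_open = 6L,
                         gap_ext = 1L, min_identity = 0.6) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_ext > 0,
            min_identity >= 0, min_identity <= 1)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, min_identity = min_identity)
}

#' Align one read against an amplicon
#'
#' Semi-global (glocal) affine-gap alignment: every read base is aligned,
#' leading/trailing amplicon bases are free. Traceback prefers, in order,
#' diagonal, deletion, insertion; indel placement is made canonical
#' afterwards by left-normalisation in [extract_indels()].
#'
#' @param read read sequence (ACGTN).
#' @param amplicon reference amplicon sequence.
#' @param params scoring from [align_params()].
#' @return object of class `read_alignment`: `score`, `ref_start`/`ref_end`
#'   (0-based half-open span on the amplicon), `ops` (per-column M/D/I
#'   string), `n_match`, `identity` (matches / read length), and `aligned`
#'   (identity above the floor).
#' @export
align_read <- function(read, amplicon, params = align_params()) {
  .check_dna(read, "read"); .check_dna(amplicon, "amplicon")
  a <- align_read_cpp(read, amplicon, params$match, params$mismatch,
                      params$gap_open, params$gap_ext)
  a$identity <- a$n_match / nchar(read)
  a$aligned <- a$identity >= params$min_identity
  a$read <- read
  class(a) <- "read_alignment"
  a
}

#' @export
print.read_alignment <- function(x, ...) {
  cat("read alignment: score ", x$score, ", reference span [", x$ref_start,
      ", ", x$ref_end, "), identity ", sprintf("%.1f%%", 100 * x$identity),
      if (!x$aligned) " (below floor: unaligned)", "\n", sep = "")
  invisible(x)
}

# Shift a deletion [s, e) left while the base before it equals the last
# deleted base (0-based half-open; `ref` is the amplicon string).
.left_normalize_deletion <- function(ref, s, e) {
  while (s > 0L &&
         substr(ref, s, s) == substr(ref, e, e)) { # ref[s-1] == ref[e-1]
    s <- s - 1L; e <- e - 1L
  }
  c(s, e)
}

# Shift an insertion left while the base before the anchor equals the last
# inserted base, rotating the inserted sequence accordingly.
.left_normalize_insertion <- function(ref, anchor, ins) {
  k <- nchar(ins)
  while (anchor > 0L && substr(ref, anchor, anchor) == substr(ins, k, k)) {
    ins <- paste0(substr(ins, k, k), substr(ins, 1L, k - 1L))
    anchor <- anchor - 1L
  }
  list(anchor = anchor, inserted = ins)
}

.indel_key <- function(kind, start, end, inserted) {
  ifelse(kind == "deletion",
         paste0("D:", start, "-", end),
         paste0("I:", start, ":", inserted))
}

#' Extract normalized indel events from an alignment
#'
#' Each gap run in the alignment becomes one event in amplicon coordinates
#' (0-based half-open; insertions are anchored at an inter-base coordinate).
#' Events are left-aligned: shifted left while the flanking base equals the
#' last base of the event, so sequence-equivalent placements collapse to one
#' canonical event. Substitutions are ignored.
#'
#' @param alignment a [align_read()] result.
#' @param amplicon the reference amplicon sequence.
#' @return data.frame with columns `kind` (`"deletion"`/`"insertion"`),
#'   `start`, `end` (equal to `start` for insertions), `inserted`, `key`.
#' @export
extract_indels <- function(alignment, amplicon) {
  ops <- alignment$ops
  if (!grepl("[DI]", ops)) return(.empty_indels())
  r <- rle(strsplit(ops, "")[[1]])
  kinds <- character(0); starts <- integer(0); ends <- integer(0)
  ins <- character(0)
  ref_pos <- alignment$ref_start
  read_pos <- 0L
  for (i in seq_along(r$values)) {
    op <- r$values[i]; len <- r$lengths[i]
    if (op == "M") {
      ref_pos <- ref_pos + len; read_pos <- read_pos + len
    } else if (op == "D") {
      nd <- .left_normalize_deletion(amplicon, ref_pos, ref_pos + len)
      kinds <- c(kinds, "deletion"); starts <- c(starts, nd[1])
      ends <- c(ends, nd[2]); ins <- c(ins, "")
      ref_pos <- ref_pos + len
    } else {
      seq_i <- substr(alignment$read, read_pos + 1L, read_pos + len)
      ni <- .left_normalize_insertion(amplicon, ref_pos, seq_i)
      kinds <- c(kinds, "insertion"); starts <- c(starts, ni$anchor)
      ends <- c(ends, ni$anchor); ins <- c(ins, ni$inserted)
      read_pos <- read_pos + len
    }
  }
  if (!length(kinds)) return(.empty_indels())
  data.frame(kind = kinds, start = starts, end = ends, inserted = ins,
             key = .indel_key(kinds, starts, ends, ins),
             stringsAsFactors = FALSE)
}

.EMPTY_INDELS <- data.frame(kind = character(0), start = integer(0),
                            end = integer(0), inserted = character(0),
                            key = character(0), stringsAsFactors = FALSE)

.empty_indels <- function() .EMPTY_INDELS

# Does an event intersect the half-open window? Deletions intersect by
# interval overlap; insertions by their inter-base anchor falling within
# the closed span of the window.
.in_window <- function(events, window) {
  if (!nrow(events)) return(logical(0))
  ifelse(events$kind == "deletion",
         events$start < window[2] & events$end > window[1],
         events$start >= window[1] & events$start <= window[2])
}
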