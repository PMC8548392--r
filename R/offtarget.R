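#' Enumerate candidate off-target sites in a genome
#'
#' Scans both strands of a genome for candidate guide binding sites: at
#' every PAM-pattern occurrence, the spacer is aligned against the adjacent
#' window (length `|spacer| + max_bulges`, anchored at the PAM, distal end
#' free) by a layered edit DP with unit mismatch and unit gap costs. A site
#' is emitted when some alignment uses at most `max_mm` mismatches and
#' `max_bulges` gaps; among feasible alignments the one with fewest gaps,
#' then fewest mismatches, then shortest genomic footprint is reported
#' (minimal-distortion interpretation). Genomic `N` never matches.
#' A gap on the genome (guide base unpaired) is an RNA bulge; a gap on the
#' guide (extra genome base) is a DNA bulge.
#'
#' @param genome genome sequence (uppercase ACGTN string) or a named
#'   character vector of contigs.
#' @param spacer guide spacer, 16-24 nt.
#' @param pam PAM pattern ([pam_pattern()] or string), 5' of the
#'   protospacer.
#' @param max_mm maximum mismatches (default 4).
#' @param max_bulges maximum bulges/gaps (default 2).
#' @param cut_offset,window_width expected-cut geometry for each candidate,
#'   measured on the genome from the PAM end along the protospacer strand.
#' @return data.frame of class `offtarget_candidates`: `chrom`, `start`,
#'   `end` (0-based half-open protospacer footprint on the top strand),
#'   `strand`, `n_mismatches`, `n_bulges`, `n_dna_bulges`, `n_rna_bulges`,
#'   `pam_seq`, `protospacer` (genomic slice, protospacer-strand
#'   orientation), `guide_aln`, `genome_aln` (gapped alignment strings),
#'   `cut_center`, `window_start`, `window_end`.
#' @export
enumerate_offtargets <- function(genome, spacer, pam, max_mm = 4L,
                                 max_bulges = 2L, cut_offset = 23L,
                                 window_width = 12L) {
  if (!inherits(pam, "pam_pattern")) pam <- pam_pattern(pam)
  spacer <- toupper(chartr("U", "T", spacer))
  if (nchar(spacer) < 16L) stop("spacer must be at least 16 nt")
  if (nchar(spacer) > 24L) stop("spacer must be at most 24 nt")
  if (is.null(names(genome))) names(genome) <- "genome"
  out <- list()
  for (chrom in names(genome)) {
    g <- toupper(genome[[chrom]])
    if (!nzchar(g)) next
    n <- nchar(g)
    for (st in c("+", "-")) {
      gs <- if (st == "+") g else .revcomp(g)
      hits <- scan_offtargets_cpp(gs, spacer, unclass(pam), max_mm, max_bulges)
      if (!nrow(hits)) next
      for (r in seq_len(nrow(hits))) {
        p <- hits[r, "pam_start"]; f <- hits[r, "footprint"]
        gg <- hits[r, "n_bulges"]; mm <- hits[r, "n_mismatches"]
        plen <- nchar(pam)
        if (st == "+") {
          start <- p + plen; end <- start + f
          pam_seq <- substr(gs, p + 1L, p + plen)
          cc <- start + cut_offset
        } else {
          start <- n - (p + plen + f); end <- n - (p + plen)
          pam_seq <- substr(gs, p + 1L, p + plen)
          cc <- end - cut_offset
        }
        proto <- substr(gs, p + plen + 1L, p + plen + f)
        win <- substr(gs, p + plen + 1L,
                      min(p + plen + nchar(spacer) + max_bulges, nchar(gs)))
        det <- .ot_align_detail(win, spacer, gg, mm, f)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = start, end = end, strand = st,
          n_mismatches = mm, n_bulges = gg,
          n_dna_bulges = det$n_dna, n_rna_bulges = det$n_rna,
          pam_seq = pam_seq, protospacer = proto,
          guide_aln = det$guide_aln, genome_aln = det$genome_aln,
          cut_center = cc,
          window_start = cc - window_width %/% 2L,
          window_end = cc + window_width %/% 2L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatches = integer(0), n_bulges = integer(0),
                      n_dna_bulges = integer(0), n_rna_bulges = integer(0),
                      pam_seq = character(0), protospacer = character(0),
                      guide_aln = character(0), genome_aln = character(0),
                      cut_center = integer(0), window_start = integer(0),
                      window_end = integer(0), stringsAsFactors = FALSE)
    class(res) <- c("offtarget_candidates", "data.frame")
    return(res)
  }
  res <- do.call(rbind, out)
  # deduplicate identical footprints, keeping the least-distorted alignment
  res <- res[order(res$chrom, res$start, res$end, res$strand,
                   res$n_bulges, res$n_mismatches), ]
  dupkey <- paste(res$chrom, res$start, res$end, res$strand)
  res <- res[!duplicated(dupkey), ]
  res <- res[order(res$chrom, res$start, res$strand), ]
  rownames(res) <- NULL
  class(res) <- c("offtarget_candidates", "data.frame")
  res
}

# Reconstruct one alignment achieving (g gaps, mm mismatches, footprint f)
# of the spacer against a PAM-anchored window; layered DP with traceback.
# Returns gapped strings plus DNA/RNA bulge counts.
.ot_align_detail <- function(window, spacer, g_target, mm_target, f) {
  L <- nchar(spacer); W <- nchar(window)
  sp <- strsplit(spacer, "")[[1]]; wn <- strsplit(window, "")[[1]]
  INF <- 1e9
  D <- array(INF, dim = c(g_target + 1L, L + 1L, W + 1L))
  D[1, 1, 1] <- 0
  cost <- function(a, b) if (a == b && a %in% c("A", "C", "G", "T")) 0 else 1
  for (g in 0:g_target) for (i in 0:L) for (j in 0:W) {
    cur <- D[g + 1, i + 1, j + 1]
    if (cur >= INF) next
    if (i < L && j < W) {
      v <- cur + cost(sp[i + 1], wn[j + 1])
      if (v < D[g + 1, i + 2, j + 2]) D[g + 1, i + 2, j + 2] <- v
    }
    if (g < g_target) {
      if (i < L && cur < D[g + 2, i + 2, j + 1]) D[g + 2, i + 2, j + 1] <- cur
      if (j < W && cur < D[g + 2, i + 1, j + 2]) D[g + 2, i + 1, j + 2] <- cur
    }
  }
  g <- g_target; i <- L; j <- f
  ga <- character(0); na_ <- character(0)
  n_dna <- 0L; n_rna <- 0L
  while (i > 0L || j > 0L) {
    cur <- D[g + 1, i + 1, j + 1]
    if (i > 0L && j > 0L &&
        D[g + 1, i, j] + cost(sp[i], wn[j]) == cur) {
      ga <- c(sp[i], ga); na_ <- c(wn[j], na_)
      i <- i - 1L; j <- j - 1L
    } else if (g > 0L && i > 0L && D[g, i, j + 1] == cur) {
      ga <- c(sp[i], ga); na_ <- c("-", na_)          # RNA bulge
      n_rna <- n_rna + 1L; i <- i - 1L; g <- g - 1L
    } else if (g > 0L && j > 0L && D[g, i + 1, j] == cur) {
      ga <- c("-", ga); na_ <- c(wn[j], na_)          # DNA bulge
      n_dna <- n_dna + 1L; j <- j - 1L; g <- g - 1L
    } else {
      stop("internal error: off-target alignment traceback failed")
    }
  }
  list(guide_aln = paste0(ga, collapse = ""),
       genome_aln = paste0(na_, collapse = ""),
       n_dna = n_dna, n_rna = n_rna)
}

#' Screen an off-target candidate locus for putative edits
#'
#' Read-level screening rules: a candidate needs at least `min_reads`
#' uniquely assigned reads; alterations are counted within the candidate's
#' 12-bp window (reusing the on-target indel extraction); the site is a
#' putative edit only when the mutant fraction exceeds `frac` (strict) and
#' the negative control is clean (at most `control_floor`). Uniqueness of a
#' read is decided by alignment-score margin: its score at the focal locus
#' must exceed its best score at any competing locus by at least `margin`.
#'
#' @param locus reference sequence of the candidate locus (slice of the
#'   genome around the candidate).
#' @param window 0-based half-open cut-site window within `locus`.
#' @param reads treated-sample reads assigned to the locus
#'   (data.frame `id`/`seq`/`qual` or `sim_reads`).
#' @param control_reads negative-control reads for the same locus.
#' @param competing_loci optional character vector of other candidate locus
#'   sequences used for the uniqueness margin.
#' @param min_reads minimum uniquely mapped reads (default 5).
#' @param frac mutant-fraction threshold, strict (default 0.20).
#' @param margin uniqueness score margin (default 10).
#' @param control_floor maximum control mutant fraction still considered
#'   clean (default 0.005; tolerates sequencing error rather than
#'   demanding a literal zero).
#' @param params alignment scoring from [align_params()].
#' @return object of class `screen_verdict`: `verdict` (`"putative_edit"`,
#'   `"clean"` or `"insufficient_coverage"`), `n_unique_reads`,
#'   `mutant_fraction`, `control_mutant_fraction`.
#' @export
screen_candidate <- function(locus, window, reads, control_reads,
                             competing_loci = NULL, min_reads = 5L,
                             frac = 0.20, margin = 10L,
                             control_floor = 0.005,
                             params = align_params()) {
  if (inherits(reads, "sim_reads")) reads <- reads$reads
  if (inherits(control_reads, "sim_reads")) control_reads <- control_reads$reads
  stats_for <- function(rd) {
    if (is.null(rd) || !nrow(rd)) return(list(n_unique = 0L, frac = 0))
    n_unique <- 0L; n_mut <- 0L
    for (i in seq_len(nrow(rd))) {
      a <- align_read(rd$seq[i], locus, params)
      if (!a$aligned) next
      if (!is.null(competing_loci) && length(competing_loci)) {
        other <- max(vapply(competing_loci, function(cl)
          align_read_cpp(rd$seq[i], cl, params$match, params$mismatch,
                         params$gap_open, params$gap_ext)$score, numeric(1)))
        if (a$score - other < margin) next
      }
      n_unique <- n_unique + 1L
      ev <- extract_indels(a, locus)
      if (any(.in_window(ev, window))) n_mut <- n_mut + 1L
    }
    list(n_unique = n_unique,
         frac = if (n_unique) n_mut / n_unique else 0)
  }
  s <- stats_for(reads)
  ctl <- stats_for(control_reads)
  verdict <- if (s$n_unique < min_reads) "insufficient_coverage"
             else if (s$frac > frac && ctl$frac <= control_floor) "putative_edit"
             else "clean"
  structure(list(verdict = verdict,
                 n_unique_reads = s$n_unique,
                 mutant_fraction = s$frac,
                 control_unique_reads = ctl$n_unique,
                 control_mutant_fraction = ctl$frac,
                 min_reads = min_reads, frac = frac,
                 control_floor = control_floor),
            class = "screen_verdict")
}

#' @export
print.screen_verdict <- function(x, ...) {
  cat("off-target screen: ", x$verdict, "\n", sep = "")
  cat(sprintf("  unique reads %d (min %d); mutant fraction %.3f (threshold > %.2f); control %.3f (floor %.3f)\n",
              x$n_unique_reads, x$min_reads, x$mutant_fraction, x$frac,
              x$control_mutant_fraction, x$control_floor))
  invisible(x)
}

#' Extract the locus around an off-target candidate
#'
#' Returns the genomic slice around one candidate in protospacer-strand
#' orientation, with the candidate's cut-site window re-expressed in slice
#' coordinates — the reference against which locus reads are screened.
#'
#' @param genome genome string (or named vector of contigs).
#' @param candidate one row of an [enumerate_offtargets()] result.
#' @param flank bases kept on each side of the window (default 60).
#' @return list with `seq` and `window` (0-based half-open in slice
#'   coordinates).
#' @export
candidate_locus <- function(genome, candidate, flank = 60L) {
  if (is.null(names(genome))) names(genome) <- "genome"
  g <- genome[[candidate$chrom]]
  n <- nchar(g)
  lo <- max(0L, candidate$window_start - flank)
  hi <- min(n, candidate$window_end + flank)
  seq <- substr(g, lo + 1L, hi)
  if (candidate$strand == "+") {
    win <- c(candidate$window_start - lo, candidate$window_end - lo)
  } else {
    seq <- .revcomp(seq)
    win <- c(hi - candidate$window_end, hi - candidate$window_start)
  }
  list(seq = seq, window = win)
}

#' Write off-target candidates as a BED6+ table
#'
#' Standard BED columns (0-based half-open; score = mismatches + bulges)
#' followed by mismatch/bulge detail columns.
#'
#' @param candidates an [enumerate_offtargets()] result.
#' @param path output path.
#' @param guide_name value for the BED name column.
#' @return the path, invisibly.
#' @export
write_offtarget_bed <- function(candidates, path, guide_name = "guide") {
  out <- data.frame(
    chrom = candidates$chrom, start = candidates$start, end = candidates$end,
    name = guide_name, score = candidates$n_mismatches + candidates$n_bulges,
    strand = candidates$strand,
    n_mismatches = candidates$n_mismatches, n_bulges = candidates$n_bulges,
    n_dna_bulges = candidates$n_dna_bulges,
    n_rna_bulges = candidates$n_rna_bulges,
    pam = candidates$pam_seq)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
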