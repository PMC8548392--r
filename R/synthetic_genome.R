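#' Plant off-target sites in a synthetic genome
#'
#' Generates a uniform-composition random genome and plants guide binding
#' sites with exactly the requested mismatch/bulge compositions, each with
#' a valid PAM. Every planted site is verified in place (the layered DP
#' must report exactly the requested counts, so flank aliasing is
#' excluded), and background regions producing spurious candidates within
#' the verification limits are resampled until none remain outside the
#' planted sites.
#'
#' @param genome_length genome size in bp.
#' @param spacer guide spacer (DNA string, >= 16 nt).
#' @param pam PAM pattern ([pam_pattern()] or string).
#' @param spec site specification: a data.frame with columns
#'   `n_mismatches`, `n_bulges` and optionally `bulge_kind`
#'   (`"dna"`, `"rna"` or `"mixed"`) and `strand`; or a list of
#'   `c(mm, bulges)` vectors.
#' @param seed RNG seed.
#' @param scan_max_mm,scan_max_bulges limits within which the genome is
#'   guaranteed free of spurious sites (defaults 4 and 2).
#' @return object of class `sim_genome`: `genome` (string) and `truth`
#'   (one row per planted site: coordinates, strand, realized mismatch and
#'   bulge counts and kinds, PAM and variant sequences).
#' @export
plant_offtargets <- function(genome_length, spacer, pam, spec, seed = 1L,
                             scan_max_mm = 4L, scan_max_bulges = 2L) {
  if (!inherits(pam, "pam_pattern")) pam <- pam_pattern(pam)
  spacer <- toupper(chartr("U", "T", spacer)); .check_dna(spacer, "spacer")
  L <- nchar(spacer); plen <- nchar(pam)
  spec <- .normalize_ot_spec(spec)
  if (any(spec$n_bulges > L))
    stop("infeasible site specification: more bulges than spacer bases")
  if (any(spec$n_mismatches + spec$n_bulges > L - 2L))
    stop("infeasible site specification: too many edits for interior placement")
  set.seed(seed)
  nsites <- nrow(spec)
  if (!nrow(spec)) stop("empty off-target specification")
  slot <- plen + L + scan_max_bulges + 60L
  if (nsites * slot > genome_length - 2L * slot)
    stop("requested sites do not fit in a genome of length ", genome_length)
  bases <- c("A", "C", "G", "T")
  genome <- paste0(sample(bases, genome_length, replace = TRUE),
                   collapse = "")
  if (!("strand" %in% names(spec)))
    spec$strand <- sample(c("+", "-"), nsites, replace = TRUE)

  # evenly spaced slots with margins
  anchors <- round(seq(slot, genome_length - slot, length.out = nsites))
  truth <- vector("list", nsites)
  for (k in seq_len(nsites)) {
    placed <- FALSE
    for (try in 1:80) {
      v <- .make_site_variant(spacer, spec$n_mismatches[k], spec$n_bulges[k],
                              spec$bulge_kind[k])
      pam_seq <- paste0(vapply(strsplit(unclass(pam), "")[[1]], function(p) {
        sample(setdiff(.IUPAC[[p]], "N"), 1L)
      }, character(1)), collapse = "")
      site_seq <- paste0(pam_seq, v$variant)
      s <- anchors[k]
      ins <- if (spec$strand[k] == "+") site_seq else .revcomp(site_seq)
      genome2 <- paste0(substr(genome, 1L, s),
                        ins,
                        substr(genome, s + nchar(ins) + 1L, genome_length))
      vlen <- nchar(v$variant)
      if (spec$strand[k] == "+") {
        proto_start <- s + plen; proto_end <- proto_start + vlen
        win <- substr(genome2, proto_start + 1L,
                      min(proto_start + L + scan_max_bulges, genome_length))
        pam_start <- s
      } else {
        proto_start <- s; proto_end <- s + vlen
        wlo <- max(0L, proto_end - (L + scan_max_bulges))
        win <- .revcomp(substr(genome2, wlo + 1L, proto_end))
        pam_start <- proto_end
      }
      res <- offtarget_dp_cpp(win, spacer, scan_max_mm, scan_max_bulges)
      if (res[1] == spec$n_bulges[k] && res[2] == spec$n_mismatches[k] &&
          res[3] == vlen) {
        genome <- genome2
        truth[[k]] <- data.frame(
          name = sprintf("site_%02d", k), chrom = "genome",
          start = proto_start, end = proto_end, strand = spec$strand[k],
          n_mismatches = spec$n_mismatches[k], n_bulges = spec$n_bulges[k],
          n_dna_bulges = v$n_dna, n_rna_bulges = v$n_rna,
          pam_start = pam_start, pam_seq = pam_seq, variant = v$variant,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not realize site specification (", spec$n_mismatches[k],
           " mm, ", spec$n_bulges[k], " bulges) without aliasing")
  }
  truth <- do.call(rbind, truth)

  # scrub spurious background candidates within the verification limits;
  # only the exact planted PAM+variant cores are untouchable
  core <- cbind(ifelse(truth$strand == "+", truth$pam_start, truth$start),
                ifelse(truth$strand == "+", truth$end,
                       truth$pam_start + plen))
  core_pos <- unlist(apply(core, 1, function(p) seq.int(p[1] + 1L, p[2])))
  truth_key <- paste(truth$start, truth$end, truth$strand)
  clean <- FALSE
  for (iter in 1:40) {
    cand <- enumerate_offtargets(genome, spacer, pam, scan_max_mm,
                                 scan_max_bulges)
    spurious <- cand[!(paste(cand$start, cand$end, cand$strand) %in%
                         truth_key), , drop = FALSE]
    if (!nrow(spurious)) { clean <- TRUE; break }
    gch <- strsplit(genome, "")[[1]]
    touched <- FALSE
    for (i in seq_len(nrow(spurious))) {
      lo <- max(1L, spurious$start[i] - plen)
      hi <- min(genome_length, spurious$end[i] + plen)
      pos <- setdiff(lo:hi, core_pos)
      if (length(pos)) {
        gch[pos] <- sample(bases, length(pos), replace = TRUE)
        touched <- TRUE
      }
    }
    if (!touched)
      stop("a spurious candidate lies entirely within a planted site; ",
           "use a different seed")
    genome <- paste0(gch, collapse = "")
  }
  if (!clean)
    stop("could not scrub spurious background sites; use a different seed")
  # flank resampling must not have disturbed the planted compositions
  cand_key <- paste(cand$start, cand$end, cand$strand,
                    cand$n_mismatches, cand$n_bulges)
  full_key <- paste(truth$start, truth$end, truth$strand,
                    truth$n_mismatches, truth$n_bulges)
  if (!all(full_key %in% cand_key))
    stop("planted site composition changed during background scrubbing; ",
         "use a different seed")
  structure(list(genome = c(genome = genome), truth = truth, spacer = spacer,
                 pam = pam, seed = seed),
            class = "sim_genome")
}

.normalize_ot_spec <- function(spec) {
  if (is.data.frame(spec)) {
    stopifnot(all(c("n_mismatches", "n_bulges") %in% names(spec)))
    if (!("bulge_kind" %in% names(spec))) spec$bulge_kind <- "mixed"
    return(spec)
  }
  if (is.list(spec)) {
    df <- do.call(rbind, lapply(spec, function(x)
      data.frame(n_mismatches = x[[1]], n_bulges = x[[2]],
                 bulge_kind = if (length(x) >= 3) as.character(x[[3]])
                              else "mixed",
                 stringsAsFactors = FALSE)))
    return(df)
  }
  stop("spec must be a data.frame or a list of (mm, bulges) vectors")
}

# Build a protospacer variant with exactly m substitutions and b bulges at
# interior positions; the in-place DP verification upstream rejects drawn
# variants whose minimal alignment distance aliases to something smaller.
.make_site_variant <- function(spacer, m, b, bulge_kind = "mixed") {
  sp <- strsplit(spacer, "")[[1]]
  L <- length(sp)
  bases <- c("A", "C", "G", "T")
  interior <- 2:(L - 1L)
  kinds <- if (b > 0) switch(bulge_kind,
                             dna = rep("dna", b), rna = rep("rna", b),
                             sample(c("dna", "rna"), b, replace = TRUE))
           else character(0)
  pos <- sample(interior, m + b)
  sub_pos <- if (m > 0) pos[seq_len(m)] else integer(0)
  bulge_pos <- if (b > 0) pos[m + seq_len(b)] else integer(0)
  out <- character(0)
  for (i in seq_len(L)) {
    if (i %in% bulge_pos) {
      kind <- kinds[match(i, bulge_pos)]
      if (kind == "rna") {
        # guide base unpaired: genome lacks this position
      } else {
        out <- c(out, sp[i], sample(bases, 1L))  # extra genome base after i
      }
    } else if (i %in% sub_pos) {
      out <- c(out, sample(setdiff(bases, sp[i]), 1L))
    } else {
      out <- c(out, sp[i])
    }
  }
  list(variant = paste0(out, collapse = ""),
       n_dna = sum(kinds == "dna"), n_rna = sum(kinds == "rna"))
}

#' Simulate reads over an off-target locus
#'
#' Emits reads spanning a candidate locus; a configurable fraction carry a
#' deletion centred in the cut-site window (a putative edit signal), the
#' rest are reference reads with sequencing error.
#'
#' @param locus locus reference sequence.
#' @param window 0-based half-open cut-site window in locus coordinates.
#' @param depth number of reads.
#' @param mutant_fraction fraction of reads carrying the window deletion.
#' @param seed RNG seed.
#' @param del_length deletion length for mutant reads (default 5).
#' @param substitution_error_rate per-base substitution error (default 1e-3).
#' @param quality_char Phred+33 quality character used for all bases.
#' @return data.frame of reads (`id`, `seq`, `qual`).
#' @export
simulate_locus_reads <- function(locus, window, depth, mutant_fraction = 0,
                                 seed = 1L, del_length = 5L,
                                 substitution_error_rate = 1e-3,
                                 quality_char = "I") {
  set.seed(seed)
  centre <- (window[1] + window[2]) %/% 2L
  s <- centre - del_length %/% 2L
  mut <- paste0(substr(locus, 1L, s),
                substr(locus, s + del_length + 1L, nchar(locus)))
  is_mut <- runif(depth) < mutant_fraction
  seqs <- ifelse(is_mut, mut, locus)
  seqs <- .apply_seq_errors(seqs, substitution_error_rate, 0)
  data.frame(id = sprintf("lread_%05d", seq_len(depth)),
             seq = seqs,
             qual = strrep(quality_char, nchar(seqs)),
             stringsAsFactors = FALSE)
}
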