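#' PAM pattern
#'
#' Validates an IUPAC protospacer-adjacent-motif pattern. Cas12f1 PAMs sit
#' 5' of the protospacer; SpCas12f1 prefers 5'-TTC, AsCas12f1 5'-YTTN.
#'
#' @param pattern IUPAC nucleotide string, e.g. `"TTC"` or `"YTTN"`.
#' @return The pattern as a classed character scalar.
#' @examples
#' pam_pattern("YTTN")
#' @export
pam_pattern <- function(pattern) {
  if (length(pattern) != 1L || !is.character(pattern) || !nzchar(pattern))
    stop("PAM pattern must be a non-empty string")
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC code(s) in PAM pattern: ", paste(bad, collapse = ", "))
  structure(pattern, class = "pam_pattern")
}

#' Match a sequence window against a PAM pattern
#'
#' Each base must fall in the IUPAC class of the corresponding pattern
#' symbol. An `N` in the sequence matches only the pattern symbol `N`
#' (an undetermined base is never accepted by a degenerate symbol).
#'
#' @param window_seq uppercase ACGTN string, same length as the pattern.
#' @param pattern a [pam_pattern()] or plain IUPAC string.
#' @return `TRUE` or `FALSE`.
#' @examples
#' match_pam("TTC", "TTC")
#' match_pam("CTTA", "YTTN")
#' @export
match_pam <- function(window_seq, pattern) {
  if (!inherits(pattern, "pam_pattern")) pattern <- pam_pattern(pattern)
  .check_dna(window_seq, "PAM window")
  if (nchar(window_seq) != nchar(pattern))
    stop("PAM window length (", nchar(window_seq),
         ") does not match pattern length (", nchar(pattern), ")")
  seq_chars <- strsplit(window_seq, "")[[1]]
  pat_chars <- strsplit(unclass(pattern), "")[[1]]
  all(mapply(function(s, p) s %in% .IUPAC[[p]], seq_chars, pat_chars))
}

#' Expected cut-site window
#'
#' Cas12f1 cleaves 22-24 bp downstream of the 5' PAM; indel analysis uses a
#' 12-bp window centred over the expected cleavage site. Coordinates are
#' 0-based: `cut_center` is an inter-base coordinate and the window is
#' half-open.
#'
#' @param pam_end 0-based coordinate of the PAM end adjacent to the
#'   protospacer (for a minus-strand site, the lower amplicon coordinate of
#'   the PAM interval).
#' @param strand `"+"` or `"-"` of the protospacer.
#' @param offset distance from PAM end to the cut centre (22-24; default 23,
#'   the midpoint of the observed cleavage range).
#' @param width even window width (default 12).
#' @param amplicon_length optional; when given, a window extending beyond
#'   the amplicon is an error.
#' @param id site name used in error messages.
#' @return list with `cut_center` and `window` (length-2 half-open interval).
#' @examples
#' expected_cut_window(13, "+")  # cut centre 36, window [30, 42)
#' @export
expected_cut_window <- function(pam_end, strand = c("+", "-"), offset = 23L,
                                width = 12L, amplicon_length = NULL,
                                id = "site") {
  strand <- match.arg(strand)
  if (offset < 22 || offset > 24)
    stop("cut offset must lie in 22..24 (observed cleavage range)")
  if (width %% 2 != 0) stop("window width must be even")
  cut_center <- if (strand == "+") pam_end + offset else pam_end - offset
  window <- c(cut_center - width %/% 2, cut_center + width %/% 2)
  if (!is.null(amplicon_length) &&
      (window[1] < 0 || window[2] > amplicon_length || cut_center < 0 ||
       cut_center > amplicon_length))
    stop("cut window of '", id, "' extends beyond the amplicon [0, ",
         amplicon_length, "): window [", window[1], ", ", window[2], ")")
  list(cut_center = cut_center, window = window)
}

#' Validate a spacer sequence
#'
#' Effective Cas12f1 cleavage requires spacers of at least 16 nt.
#'
#' @param spacer nucleotide string.
#' @param min_length minimum accepted length (default 16).
#' @return list with `ok` (logical) and, when not ok, `reason`.
#' @export
validate_spacer <- function(spacer, min_length = 16L) {
  .check_dna(toupper(chartr("U", "T", spacer)), "spacer")
  if (nchar(spacer) >= min_length) return(list(ok = TRUE, reason = NULL))
  list(ok = FALSE,
       reason = sprintf("spacer length %d is below the %d nt minimum for effective cleavage",
                        nchar(spacer), min_length))
}

#' Construct a Cas12f1 target site on an amplicon
#'
#' Locates the protospacer (exact spacer match) and its PAM on the requested
#' strand(s) of the amplicon, and derives the expected cut centre and the
#' 12-bp analysis window. All coordinates are 0-based half-open on the
#' amplicon top strand.
#'
#' @param amplicon amplicon sequence (ACGTN string).
#' @param spacer guide spacer (DNA alphabet; >= 16 nt).
#' @param pam PAM pattern ([pam_pattern()] or string), 5' of the protospacer.
#' @param amplicon_id amplicon name.
#' @param strand `"+"`, `"-"`, or `NULL` to search both strands.
#' @param cut_offset,window_width see [expected_cut_window()].
#' @return object of class `target_site`.
#' @export
target_site <- function(amplicon, spacer, pam, amplicon_id = "amplicon",
                        strand = NULL, cut_offset = 23L, window_width = 12L) {
  if (!inherits(pam, "pam_pattern")) pam <- pam_pattern(pam)
  amplicon <- toupper(amplicon); .check_dna(amplicon, "amplicon")
  spacer <- toupper(chartr("U", "T", spacer)); .check_dna(spacer, "spacer")
  v <- validate_spacer(spacer)
  if (!v$ok) warning(v$reason)
  plen <- nchar(pam)

  hits <- list()
  strands <- if (is.null(strand)) c("+", "-") else strand
  for (st in strands) {
    target <- if (st == "+") spacer else .revcomp(spacer)
    starts <- gregexpr(target, amplicon, fixed = TRUE)[[1]]
    if (starts[1] == -1) next
    for (s0 in as.integer(starts) - 1L) {   # 0-based protospacer start
      if (st == "+") {
        ps <- s0 - plen
        if (ps < 0) next
        pam_seq <- substr(amplicon, ps + 1, ps + plen)
      } else {
        ps <- s0 + nchar(spacer)
        if (ps + plen > nchar(amplicon)) next
        pam_seq <- .revcomp(substr(amplicon, ps + 1, ps + plen))
      }
      if (!match_pam(pam_seq, pam)) next
      hits[[length(hits) + 1L]] <- list(strand = st, proto_start = s0,
                                        pam_start = ps, pam_seq = pam_seq)
    }
  }
  if (!length(hits))
    stop("no protospacer with a matching PAM found on amplicon '",
         amplicon_id, "'")
  if (length(hits) > 1L)
    stop("protospacer matches at multiple positions on amplicon '",
         amplicon_id, "'; disambiguate with `strand`")
  h <- hits[[1]]
  pam_end <- if (h$strand == "+") h$pam_start + plen else h$pam_start
  cw <- expected_cut_window(pam_end, h$strand, cut_offset, window_width,
                            nchar(amplicon), amplicon_id)
  structure(list(
    amplicon_id = amplicon_id,
    amplicon = amplicon,
    spacer = spacer,
    pam = pam,
    pam_seq = h$pam_seq,
    pam_interval = c(h$pam_start, h$pam_start + plen),
    strand = h$strand,
    protospacer_interval = c(h$proto_start, h$proto_start + nchar(spacer)),
    cut_center = cw$cut_center,
    window = cw$window,
    cut_offset = cut_offset
  ), class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat("Cas12f1 target site on '", x$amplicon_id, "' (", nchar(x$amplicon),
      " bp)\n", sep = "")
  cat("  spacer      : ", x$spacer, " (", nchar(x$spacer), " nt)\n", sep = "")
  cat("  PAM         : ", x$pam_seq, " (pattern ", unclass(x$pam),
      "), positions ", x$pam_interval[1] + 1, "-", x$pam_interval[2],
      " (", x$strand, ")\n", sep = "")
  cat("  cut centre  : after base ", x$cut_center,
      " (", x$cut_offset, " bp from PAM)\n", sep = "")
  cat("  window      : positions ", x$window[1] + 1, "-", x$window[2],
      " (", x$window[2] - x$window[1], " bp)\n", sep = "")
  invisible(x)
}

# RNA base-pair score for the repeat:anti-repeat duplex. Watson-Crick 2,
# G:U wobble 1, otherwise -2.
.rna_pair_score <- function(a, b) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  wb <- (a == "G" & b == "U") | (a == "U" & b == "G")
  ifelse(wc, 2L, ifelse(wb, 1L, -2L))
}

#' Locate the anti-repeat region of a tracrRNA
#'
#' Finds the highest-scoring ungapped antiparallel pairing of the CRISPR
#' repeat against any window of the tracrRNA. Watson-Crick pairs score 2,
#' G:U wobbles 1, other juxtapositions -2.
#'
#' @param tracr,crrna_repeat RNA strings (`U`, not `T`).
#' @param min_score minimum duplex score to report (default 8).
#' @return `NULL` when no window reaches `min_score`; otherwise a list with
#'   `repeat_interval` and `tracr_interval` (0-based half-open), `score`,
#'   and `pairing` (per repeat position: `"WC"`, `"wobble"` or `"mismatch"`,
#'   5'->3' along the repeat).
#' @export
find_anti_repeat <- function(tracr, crrna_repeat, min_score = 8L) {
  for (s in c(tracr, crrna_repeat)) {
    if (length(s) != 1L || !nzchar(s)) stop("empty RNA sequence")
    if (grepl("[^ACGU]", s)) stop("RNA alphabet required (ACGU)")
  }
  L <- nchar(crrna_repeat); nt <- nchar(tracr)
  if (L > nt) return(NULL)
  rep_chars <- strsplit(crrna_repeat, "")[[1]]
  tr_chars <- strsplit(tracr, "")[[1]]
  best <- NULL
  for (s in 1:(nt - L + 1L)) {
    win <- tr_chars[(s + L - 1L):s]          # antiparallel: reversed window
    sc <- .rna_pair_score(rep_chars, win)
    tot <- sum(sc)
    if (is.null(best) || tot > best$score) {
      best <- list(repeat_interval = c(0L, L),
                   tracr_interval = c(s - 1L, s - 1L + L),
                   score = tot,
                   pairing = ifelse(sc == 2L, "WC",
                                    ifelse(sc == 1L, "wobble", "mismatch")))
    }
  }
  if (best$score < min_score) return(NULL)
  best
}

#' Guide architecture
#'
#' Describes a single-guide RNA as tracrRNA + tetranucleotide linker +
#' crRNA repeat + spacer, with the repeat:anti-repeat duplex located by
#' [find_anti_repeat()].
#'
#' @param tracr,crrna_repeat,spacer RNA strings.
#' @param linker 4-nt RNA linker joining tracrRNA and crRNA (default GAAA).
#' @param min_duplex_score passed to [find_anti_repeat()].
#' @return object of class `guide_architecture`.
#' @export
guide_architecture <- function(tracr, crrna_repeat, spacer, linker = "GAAA",
                               min_duplex_score = 8L) {
  if (nchar(linker) != 4L) stop("linker must be exactly 4 nt")
  for (s in c(tracr, crrna_repeat, spacer))
    if (!nzchar(s)) stop("guide components must be non-empty")
  duplex <- find_anti_repeat(tracr, crrna_repeat, min_duplex_score)
  structure(list(tracr = tracr, crrna_repeat = crrna_repeat, spacer = spacer,
                 linker = linker, duplex = duplex),
            class = "guide_architecture")
}

#' Assemble a single-guide RNA
#'
#' Concatenates the guide components 5'->3'. The default order is
#' tracrRNA, linker, crRNA repeat, spacer; the junction order is
#' configurable.
#'
#' @param arch a [guide_architecture()] (or list with the same fields).
#' @param order component order, a permutation of
#'   `c("tracr", "linker", "crrna_repeat", "spacer")`.
#' @return the sgRNA sequence (RNA string).
#' @export
assemble_sgRNA <- function(arch,
                           order = c("tracr", "linker", "crrna_repeat",
                                     "spacer")) {
  stopifnot(setequal(order, c("tracr", "linker", "crrna_repeat", "spacer")))
  parts <- lapply(order, function(f) arch[[f]])
  if (any(!vapply(parts, nzchar, logical(1))))
    stop("guide components must be non-empty")
  if (nchar(arch$linker) != 4L) stop("linker must be exactly 4 nt")
  paste0(unlist(parts), collapse = "")
}

#' Call enriched RNA species from a coverage track
#'
#' Identifies maximal intervals whose read depth is at least `k` times the
#' track median (runs of above-threshold positions), merging runs separated
#' by gaps of at most `merge_gap` positions. Used to pick out crRNA and
#' tracrRNA species from RNA-seq pileups. With an all-zero median the
#' threshold floor is `k` (a median of 1 read is assumed).
#'
#' @param coverage non-negative integer vector of per-position depths.
#' @param k enrichment multiplier over the median (default 10).
#' @param merge_gap maximum gap bridged between runs (default 5).
#' @return data.frame with 0-based half-open `start`, `end` and `mean_depth`;
#'   zero rows when nothing is enriched.
#' @export
call_enriched_species <- function(coverage, k = 10, merge_gap = 5L) {
  if (any(coverage < 0)) stop("coverage must be non-negative")
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_depth = numeric(0))
  if (!length(coverage) || all(coverage == 0)) return(empty)
  med <- stats::median(coverage)
  thr <- k * max(med, 1)
  above <- coverage >= thr & coverage > 0
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])   # 1-based closed
  # merge across small gaps
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] - merged[nrow(merged), 2] - 1L <= merge_gap)
      merged[nrow(merged), 2] <- iv[i, 2]
    else merged <- rbind(merged, iv[i, ])
  }
  data.frame(start = merged[, 1] - 1L, end = merged[, 2],
             mean_depth = apply(merged, 1, function(r2)
               mean(coverage[r2[1]:r2[2]])))
}
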