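# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (exhaustive enumeration / recursion) and separate from
# the implementation paths they check.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste0(sample(BASES, n, replace = TRUE),
                                 collapse = "")

# A standard test site: 40 bp left flank, TTC PAM, 20-nt spacer, 80 bp
# right flank. Cut centre falls 23 bp into the amplicon interior.
make_test_site <- function(seed = 42, spacer = "GCTGACGTATGCAATGCTAC",
                           pam = "TTC", left = 40, right = 80) {
  set.seed(seed)
  amp <- paste0(random_dna(left), pam, spacer, random_dna(right))
  target_site(amp, spacer, pam)
}

# Exhaustive 3'-trim oracle: try every cut point, maximize the suffix sum
# of (threshold - q); ties keep the leftmost (most aggressive) cut.
oracle_trim_keep <- function(q, threshold = 13L) {
  L <- length(q)
  best_sum <- 0; best_keep <- L
  for (cut in 1:L) {                 # left-to-right; '>' keeps leftmost ties
    s <- sum(threshold - q[cut:L])
    if (s > best_sum) { best_sum <- s; best_keep <- cut - 1L }
  }
  best_keep
}

# Independent semi-global alignment score oracle: top-down memoized
# recursion over (ref pos, read pos, last op), read global, reference
# end-gaps free. Gap of length k costs open + k * ext.
oracle_align_score <- function(read, ref, match = 2, mis = -3,
                               go = 6, ge = 1) {
  rd <- strsplit(read, "")[[1]]; rf <- strsplit(ref, "")[[1]]
  m <- length(rd); n <- length(rf)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, state) {
    if (j == m) return(0)                # trailing reference is free
    key <- paste(i, j, state)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- -Inf
    if (i < n) {
      v <- max(v, (if (rf[i + 1L] == rd[j + 1L]) match else mis) +
                 rec(i + 1L, j + 1L, "M"))
      v <- max(v, -(if (state == "D") ge else go + ge) +
                 rec(i + 1L, j, "D"))
    }
    v <- max(v, -(if (state == "I") ge else go + ge) + rec(i, j + 1L, "I"))
    memo[[key]] <- v
    v
  }
  max(vapply(0:n, function(s) rec(s, 0L, "S"), numeric(1)))
}

# Exhaustive anti-repeat oracle: naive per-window rescoring with explicit
# character loops.
oracle_anti_repeat <- function(tracr, rep_seq) {
  pair_score <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(2)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(1)
    -2
  }
  L <- nchar(rep_seq); nt <- nchar(tracr)
  rc <- strsplit(rep_seq, "")[[1]]; tc <- strsplit(tracr, "")[[1]]
  best <- -Inf; best_start <- NA
  for (s in 1:(nt - L + 1)) {
    tot <- 0
    for (i in 1:L) tot <- tot + pair_score(rc[i], tc[s + L - i])
    if (tot > best) { best <- tot; best_start <- s }
  }
  list(score = best, tracr_start = best_start - 1L)
}

# Full-DP off-target oracle: at every PAM match on both strands, top-down
# memoized recursion over (spacer consumed, window consumed, gaps used)
# computing the minimum mismatches; lexicographically smallest feasible
# (gaps, mismatches) reported per site.
oracle_offtargets <- function(genome, spacer, pam, max_mm, max_b) {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  L <- nchar(spacer); plen <- nchar(pam)
  sp <- strsplit(spacer, "")[[1]]
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T", "N"))
  pc <- strsplit(pam, "")[[1]]
  pam_ok <- function(s) all(mapply(function(ch, p) ch %in% iupac[[p]],
                                   strsplit(s, "")[[1]], pc))
  scan_strand <- function(g) {
    n <- nchar(g)
    out <- list()
    for (p in 0:(n - plen - 1L)) {
      if (!pam_ok(substr(g, p + 1L, p + plen))) next
      wlen <- min(L + max_b, n - (p + plen))
      if (wlen < L - max_b) next
      wn <- strsplit(substr(g, p + plen + 1L, p + plen + wlen), "")[[1]]
      memo <- new.env(hash = TRUE)
      mm_min <- function(i, j, g_used) {
        # min mismatches aligning spacer[1..i] to window[1..j] with g_used gaps
        if (i == 0L && j == 0L) return(if (g_used == 0L) 0L else Inf)
        if (g_used < 0L) return(Inf)
        key <- paste(i, j, g_used)
        if (!is.null(memo[[key]])) return(memo[[key]])
        v <- Inf
        if (i > 0L && j > 0L) {
          mmc <- if (sp[i] == wn[j] && sp[i] %in% BASES) 0L else 1L
          v <- min(v, mm_min(i - 1L, j - 1L, g_used) + mmc)
        }
        if (i > 0L) v <- min(v, mm_min(i - 1L, j, g_used - 1L))
        if (j > 0L) v <- min(v, mm_min(i, j - 1L, g_used - 1L))
        memo[[key]] <- v
        v
      }
      found <- NULL
      for (g_used in 0:max_b) {
        mms <- vapply(0:wlen, function(j) mm_min(L, j, g_used), numeric(1))
        if (min(mms) <= max_mm) {
          found <- c(g_used, min(mms), which.min(mms) - 1L)
          break
        }
      }
      if (!is.null(found))
        out[[length(out) + 1L]] <- c(pam_start = p, n_bulges = found[1],
                                     n_mismatches = found[2],
                                     footprint = found[3])
    }
    out
  }
  n <- nchar(genome)
  res <- list()
  for (h in scan_strand(genome)) {
    res[[length(res) + 1L]] <- data.frame(
      start = h["pam_start"] + plen, end = h["pam_start"] + plen +
        h["footprint"], strand = "+",
      n_bulges = h["n_bulges"], n_mismatches = h["n_mismatches"])
  }
  for (h in scan_strand(rc(genome))) {
    res[[length(res) + 1L]] <- data.frame(
      start = n - (h["pam_start"] + plen + h["footprint"]),
      end = n - (h["pam_start"] + plen), strand = "-",
      n_bulges = h["n_bulges"], n_mismatches = h["n_mismatches"])
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_bulges = integer(0),
                      n_mismatches = integer(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start, out$strand), ]
}

# Minimal hand-built call set for zygosity unit tests.
fake_callset <- function(mutant, wildtype, top_key = "D:60-65",
                         top_count = mutant) {
  types <- if (is.na(top_key))
    data.frame(key = character(0), kind = character(0), start = integer(0),
               end = integer(0), inserted = character(0), count = integer(0),
               control_count = integer(0), freq = numeric(0),
               control_freq = numeric(0), retained = logical(0))
  else {
    st <- as.integer(sub("^[DI]:(\\d+).*$", "\\1", top_key))
    data.frame(key = top_key, kind = "deletion", start = st, end = st + 5L,
               inserted = "", count = as.integer(top_count),
               control_count = 0L, freq = top_count / (mutant + wildtype),
               control_freq = 1e-5, retained = TRUE)
  }
  structure(list(sample_id = "fake", site_id = "amp", types = types,
                 total_reads = mutant + wildtype, trimmed_discarded = 0L,
                 unaligned = 0L, aligned_reads = mutant + wildtype,
                 control_aligned = 10000L, multiplier = 30,
                 mutant_reads = mutant, wildtype_reads = wildtype,
                 frequency_ratio = if (wildtype) mutant / wildtype else Inf,
                 frequency_pct = 100 * mutant / (mutant + wildtype),
                 saturated = FALSE),
            class = "sample_callset")
}
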