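#' Simulation configuration
#'
#' Parameters for the amplicon read simulator. Defaults emulate the study
#' conditions: deletion-dominated editing outcomes centred on the expected
#' cut site, low independent per-base substitution error, rare 1-bp error
#' indels, and high mean base quality with a mild 3' decay.
#'
#' @param seed integer RNG seed; every generator is bit-reproducible under
#'   a fixed seed.
#' @param depth reads per sample.
#' @param edit_fraction fraction of reads carrying a true edit, in `[0, 1]`.
#' @param indel_spectrum from [indel_spectrum()].
#' @param substitution_error_rate per-base substitution error (default 1e-3).
#' @param error_indel_rate per-base 1-bp spurious indel rate (default 1e-4).
#' @param quality_mean,quality_decay,quality_sd Phred quality profile: mean
#'   at the 5' end, linear drop towards the 3' end, per-base Gaussian
#'   noise; clipped to `[2, 40]`.
#' @param fixed_indel optional single-row data.frame (`kind`, `start`,
#'   `end`, `inserted`) used for every edited read instead of drawing from
#'   the spectrum (used for plant simulations, where a germline edit is one
#'   shared allele).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, depth = 10000L, edit_fraction = 0,
                       indel_spectrum = cas12fkit::indel_spectrum(),
                       substitution_error_rate = 1e-3,
                       error_indel_rate = 1e-4,
                       quality_mean = 37, quality_decay = 8, quality_sd = 2,
                       fixed_indel = NULL) {
  stopifnot(edit_fraction >= 0, edit_fraction <= 1,
            substitution_error_rate >= 0, substitution_error_rate <= 1,
            error_indel_rate >= 0, error_indel_rate <= 1,
            depth >= 1)
  structure(list(seed = as.integer(seed), depth = as.integer(depth),
                 edit_fraction = edit_fraction,
                 indel_spectrum = indel_spectrum,
                 substitution_error_rate = substitution_error_rate,
                 error_indel_rate = error_indel_rate,
                 quality_mean = quality_mean, quality_decay = quality_decay,
                 quality_sd = quality_sd, fixed_indel = fixed_indel),
            class = "sim_config")
}

#' Indel spectrum for simulated edits
#'
#' Distribution over editing outcomes: deletion-dominated (deletions are
#' the predominant repair outcome at Cas12f1 cut sites), deletion lengths
#' 1-30 weighted toward 2-12, insertion lengths 1-5 uniform. Deletions are
#' placed to span the cut centre; insertion anchors fall within a few bases
#' of it.
#'
#' @param p_deletion probability an edit is a deletion (default 0.8).
#' @param del_lengths,del_weights deletion length support and weights.
#' @param ins_lengths,ins_weights insertion length support and weights.
#' @param ins_anchor_jitter maximum distance of an insertion anchor from
#'   the cut centre (default 3).
#' @return object of class `indel_spectrum`.
#' @export
indel_spectrum <- function(p_deletion = 0.8,
                           del_lengths = 1:30,
                           del_weights = ifelse(del_lengths %in% 2:12, 4, 1),
                           ins_lengths = 1:5,
                           ins_weights = rep(1, length(ins_lengths)),
                           ins_anchor_jitter = 3L) {
  stopifnot(p_deletion >= 0, p_deletion <= 1,
            length(del_lengths) == length(del_weights),
            length(ins_lengths) == length(ins_weights),
            all(del_weights >= 0), all(ins_weights >= 0))
  structure(list(p_deletion = p_deletion,
                 del_lengths = del_lengths,
                 del_weights = del_weights / sum(del_weights),
                 ins_lengths = ins_lengths,
                 ins_weights = ins_weights / sum(ins_weights),
                 ins_anchor_jitter = as.integer(ins_anchor_jitter)),
            class = "indel_spectrum")
}

# Draw n true edits overlapping the site's cut centre. Deletion intervals
# are uniform over placements containing the cut centre; insertion anchors
# jitter around it. Returns a data.frame of events (0-based half-open).
.draw_indels <- function(n, site, spectrum) {
  amp_len <- nchar(site$amplicon)
  cc <- site$cut_center
  is_del <- runif(n) < spectrum$p_deletion
  len <- integer(n); start <- integer(n); end <- integer(n)
  inserted <- character(n)
  nd <- sum(is_del)
  if (nd) {
    dl <- sample(spectrum$del_lengths, nd, replace = TRUE,
                 prob = spectrum$del_weights)
    if (any(dl >= amp_len))
      stop("deletion longer than the amplicon")
    lo <- pmax(0L, cc - dl); hi <- pmin(cc, amp_len - dl)
    ds <- lo + floor(runif(nd) * (hi - lo + 1L))
    start[is_del] <- as.integer(ds); end[is_del] <- as.integer(ds + dl)
    len[is_del] <- dl
  }
  ni <- n - nd
  if (ni) {
    il <- sample(spectrum$ins_lengths, ni, replace = TRUE,
                 prob = spectrum$ins_weights)
    j <- spectrum$ins_anchor_jitter
    anc <- pmin(pmax(cc + sample(-j:j, ni, replace = TRUE), 0L), amp_len)
    start[!is_del] <- anc; end[!is_del] <- anc
    inserted[!is_del] <- vapply(il, function(k)
      paste0(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
      character(1))
    len[!is_del] <- il
  }
  kind <- ifelse(is_del, "deletion", "insertion")
  data.frame(kind = kind, start = start, end = end, inserted = inserted,
             key = .indel_key(kind, start, end, inserted),
             stringsAsFactors = FALSE)
}

# Apply one indel event to a reference sequence.
.apply_indel <- function(ref, ev) {
  if (ev$kind == "deletion")
    paste0(substr(ref, 1L, ev$start), substr(ref, ev$end + 1L, nchar(ref)))
  else
    paste0(substr(ref, 1L, ev$start), ev$inserted,
           substr(ref, ev$start + 1L, nchar(ref)))
}

# Inject per-base substitution errors and rare 1-bp error indels into a
# character vector of read sequences.
.apply_seq_errors <- function(seqs, sub_rate, indel_rate) {
  n <- length(seqs)
  lens <- nchar(seqs)
  n_sub <- rbinom(n, lens, sub_rate)
  n_ind <- rbinom(n, lens, indel_rate)
  todo <- which(n_sub > 0L | n_ind > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in todo) {
    s <- strsplit(seqs[i], "")[[1]]
    if (n_sub[i] > 0L) {
      pos <- sample.int(length(s), min(n_sub[i], length(s)))
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    if (n_ind[i] > 0L) for (k in seq_len(n_ind[i])) {
      p <- sample.int(length(s), 1L)
      if (runif(1) < 0.5 && length(s) > 1L) s <- s[-p]           # 1-bp deletion
      else s <- append(s, sample(bases, 1L), after = p - 1L)     # 1-bp insertion
    }
    seqs[i] <- paste0(s, collapse = "")
  }
  seqs
}

# Phred+33 quality strings following the configured profile. Reads are
# grouped by length so the Gaussian noise is drawn in bulk.
.draw_qualities <- function(lens, cfg) {
  out <- character(length(lens))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    prof <- cfg$quality_mean -
      cfg$quality_decay * (seq_len(L) - 1) / max(L - 1, 1)
    q <- matrix(round(prof + rnorm(L * length(idx), 0, cfg$quality_sd)),
                nrow = L)
    q <- pmin(pmax(q, 2), 40) + 33L
    out[idx] <- vapply(seq_along(idx), function(j) intToUtf8(q[, j]),
                       character(1))
  }
  out
}

#' Simulate amplicon deep-sequencing reads
#'
#' Emits `depth` single-end reads spanning the full amplicon. Each read is
#' independently marked edited with probability `edit_fraction`; edited
#' reads carry one indel drawn from the spectrum (always overlapping the
#' cut centre). All reads then receive substitution errors, rare 1-bp error
#' indels, and Phred qualities. Deterministic under the configured seed.
#'
#' @param site a [target_site()].
#' @param cfg a [sim_config()].
#' @return object of class `sim_reads`: `reads` (data.frame `id`, `seq`,
#'   `qual`) and `truth` (per-read label and true event; the ground-truth
#'   manifest).
#' @export
simulate_amplicon_reads <- function(site, cfg = sim_config()) {
  stopifnot(inherits(site, "target_site"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$depth
  amp <- site$amplicon
  edited <- runif(n) < cfg$edit_fraction
  ne <- sum(edited)
  truth <- data.frame(read_id = sprintf("read_%06d", seq_len(n)),
                      edited = edited, key = NA_character_,
                      kind = NA_character_, start = NA_integer_,
                      end = NA_integer_, inserted = NA_character_,
                      stringsAsFactors = FALSE)
  seqs <- rep(amp, n)
  if (ne) {
    ev <- if (!is.null(cfg$fixed_indel)) {
      fi <- cfg$fixed_indel
      fi$key <- .indel_key(fi$kind, fi$start, fi$end, fi$inserted)
      fi[rep(1L, ne), , drop = FALSE]
    } else .draw_indels(ne, site, cfg$indel_spectrum)
    # apply each distinct event once
    ukey <- unique(ev$key)
    mut_seq <- setNames(vapply(ukey, function(k) {
      .apply_indel(amp, ev[match(k, ev$key), ])
    }, character(1)), ukey)
    seqs[edited] <- mut_seq[ev$key]
    truth$key[edited] <- ev$key
    truth$kind[edited] <- ev$kind
    truth$start[edited] <- ev$start
    truth$end[edited] <- ev$end
    truth$inserted[edited] <- ev$inserted
  }
  seqs <- .apply_seq_errors(seqs, cfg$substitution_error_rate,
                            cfg$error_indel_rate)
  quals <- .draw_qualities(nchar(seqs), cfg)
  structure(list(
    reads = data.frame(id = truth$read_id, seq = unname(seqs),
                       qual = quals, stringsAsFactors = FALSE),
    truth = truth,
    edit_fraction = cfg$edit_fraction,
    seed = cfg$seed
  ), class = "sim_reads")
}

#' Simulate a negative-control read set
#'
#' A control sample is the same amplicon sequenced without the guide:
#' identical to [simulate_amplicon_reads()] with `edit_fraction = 0`, so
#' only sequencing error remains.
#'
#' @inheritParams simulate_amplicon_reads
#' @return a `sim_reads` object with no edited reads.
#' @export
simulate_negative_control <- function(site, cfg = sim_config()) {
  cfg$edit_fraction <- 0
  simulate_amplicon_reads(site, cfg)
}

#' Simulate a diploid T0 plant sampled by two leaf punches
#'
#' Two read sets from different leaves of one plant. Zygosity structure:
#' `hom` - both punches fully edited with one shared indel allele;
#' `het` - both punches ~50% edited with one shared allele;
#' `chimeric` - punch edit fractions drawn independently from
#' Uniform(0.05, 0.95) with independently drawn (possibly distinct) indel
#' types; `wt` - unedited, error background only.
#'
#' @param site a [target_site()].
#' @param zygosity `"hom"`, `"het"`, `"chimeric"` or `"wt"`.
#' @param cfg a [sim_config()]; `depth` is per punch.
#' @return list of class `sim_plant`: `punches` (two `sim_reads`),
#'   `zygosity`, `fractions`, `types`.
#' @export
simulate_plant <- function(site, zygosity = c("hom", "het", "chimeric", "wt"),
                           cfg = sim_config()) {
  zygosity <- match.arg(zygosity)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  shared <- .draw_indels(2L, site, cfg$indel_spectrum)  # draws for allele(s)
  fr <- switch(zygosity,
               hom = c(1, 1), het = c(0.5, 0.5),
               chimeric = runif(2, 0.05, 0.95), wt = c(0, 0))
  types <- switch(zygosity,
                  hom = shared[c(1, 1), ], het = shared[c(1, 1), ],
                  chimeric = shared, wt = NULL)
  punches <- lapply(1:2, function(i) {
    pc <- cfg
    pc$seed <- seeds[i]
    pc$edit_fraction <- fr[i]
    pc$fixed_indel <- if (!is.null(types)) types[i, , drop = FALSE] else NULL
    simulate_amplicon_reads(site, pc)
  })
  structure(list(punches = punches, zygosity = zygosity, fractions = fr,
                 types = if (!is.null(types)) types$key else c(NA, NA),
                 seed = cfg$seed),
            class = "sim_plant")
}

#' Simulate a cohort of T0 plants
#'
#' @param site a [target_site()].
#' @param classes named integer vector of plant counts per zygosity class,
#'   e.g. `c(hom = 50, het = 50, chimeric = 50, wt = 50)`.
#' @param cfg a [sim_config()]; per-plant seeds are derived from its seed.
#' @return list of `sim_plant` objects with a `truth` attribute (the
#'   per-plant true zygosity labels).
#' @export
simulate_plant_cohort <- function(site, classes, cfg = sim_config()) {
  stopifnot(!is.null(names(classes)),
            all(names(classes) %in% c("hom", "het", "chimeric", "wt")))
  set.seed(cfg$seed)
  labels <- rep(names(classes), classes)
  seeds <- sample.int(.Machine$integer.max - 1L, length(labels))
  plants <- lapply(seq_along(labels), function(i) {
    pc <- cfg; pc$seed <- seeds[i]
    simulate_plant(site, labels[i], pc)
  })
  attr(plants, "truth") <- labels
  plants
}
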