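#' Tally cut-site indel types in one sample
#'
#' Runs the per-read stages of the on-target analysis: quality trimming,
#' semi-global alignment to the amplicon, indel extraction with
#' left-normalisation, and restriction to events intersecting the site's
#' cut-site window. Identical normalized events are grouped into types.
#' Identical read sequences are aligned once, so deep homogeneous samples
#' tally quickly.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (or a
#'   `sim_reads` object).
#' @param site a [target_site()].
#' @param quality_threshold Phred trim threshold (default 13).
#' @param min_read_length minimum post-trim read length (default 30).
#' @param params alignment scoring from [align_params()].
#' @return object of class `sample_tally`: per-type counts over window
#'   events, per-read type assignments, and read accounting
#'   (`total`, `trimmed_discarded`, `unaligned`, `aligned`).
#' @export
tally_sample <- function(reads, site, quality_threshold = 13L,
                         min_read_length = 30L, params = align_params()) {
  if (inherits(reads, "sim_reads")) reads <- reads$reads
  stopifnot(inherits(site, "target_site"))
  total <- nrow(reads)
  tr <- trim_reads(reads, quality_threshold, min_read_length)
  reads <- tr$reads

  # align unique sequences once
  useq <- unique(reads$seq)
  amp <- site$amplicon
  keys_by_useq <- vector("list", length(useq))
  aligned_u <- logical(length(useq))
  for (i in seq_along(useq)) {
    a <- align_read_cpp(useq[i], amp, params$match, params$mismatch,
                        params$gap_open, params$gap_ext)
    aligned_u[i] <- a$n_match / nchar(useq[i]) >= params$min_identity
    if (aligned_u[i] && grepl("[DI]", a$ops)) {
      a$read <- useq[i]
      ev <- extract_indels(a, amp)
      ev <- ev[.in_window(ev, site$window), , drop = FALSE]
      if (nrow(ev)) keys_by_useq[[i]] <- ev
    }
  }
  idx <- match(reads$seq, useq)
  read_aligned <- aligned_u[idx]
  n_unaligned <- sum(!read_aligned)
  n_aligned <- sum(read_aligned)

  # group identical normalized events into types
  mult <- tabulate(idx, nbins = length(useq))
  type_rows <- list(); type_counts <- integer(0)
  read_types <- vector("list", length(useq))   # per unique sequence
  for (i in seq_along(useq)) {
    ev <- keys_by_useq[[i]]
    if (is.null(ev) || !nrow(ev)) next
    read_types[[i]] <- ev$key
    for (k in seq_len(nrow(ev))) {
      key <- ev$key[k]
      if (is.na(match(key, names(type_counts)))) {
        type_counts[key] <- mult[i]
        type_rows[[key]] <- ev[k, c("kind", "start", "end", "inserted")]
      } else {
        type_counts[key] <- type_counts[key] + mult[i]
      }
    }
  }
  types <- if (length(type_counts)) {
    cbind(key = names(type_counts),
          do.call(rbind, type_rows[names(type_counts)]),
          count = as.integer(type_counts))
  } else {
    data.frame(key = character(0), kind = character(0), start = integer(0),
               end = integer(0), inserted = character(0), count = integer(0))
  }
  rownames(types) <- NULL

  structure(list(
    types = types,
    useq = useq, useq_mult = mult, useq_aligned = aligned_u,
    useq_types = read_types,
    total = total,
    trimmed_discarded = tr$n_discarded,
    unaligned = n_unaligned,
    aligned = n_aligned
  ), class = "sample_tally")
}

#' @export
print.sample_tally <- function(x, ...) {
  cat("sample tally: ", x$total, " reads (", x$aligned, " aligned, ",
      x$unaligned, " unaligned, ", x$trimmed_discarded, " discarded); ",
      nrow(x$types), " cut-site indel type(s)\n", sep = "")
  invisible(x)
}

#' Call edited reads in a sample against a negative control
#'
#' Implements the negative-control frequency filter: indel types within the
#' cut-site window are grouped and counted, and a type is retained only
#' when its per-read frequency in the sample is at least `multiplier` times
#' its frequency in the negative control (default 30). Control types never
#' observed receive a 0.5 pseudocount so novel sample types are comparable
#' against a finite background estimate. A read carrying at least one
#' retained type is a mutant read; an aligned read carrying none is
#' wild-type. Reported metrics are the mutant/wild-type ratio and the
#' mutant percentage of aligned reads.
#'
#' @param reads sample reads (data.frame `id`/`seq`/`qual` or `sim_reads`).
#' @param site a [target_site()].
#' @param control the negative control: reads, a `sim_reads`, or a
#'   pre-computed [tally_sample()] result (tally once, reuse across
#'   samples). Required; the filter is undefined without a control.
#' @param multiplier retention threshold (default 30; must be > 1).
#' @param sample_id label carried into the result.
#' @param ... passed to [tally_sample()] (trimming/alignment settings).
#' @return object of class `sample_callset`; see Details.
#' @details Fields: `types` (per-type counts and frequencies in sample and
#'   control with `retained` flags), `total_reads`, `trimmed_discarded`,
#'   `unaligned`, `mutant_reads`, `wildtype_reads`, `frequency_ratio`
#'   (mutant/wild-type; `Inf` and `saturated = TRUE` when wild-type is 0
#'   with mutants present), `frequency_pct` (mutant share of aligned reads,
#'   percent). Read counts are conserved:
#'   mutant + wildtype + discarded + unaligned = total.
#' @export
call_sample <- function(reads, site, control, multiplier = 30,
                        sample_id = "sample", ...) {
  if (missing(control) || is.null(control))
    stop("a negative control is required: the frequency filter is undefined without one")
  if (!is.numeric(multiplier) || multiplier <= 1)
    stop("multiplier must be > 1")
  tal <- if (inherits(reads, "sample_tally")) reads
         else tally_sample(reads, site, ...)
  ctl <- if (inherits(control, "sample_tally")) control
         else tally_sample(control, site, ...)
  if (ctl$aligned == 0L)
    stop("empty control: no aligned control reads")

  types <- tal$types
  ctl_counts <- setNames(ctl$types$count, ctl$types$key)
  cc <- ctl_counts[types$key]; cc[is.na(cc)] <- 0L
  freq_s <- types$count / tal$aligned
  freq_c <- ifelse(cc == 0, 0.5, cc) / ctl$aligned
  retained <- freq_s >= multiplier * freq_c
  types$control_count <- as.integer(cc)
  types$freq <- freq_s
  types$control_freq <- freq_c
  types$retained <- retained

  retained_keys <- types$key[retained]
  has_retained <- vapply(tal$useq_types, function(k)
    !is.null(k) && any(k %in% retained_keys), logical(1))
  mutant <- sum(tal$useq_mult[has_retained & tal$useq_aligned])
  wildtype <- tal$aligned - mutant

  saturated <- wildtype == 0L && mutant > 0L
  ratio <- if (mutant == 0L && wildtype == 0L) 0
           else if (saturated) Inf else mutant / wildtype
  pct <- if (mutant + wildtype == 0L) 0 else 100 * mutant / (mutant + wildtype)

  structure(list(
    sample_id = sample_id,
    site_id = site$amplicon_id,
    types = types,
    total_reads = tal$total,
    trimmed_discarded = tal$trimmed_discarded,
    unaligned = tal$unaligned,
    aligned_reads = tal$aligned,
    control_aligned = ctl$aligned,
    multiplier = multiplier,
    mutant_reads = mutant,
    wildtype_reads = wildtype,
    frequency_ratio = ratio,
    frequency_pct = pct,
    saturated = saturated
  ), class = "sample_callset")
}

#' @export
print.sample_callset <- function(x, ...) {
  cat("sample call set '", x$sample_id, "' (site ", x$site_id, ")\n", sep = "")
  cat(sprintf("  reads: %d total = %d mutant + %d wild-type + %d discarded + %d unaligned\n",
              x$total_reads, x$mutant_reads, x$wildtype_reads,
              x$trimmed_discarded, x$unaligned))
  cat(sprintf("  indel frequency: %.4g%% of aligned reads (mutant/wild-type ratio %.4g%s)\n",
              x$frequency_pct, x$frequency_ratio,
              if (x$saturated) ", saturated" else ""))
  cat(sprintf("  indel types: %d observed in window, %d retained at the %gx control filter\n",
              nrow(x$types), sum(x$types$retained), x$multiplier))
  invisible(x)
}

#' @export
summary.sample_callset <- function(object, ...) {
  print(object)
  if (nrow(object$types)) {
    t <- object$types[order(-object$types$count), ]
    t$position <- paste0(t$start + 1L, "-", t$end)  # 1-based closed in reports
    print(utils::head(t[, c("key", "kind", "position", "inserted", "count",
                            "control_count", "retained")], 10), row.names = FALSE)
  }
  invisible(object)
}

#' Write a per-sample indel-type table
#'
#' One row per observed cut-site indel type with 1-based closed reference
#' coordinates, counts and frequencies in sample and control, and the
#' retention flag.
#'
#' @param callset a [call_sample()] result.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_callset_tsv <- function(callset, path) {
  t <- callset$types
  out <- data.frame(
    sample = callset$sample_id,
    type = t$key, kind = t$kind,
    start = t$start + 1L, end = ifelse(t$kind == "deletion", t$end, t$start),
    inserted = t$inserted, count = t$count,
    sample_freq = signif(t$freq, 6), control_freq = signif(t$control_freq, 6),
    retained = t$retained)
  out <- out[order(-out$count, out$start), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
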