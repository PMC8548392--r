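#' Zygosity classification bands
#'
#' Mutant-read-fraction bands quantifying the diploid expectations: ~100%
#' mutant reads for a homozygous edit and ~50% for a heterozygous one. The
#' defaults allow +/-15% slack for sampling noise and residual somatic
#' chimerism.
#'
#' @param hom_min lower bound of the homozygous band (default 0.85).
#' @param het_min,het_max heterozygous band (default 0.35-0.65).
#' @param wt_max upper bound of the wild-type band (default 0.05).
#' @return list of band edges.
#' @export
zygosity_bands <- function(hom_min = 0.85, het_min = 0.35, het_max = 0.65,
                           wt_max = 0.05) {
  stopifnot(wt_max < het_min, het_min < het_max, het_max < hom_min)
  list(hom_min = hom_min, het_min = het_min, het_max = het_max,
       wt_max = wt_max)
}

#' Classify the zygosity of a T0 plant from two leaf punches
#'
#' Two leaf punches from different leaves distinguish germline from
#' somatic (chimeric) edits: a genuine heterozygous or homozygous plant
#' shows concordant mutant-read fractions *and* the same dominant indel
#' allele in both punches. Homozygous: both fractions at or above the
#' homozygous band with identical top indel type; heterozygous: both
#' inside the ~50% band with identical top type; wild-type: both at
#' background; anything else (including discordant punches) is chimeric.
#'
#' @param punch_a,punch_b [call_sample()] results for the two punches.
#' @param bands from [zygosity_bands()].
#' @param min_reads minimum aligned mutant+wild-type reads per punch
#'   (default 100); below it the plant is reported
#'   `"insufficient_coverage"` and excluded from cohort proportions.
#' @param plant_id plant label.
#' @return object of class `plant_call`: `call` (one of `"homozygous"`,
#'   `"heterozygous"`, `"chimeric"`, `"wild_type"`,
#'   `"insufficient_coverage"`), `punch_fractions`, `punch_top_types`,
#'   `punch_top_counts`.
#' @export
classify_plant <- function(punch_a, punch_b, bands = zygosity_bands(),
                           min_reads = 100L, plant_id = "plant") {
  stopifnot(inherits(punch_a, "sample_callset"),
            inherits(punch_b, "sample_callset"))
  punches <- list(punch_a, punch_b)
  cov <- vapply(punches, function(p) p$mutant_reads + p$wildtype_reads,
                numeric(1))
  fr <- vapply(punches, function(p)
    if (p$mutant_reads + p$wildtype_reads == 0) 0
    else p$mutant_reads / (p$mutant_reads + p$wildtype_reads), numeric(1))
  top <- lapply(punches, function(p) {
    t <- p$types[p$types$retained, , drop = FALSE]
    if (!nrow(t)) return(list(key = NA_character_, count = 0L))
    t <- t[order(-t$count, t$start), ]
    list(key = t$key[1], count = t$count[1])
  })
  top_keys <- vapply(top, `[[`, character(1), "key")
  same_top <- !any(is.na(top_keys)) && top_keys[1] == top_keys[2]

  call <- if (any(cov < min_reads)) "insufficient_coverage"
    else if (all(fr >= bands$hom_min) && same_top) "homozygous"
    else if (all(fr >= bands$het_min & fr <= bands$het_max) && same_top)
      "heterozygous"
    else if (all(fr <= bands$wt_max)) "wild_type"
    else "chimeric"

  structure(list(plant_id = plant_id, call = call,
                 punch_fractions = fr, punch_top_types = top_keys,
                 punch_top_counts = vapply(top, `[[`, integer(1), "count"),
                 punch_coverage = cov, bands = bands),
            class = "plant_call")
}

#' @export
print.plant_call <- function(x, ...) {
  cat(sprintf("plant '%s': %s (punch fractions %.2f / %.2f, top types %s / %s)\n",
              x$plant_id, x$call, x$punch_fractions[1], x$punch_fractions[2],
              x$punch_top_types[1], x$punch_top_types[2]))
  invisible(x)
}

#' Summarize a cohort of classified T0 plants
#'
#' Edited plants are those classified heterozygous or homozygous (the
#' plants predicted to carry a heritable edit). The edited percentage is
#' taken over plants with sufficient coverage; zygosity proportions are
#' taken over edited plants. The top-indel table aggregates the shared
#' dominant allele of each edited plant, sorted by plant count then
#' leftmost coordinate.
#'
#' @param calls list of [classify_plant()] results.
#' @param k number of indel types kept in the top table (default 10).
#' @return object of class `cohort_summary`.
#' @export
summarize_cohort <- function(calls, k = 10L) {
  stopifnot(length(calls) >= 1L,
            all(vapply(calls, inherits, logical(1), "plant_call")))
  call_vec <- vapply(calls, `[[`, character(1), "call")
  called <- call_vec[call_vec != "insufficient_coverage"]
  counts <- c(table(factor(called, levels = c("homozygous", "heterozygous",
                                              "chimeric", "wild_type"))))
  n_called <- length(called)
  n_edited <- sum(counts[c("homozygous", "heterozygous")])
  pct_edited <- if (n_called) 100 * n_edited / n_called else 0
  props <- if (n_edited)
    counts[c("homozygous", "heterozygous")] / n_edited else
    setNames(numeric(0), character(0))   # undefined without edited plants

  edited <- calls[call_vec %in% c("homozygous", "heterozygous")]
  top <- if (length(edited)) {
    keys <- vapply(edited, function(p) p$punch_top_types[1], character(1))
    cnts <- vapply(edited, function(p) sum(p$punch_top_counts), numeric(1))
    agg <- aggregate(list(n_plants = rep(1L, length(keys)),
                          read_count = cnts),
                     by = list(key = keys), FUN = sum)
    start <- suppressWarnings(as.integer(sub("^[DI]:(\\d+).*$", "\\1",
                                             agg$key)))
    agg <- agg[order(-agg$n_plants, start), ]
    utils::head(agg, k)
  } else data.frame(key = character(0), n_plants = integer(0),
                    read_count = numeric(0))

  structure(list(n_plants = length(calls), n_called = n_called,
                 n_insufficient = length(calls) - n_called,
                 counts = counts, n_edited = n_edited,
                 pct_edited = pct_edited, zygosity_proportions = props,
                 top_indels = top),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("T0 cohort: ", x$n_plants, " plants (", x$n_called, " called",
      if (x$n_insufficient) paste0(", ", x$n_insufficient,
                                   " insufficient coverage"), ")\n", sep = "")
  cat(sprintf("  edited (het+hom): %d (%.1f%%)\n", x$n_edited, x$pct_edited))
  print(x$counts)
  if (x$n_edited) {
    cat("  zygosity proportions over edited plants:\n")
    print(round(x$zygosity_proportions, 3))
  }
  if (nrow(x$top_indels)) {
    cat("  top indel alleles:\n")
    print(x$top_indels, row.names = FALSE)
  }
  invisible(x)
}
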