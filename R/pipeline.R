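#' Run the editing-analysis pipeline from a config
#'
#' Orchestrates the stages in dependency order: `simulate` (amplicon
#' samples and negative control), `call` (per-sample indel calling against
#' the control), `plants` (cohort simulation + zygosity classification),
#' `offtargets` (genome planting + enumeration + screening), and `report`.
#' Writes stage outputs (TSV/JSON/FASTQ/FASTA) plus a machine-readable run
#' manifest listing inputs, seeds, thresholds and output checksums.
#' Re-running with the same config reproduces the outputs byte for byte.
#'
#' @param config path to a YAML config, or an equivalent named list. Keys:
#'   `seed`, `outdir`, `site` (see [read_site_config()]; or inline
#'   `amplicon`/`spacer`/`pam`), and optional stage blocks `simulate`,
#'   `call`, `plants`, `offtargets`.
#' @param outdir overrides the config output directory.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .validate_run_config(cfg)
  if (is.null(outdir)) outdir <- if (!is.null(cfg$outdir)) cfg$outdir else "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L

  site <- if (!is.null(cfg$site$amplicon)) {
    target_site(cfg$site$amplicon, cfg$site$spacer, cfg$site$pam,
                amplicon_id = if (!is.null(cfg$site$amplicon_id))
                  cfg$site$amplicon_id else "amplicon",
                cut_offset = if (!is.null(cfg$site$cut_offset))
                  cfg$site$cut_offset else 23L)
  } else if (is.character(config)) {
    read_site_config(config)
  } else stop("config must declare a site (inline amplicon or FASTA)")

  results <- list(site = site)
  thresholds <- list(
    quality_threshold = .cfg_get(cfg, c("call", "quality_threshold"), 13L),
    multiplier = .cfg_get(cfg, c("call", "multiplier"), 30),
    min_read_length = .cfg_get(cfg, c("call", "min_read_length"), 30L),
    cut_offset = site$cut_offset,
    window_width = site$window[2] - site$window[1],
    min_spacer_length = 16L,
    offtarget_max_mm = .cfg_get(cfg, c("offtargets", "max_mm"), 4L),
    offtarget_max_bulges = .cfg_get(cfg, c("offtargets", "max_bulges"), 2L),
    screen_min_reads = .cfg_get(cfg, c("offtargets", "min_reads"), 5L),
    screen_mutant_fraction = .cfg_get(cfg, c("offtargets", "frac"), 0.20))

  .stage_log("simulate")
  control <- NULL
  if (!is.null(cfg$simulate)) {
    sc <- sim_config(seed = seed,
                     depth = .cfg_get(cfg, c("simulate", "depth"), 5000L),
                     edit_fraction = .cfg_get(cfg, c("simulate",
                                                     "edit_fraction"), 0.1))
    sample_reads <- simulate_amplicon_reads(site, sc)
    ctl_cfg <- sc; ctl_cfg$seed <- seed + 1L
    # a deep pooled control: detecting singleton indel types under the
    # multiplier filter needs control depth > multiplier/2 x sample depth
    ctl_cfg$depth <- .cfg_get(cfg, c("simulate", "control_depth"),
                              20L * sc$depth)
    control <- simulate_negative_control(site, ctl_cfg)
    write_fastq(sample_reads, file.path(outdir, "sample.fastq"))
    write_fastq(control, file.path(outdir, "control.fastq"))
    write_truth_manifest(sample_reads$truth,
                         file.path(outdir, "sample.truth.tsv"))
    results$simulate <- sample_reads

    .stage_log("call")
    cs <- call_sample(sample_reads$reads, site, control$reads,
                      multiplier = thresholds$multiplier,
                      sample_id = "sample",
                      quality_threshold = thresholds$quality_threshold,
                      min_read_length = thresholds$min_read_length)
    write_callset_tsv(cs, file.path(outdir, "sample.indels.tsv"))
    .write_json(.callset_summary(cs), file.path(outdir, "sample.summary.json"))
    results$callset <- cs
  }

  if (!is.null(cfg$plants)) {
    .stage_log("plants")
    classes <- unlist(.cfg_get(cfg, c("plants", "classes"),
                               c(hom = 3L, het = 3L, chimeric = 3L, wt = 3L)))
    pcfg <- sim_config(seed = seed + 2L,
                       depth = .cfg_get(cfg, c("plants", "depth"), 1000L))
    cohort <- simulate_plant_cohort(site, classes, pcfg)
    ctl_p <- simulate_negative_control(
      site, sim_config(seed = seed + 3L,
                       depth = .cfg_get(cfg, c("plants", "control_depth"),
                                        20000L)))
    ctl_tally <- tally_sample(ctl_p$reads, site,
                              thresholds$quality_threshold,
                              thresholds$min_read_length)
    calls <- lapply(seq_along(cohort), function(i) {
      p <- cohort[[i]]
      cs <- lapply(p$punches, function(pu)
        call_sample(pu$reads, site, ctl_tally,
                    multiplier = thresholds$multiplier,
                    quality_threshold = thresholds$quality_threshold,
                    min_read_length = thresholds$min_read_length))
      classify_plant(cs[[1]], cs[[2]], plant_id = sprintf("plant_%03d", i))
    })
    summ <- summarize_cohort(calls)
    per_plant <- data.frame(
      plant = vapply(calls, `[[`, character(1), "plant_id"),
      call = vapply(calls, `[[`, character(1), "call"),
      frac_a = vapply(calls, function(x) x$punch_fractions[1], numeric(1)),
      frac_b = vapply(calls, function(x) x$punch_fractions[2], numeric(1)),
      top_a = vapply(calls, function(x) x$punch_top_types[1], character(1)),
      top_b = vapply(calls, function(x) x$punch_top_types[2], character(1)),
      truth = attr(cohort, "truth"))
    write.table(per_plant, file.path(outdir, "plants.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .write_json(list(n_plants = summ$n_plants, n_edited = summ$n_edited,
                     pct_edited = summ$pct_edited,
                     counts = as.list(summ$counts)),
                file.path(outdir, "cohort.json"))
    results$plant_calls <- calls
    results$cohort <- summ
  }

  if (!is.null(cfg$offtargets)) {
    .stage_log("offtargets")
    gspec <- .cfg_get(cfg, c("offtargets", "spec"),
                      list(c(0, 0), c(2, 0), c(2, 1)))
    gl <- .cfg_get(cfg, c("offtargets", "genome_length"), 20000L)
    sg <- plant_offtargets(gl, site$spacer, site$pam, gspec,
                           seed = seed + 4L,
                           scan_max_mm = thresholds$offtarget_max_mm,
                           scan_max_bulges = thresholds$offtarget_max_bulges)
    write_fasta(sg$genome, file.path(outdir, "genome.fasta"))
    write_truth_manifest(sg$truth, file.path(outdir, "genome.truth.tsv"))
    cand <- enumerate_offtargets(sg$genome, site$spacer, site$pam,
                                 thresholds$offtarget_max_mm,
                                 thresholds$offtarget_max_bulges)
    write_offtarget_bed(cand, file.path(outdir, "offtargets.bed"))
    results$offtargets <- cand
    results$offtarget_truth <- sg$truth
  }

  .stage_log("report")
  report <- render_report(results)
  writeLines(report, file.path(outdir, "report.txt"))

  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "cas12fkit",
    version = as.character(utils::packageVersion("cas12fkit")),
    seed = seed,
    site = list(amplicon_id = site$amplicon_id, spacer = site$spacer,
                pam = unclass(site$pam), strand = site$strand,
                cut_center = site$cut_center, window = site$window),
    thresholds = thresholds,
    outputs = as.list(tools::md5sum(sort(outputs))))
  .write_json(manifest, file.path(outdir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

.cfg_get <- function(cfg, keys, default) {
  x <- cfg
  for (k in keys) {
    if (is.null(x[[k]])) return(default)
    x <- x[[k]]
  }
  x
}

.validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")
  m <- .cfg_get(cfg, c("call", "multiplier"), 30)
  if (!is.numeric(m) || m <= 1)
    stop("invalid config: call.multiplier must be > 1")
  for (key in c("depth", "edit_fraction")) {
    v <- .cfg_get(cfg, c("simulate", key), 1)
    if (!is.numeric(v) || v < 0)
      stop("invalid config: simulate.", key, " must be non-negative")
  }
  invisible(TRUE)
}

.stage_log <- function(stage) {
  message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), stage))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.callset_summary <- function(cs) {
  list(sample = cs$sample_id, site = cs$site_id,
       total_reads = cs$total_reads, mutant_reads = cs$mutant_reads,
       wildtype_reads = cs$wildtype_reads,
       trimmed_discarded = cs$trimmed_discarded, unaligned = cs$unaligned,
       frequency_ratio = cs$frequency_ratio,
       frequency_pct = cs$frequency_pct,
       n_types = nrow(cs$types), n_retained = sum(cs$types$retained),
       saturated = cs$saturated)
}

#' Render a text report of the analysis
#'
#' Per-site frequency table, cohort zygosity counts, and an alignment of
#' the most abundant indel alleles against the wild-type reference with
#' the PAM, protospacer and expected cut site annotated; deletions render
#' as dashes across the deleted span.
#'
#' @param results list as assembled by [run_pipeline()]; any of `callset`,
#'   `cohort`, `offtargets` may be present alongside `site`.
#' @param k alleles shown in the alignment (default 10).
#' @return character vector of report lines.
#' @export
render_report <- function(results, k = 10L) {
  site <- results$site
  lines <- c("Cas12f1 editing-outcome report",
             strrep("=", 30), "")
  if (!is.null(site)) {
    lines <- c(lines, utils::capture.output(print(site)), "")
  }
  if (!is.null(results$callset)) {
    cs <- results$callset
    lines <- c(lines, utils::capture.output(print(cs)), "")
    lines <- c(lines, render_indel_alignment(site, cs$types, k), "")
  }
  if (!is.null(results$cohort)) {
    lines <- c(lines, utils::capture.output(print(results$cohort)), "")
  }
  if (!is.null(results$offtargets)) {
    ot <- results$offtargets
    lines <- c(lines, sprintf("off-target candidates: %d", nrow(ot)))
    if (nrow(ot)) {
      lines <- c(lines, utils::capture.output(print(
        as.data.frame(ot)[, c("chrom", "start", "end", "strand",
                              "n_mismatches", "n_bulges", "pam_seq")])))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Render the top indel alleles aligned to the reference
#'
#' @param site a [target_site()].
#' @param types a callset `types` data.frame (columns `kind`, `start`,
#'   `end`, `inserted`, `count`, `retained`).
#' @param k number of alleles shown (default 10).
#' @param retained_only show only filter-retained alleles (default TRUE).
#' @return character vector of alignment lines.
#' @export
render_indel_alignment <- function(site, types, k = 10L,
                                   retained_only = TRUE) {
  if (retained_only) types <- types[types$retained, , drop = FALSE]
  if (!nrow(types))
    return("no retained indel alleles")
  types <- types[order(-types$count, types$start), , drop = FALSE]
  types <- utils::head(types, k)
  amp <- site$amplicon
  lo <- max(0L, min(site$window[1], min(types$start)) - 10L)
  hi <- min(nchar(amp), max(site$window[2], max(types$end)) + 10L)
  ref <- substr(amp, lo + 1L, hi)
  width <- hi - lo
  ann <- rep(" ", width)
  pr <- (site$protospacer_interval[1]:(site$protospacer_interval[2] - 1L))
  pr <- pr[pr >= lo & pr < hi]
  ann[pr - lo + 1L] <- "p"
  pm <- (site$pam_interval[1]:(site$pam_interval[2] - 1L))
  pm <- pm[pm >= lo & pm < hi]
  ann[pm - lo + 1L] <- "P"
  wn <- site$window[1]:(site$window[2] - 1L)
  wn <- wn[wn >= lo & wn < hi]
  ann[wn - lo + 1L] <- ifelse(ann[wn - lo + 1L] == "p", "x", "w")
  lines <- c(sprintf("%-20s %s", "annotation", paste0(ann, collapse = "")),
             sprintf("%-20s %s  (reference)", "wild-type", ref),
             "  [P]AM  [p]rotospacer  [w]indow  [x] both")
  for (i in seq_len(nrow(types))) {
    t <- types[i, ]
    if (t$kind == "deletion") {
      row <- paste0(substr(amp, lo + 1L, t$start),
                    strrep("-", t$end - t$start),
                    substr(amp, t$end + 1L, hi))
      label <- sprintf("del %d bp @%d", t$end - t$start, t$start + 1L)
    } else {
      row <- paste0(substr(amp, lo + 1L, t$start),
                    tolower(t$inserted),
                    substr(amp, t$start + 1L, hi))
      label <- sprintf("ins %d bp @%d", nchar(t$inserted), t$start + 1L)
    }
    lines <- c(lines, sprintf("%-20s %s  (n=%d)", label, row, t$count))
  }
  lines
}
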