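test_that("read simulation is bit-reproducible under a fixed seed", {
  site <- make_test_site()
  cfg <- sim_config(seed = 11, depth = 300, edit_fraction = 0.3)
  s1 <- simulate_amplicon_reads(site, cfg)
  s2 <- simulate_amplicon_reads(site, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  p1 <- simulate_plant(site, "het", cfg)
  p2 <- simulate_plant(site, "het", cfg)
  expect_identical(p1$punches[[1]]$reads, p2$punches[[1]]$reads)
})

test_that("no edits and no error indels means no indels at all", {
  site <- make_test_site()
  cfg <- sim_config(seed = 3, depth = 500, edit_fraction = 0,
                    error_indel_rate = 0)
  s <- simulate_amplicon_reads(site, cfg)
  expect_false(any(s$truth$edited))
  expect_true(all(nchar(s$reads$seq) == nchar(site$amplicon)))
})

test_that("edited-read counts follow the binomial and events hit the window", {
  site <- make_test_site()
  cfg <- sim_config(seed = 21, depth = 2000, edit_fraction = 0.5)
  s <- simulate_amplicon_reads(site, cfg)
  ne <- sum(s$truth$edited)
  expect_lt(abs(ne - 1000), 3 * sqrt(2000 * 0.25))
  tr <- s$truth[s$truth$edited, ]
  dels <- tr[tr$kind == "deletion", ]
  expect_true(all(dels$start < site$window[2] & dels$end > site$window[1]))
  ins <- tr[tr$kind == "insertion", ]
  expect_true(all(ins$start >= site$window[1] & ins$start <= site$window[2]))
})

test_that("negative controls carry only sequencing error", {
  site <- make_test_site()
  cfg <- sim_config(seed = 9, depth = 5000)
  ctl <- simulate_negative_control(site, cfg)
  expect_false(any(ctl$truth$edited))
  # reads whose length changed carry an error indel; their rate matches
  # the configured per-base rate within 3 SE (1-bp indels shift length)
  L <- nchar(site$amplicon)
  p_ind <- 1 - (1 - cfg$error_indel_rate)^L
  n_shift <- sum(nchar(ctl$reads$seq) != L)
  expect_lt(abs(n_shift - 5000 * p_ind), 3 * sqrt(5000 * p_ind) + 3)
  # and its FASTQ output is valid 4-line Phred+33
  f <- tempfile(fileext = ".fastq")
  write_fastq(ctl, f)
  lines <- readLines(f)
  expect_equal(length(lines), 4 * 5000)
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
  back <- read_fastq(f)
  expect_identical(back$seq, ctl$reads$seq)
  expect_identical(back$qual, ctl$reads$qual)
})

test_that("plant zygosity structure drives punch edit fractions", {
  site <- make_test_site()
  # homozygous, error-free: both punches 100% edited with one shared allele
  p <- simulate_plant(site, "hom",
                      sim_config(seed = 5, depth = 200,
                                 substitution_error_rate = 0,
                                 error_indel_rate = 0))
  expect_true(all(p$punches[[1]]$truth$edited))
  expect_true(all(p$punches[[2]]$truth$edited))
  expect_equal(p$types[1], p$types[2])
  expect_equal(length(unique(stats::na.omit(p$punches[[1]]$truth$key))), 1)

  # heterozygous: each punch within 3 binomial SE of 50%
  ph <- simulate_plant(site, "het", sim_config(seed = 6, depth = 1000))
  for (pu in ph$punches) {
    ne <- sum(pu$truth$edited)
    expect_lt(abs(ne - 500), 3 * sqrt(1000 * 0.25))
  }

  # wild type: mutant truth zero; error indels bounded (Poisson tail)
  pw <- simulate_plant(site, "wt", sim_config(seed = 7, depth = 1000))
  for (pu in pw$punches) {
    expect_false(any(pu$truth$edited))
    lam <- 1000 * 1e-4 * nchar(site$amplicon)
    expect_lt(sum(nchar(pu$reads$seq) != nchar(site$amplicon)),
              10 * lam)
  }

  # chimeric punches live in (0.05, 0.95)
  pc <- simulate_plant(site, "chimeric", sim_config(seed = 8, depth = 500))
  expect_true(all(pc$fractions > 0.05 & pc$fractions < 0.95))
})

test_that("truth manifests round-trip losslessly through TSV", {
  site <- make_test_site()
  s <- simulate_amplicon_reads(site, sim_config(seed = 2, depth = 100,
                                                edit_fraction = 0.4))
  f <- tempfile(fileext = ".tsv")
  write_truth_manifest(s$truth, f)
  back <- read_truth_manifest(f)
  expect_equal(back, s$truth)
})

test_that("planted off-target genomes realize their specifications", {
  spacer <- "GCTGACGTATGCAATGCTAC"
  # (0,0): the exact protospacer+PAM occurs exactly once
  sg0 <- plant_offtargets(4000, spacer, "TTC",
                          data.frame(n_mismatches = 0, n_bulges = 0,
                                     strand = "+", bulge_kind = "mixed"),
                          seed = 12)
  hits <- gregexpr(paste0("TTC", spacer), sg0$genome[[1]], fixed = TRUE)[[1]]
  expect_equal(length(hits), 1)
  expect_equal(as.integer(hits[1]) - 1L, sg0$truth$pam_start)

  # (2,1): the exhaustive-DP oracle finds exactly one such site
  sg21 <- plant_offtargets(4000, spacer, "TTC", list(c(2, 1)), seed = 13)
  o <- oracle_offtargets(sg21$genome[[1]], spacer, "TTC", 4, 2)
  expect_equal(nrow(o), 1)
  expect_equal(o$n_mismatches, 2)
  expect_equal(o$n_bulges, 1)
  expect_equal(o$start, sg21$truth$start)

  # infeasible specifications error out
  expect_error(plant_offtargets(4000, spacer, "TTC", list(c(0, 25))),
               "infeasible")
  expect_error(plant_offtargets(200, spacer, "TTC",
                                list(c(0, 0), c(1, 0))), "fit")
})

test_that("planting is strand-symmetric under reverse complement", {
  spacer <- "GCTGACGTATGCAATGCTAC"
  sg <- plant_offtargets(4000, spacer, "TTC", list(c(1, 0)), seed = 14)
  g <- sg$genome[[1]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  cand_fwd <- enumerate_offtargets(g, spacer, "TTC", 4, 2)
  cand_rc <- enumerate_offtargets(rc, spacer, "TTC", 4, 2)
  expect_equal(nrow(cand_fwd), nrow(cand_rc))
  n <- nchar(g)
  expect_setequal(paste(n - cand_rc$end, n - cand_rc$start,
                        ifelse(cand_rc$strand == "+", "-", "+")),
                  paste(cand_fwd$start, cand_fwd$end, cand_fwd$strand))
})
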