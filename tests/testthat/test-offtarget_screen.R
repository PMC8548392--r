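SPACER <- "GCTGACGTATGCAATGCTAC"

test_that("exact protospacers are found and bad PAMs are gated out", {
  set.seed(81)
  flank1 <- random_dna(500); flank2 <- random_dna(500)
  genome <- paste0(flank1, "TTC", SPACER, flank2, "GAG", SPACER,
                   random_dna(300))
  cand <- enumerate_offtargets(genome, SPACER, "TTC", 2, 1)
  hit <- cand[cand$n_mismatches == 0 & cand$n_bulges == 0, ]
  expect_equal(nrow(hit), 1)            # the GAG-preceded copy is invisible
  expect_equal(hit$start, 503)
  expect_equal(hit$pam_seq, "TTC")
  expect_equal(hit$protospacer, SPACER)
  # expected cut window measured on the genome from the PAM end
  expect_equal(hit$cut_center, 503 + 23)
  expect_error(enumerate_offtargets(genome, strrep("A", 15), "TTC"), "16")
  empty <- enumerate_offtargets("", SPACER, "TTC")
  expect_equal(nrow(empty), 0)
})

test_that("enumeration equals the exhaustive full-DP oracle on planted genomes", {
  spec <- list(c(0, 0), c(1, 0), c(2, 0), c(1, 1), c(2, 1), c(0, 2),
               c(3, 0), c(3, 2))
  sg <- plant_offtargets(12000, SPACER, "TTC", spec, seed = 91,
                         scan_max_mm = 3, scan_max_bulges = 2)
  cand <- enumerate_offtargets(sg$genome, SPACER, "TTC", 3, 2)
  orc <- oracle_offtargets(sg$genome[[1]], SPACER, "TTC", 3, 2)
  expect_equal(nrow(cand), nrow(orc))
  expect_setequal(paste(cand$start, cand$end, cand$strand,
                        cand$n_mismatches, cand$n_bulges),
                  paste(orc$start, orc$end, orc$strand,
                        orc$n_mismatches, orc$n_bulges))
  # every planted site recovered with its exact composition
  expect_setequal(paste(sg$truth$start, sg$truth$end, sg$truth$strand,
                        sg$truth$n_mismatches, sg$truth$n_bulges),
                  paste(cand$start, cand$end, cand$strand,
                        cand$n_mismatches, cand$n_bulges))
})

test_that("alignment strings reconstruct the genomic slice", {
  sg <- plant_offtargets(8000, SPACER, "TTC",
                         list(c(2, 1), c(1, 2), c(0, 0)), seed = 92)
  cand <- enumerate_offtargets(sg$genome, SPACER, "TTC", 4, 2)
  for (i in seq_len(nrow(cand))) {
    expect_identical(gsub("-", "", cand$genome_aln[i]), cand$protospacer[i])
    expect_identical(gsub("-", "", cand$guide_aln[i]), SPACER)
    aln_mm <- sum(strsplit(cand$guide_aln[i], "")[[1]] !=
                    strsplit(cand$genome_aln[i], "")[[1]]) -
      (cand$n_dna_bulges[i] + cand$n_rna_bulges[i])
    expect_equal(aln_mm, cand$n_mismatches[i])
    expect_equal(cand$n_dna_bulges[i] + cand$n_rna_bulges[i],
                 cand$n_bulges[i])
  }
})

test_that("enumeration is monotone in the mismatch and bulge limits", {
  sg <- plant_offtargets(10000, SPACER, "TTC",
                         list(c(0, 0), c(2, 0), c(2, 1), c(1, 2)), seed = 93)
  key <- function(x) paste(x$start, x$end, x$strand)
  k21 <- key(enumerate_offtargets(sg$genome, SPACER, "TTC", 2, 1))
  k41 <- key(enumerate_offtargets(sg$genome, SPACER, "TTC", 4, 1))
  k42 <- key(enumerate_offtargets(sg$genome, SPACER, "TTC", 4, 2))
  expect_true(all(k21 %in% k41))
  expect_true(all(k41 %in% k42))
})

test_that("screening applies the five-read, 20% and clean-control rules", {
  sg <- plant_offtargets(9000, SPACER, "TTC", list(c(0, 0), c(2, 1)),
                         seed = 94)
  cand <- enumerate_offtargets(sg$genome, SPACER, "TTC", 4, 2)
  loc <- candidate_locus(sg$genome, cand[1, ])
  clean <- simulate_locus_reads(loc$seq, loc$window, 80, 0, seed = 1)
  ctl <- simulate_locus_reads(loc$seq, loc$window, 80, 0, seed = 2)
  mut25 <- simulate_locus_reads(loc$seq, loc$window, 80, 0.25, seed = 3)

  expect_equal(screen_candidate(loc$seq, loc$window, clean, ctl)$verdict,
               "clean")
  expect_equal(screen_candidate(loc$seq, loc$window, mut25, ctl)$verdict,
               "putative_edit")
  # below five uniquely mapped reads: insufficient, never flagged
  expect_equal(screen_candidate(loc$seq, loc$window, mut25[1:4, ],
                                ctl)$verdict, "insufficient_coverage")
  # exactly 20% is not >20%
  mut20 <- simulate_locus_reads(loc$seq, loc$window, 100, 0, seed = 4)
  mutread <- simulate_locus_reads(loc$seq, loc$window, 100, 1, seed = 5)
  at20 <- rbind(mutread[1:20, ], mut20[1:80, ])
  expect_equal(screen_candidate(loc$seq, loc$window, at20, ctl)$verdict,
               "clean")
  # a dirty control suppresses the call
  expect_equal(screen_candidate(loc$seq, loc$window, mut25, mut25)$verdict,
               "clean")
})

test_that("screening across candidates flags exactly the edited locus", {
  sg <- plant_offtargets(12000, SPACER, "TTC",
                         list(c(0, 0), c(1, 1), c(2, 0), c(2, 2)), seed = 95)
  cand <- enumerate_offtargets(sg$genome, SPACER, "TTC", 4, 2)
  expect_equal(nrow(cand), 4)
  edited_idx <- 2L
  verdicts <- vapply(seq_len(nrow(cand)), function(i) {
    loc <- candidate_locus(sg$genome, cand[i, ])
    # exactly 25% mutant reads at the edited locus, 0% elsewhere
    clean <- simulate_locus_reads(loc$seq, loc$window, 150, 0,
                                  seed = 100 + i)
    rd <- if (i == edited_idx)
      rbind(simulate_locus_reads(loc$seq, loc$window, 50, 1, seed = 50 + i),
            clean)
    else clean
    ctl <- simulate_locus_reads(loc$seq, loc$window, 200, 0, seed = 200 + i)
    screen_candidate(loc$seq, loc$window, rd, ctl)$verdict
  }, character(1))
  expect_equal(which(verdicts == "putative_edit"), edited_idx)
  expect_true(all(verdicts[-edited_idx] == "clean"))
})

test_that("ambiguously mapping reads fail the uniqueness margin", {
  sg <- plant_offtargets(9000, SPACER, "TTC", list(c(0, 0)), seed = 96)
  cand <- enumerate_offtargets(sg$genome, SPACER, "TTC", 4, 2)
  loc <- candidate_locus(sg$genome, cand[1, ])
  rd <- simulate_locus_reads(loc$seq, loc$window, 30, 0, seed = 6,
                             substitution_error_rate = 0)
  # a competing locus identical to the focal one: no read is unique
  v <- screen_candidate(loc$seq, loc$window, rd, rd,
                        competing_loci = loc$seq)
  expect_equal(v$verdict, "insufficient_coverage")
  expect_equal(v$n_unique_reads, 0)
})
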