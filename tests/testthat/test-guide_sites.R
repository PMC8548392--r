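test_that("match_pam agrees with set-membership over the full IUPAC table", {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T", "N"))
  for (sym in names(iupac))
    for (base in c("A", "C", "G", "T", "N"))
      expect_identical(match_pam(base, sym), base %in% iupac[[sym]],
                       info = paste(base, "vs", sym))
})

test_that("match_pam handles the Cas12f1 PAMs and rejects bad input", {
  expect_true(match_pam("TTC", "TTC"))
  expect_true(match_pam("CTTA", "YTTN"))
  expect_true(match_pam("TTTG", "YTTN"))
  expect_false(match_pam("TTA", "TTC"))
  expect_false(match_pam("GTTA", "YTTN"))
  expect_error(match_pam("TT", "TTC"), "length")
  expect_error(match_pam("TTX", "TTC"), "nucleotide")
  expect_error(pam_pattern("T1C"), "IUPAC")
})

test_that("expected cut window follows the 22-24 bp downstream geometry", {
  w <- expected_cut_window(13, "+", offset = 23)
  expect_equal(w$cut_center, 36)
  expect_equal(w$window, c(30, 42))
  expect_equal(expected_cut_window(13, "+", offset = 22)$cut_center, 35)
  expect_equal(expected_cut_window(13, "+", offset = 24)$cut_center, 37)
  expect_equal(expected_cut_window(13, "+", offset = 24)$window, c(31, 43))
  # minus strand mirrors toward decreasing coordinates
  expect_equal(expected_cut_window(50, "-", offset = 23)$cut_center, 27)
  expect_error(expected_cut_window(13, "+", offset = 25), "22")
  expect_error(expected_cut_window(13, "+", width = 11), "even")
  expect_error(expected_cut_window(13, "+", amplicon_length = 40,
                                   id = "siteX"), "siteX")
})

test_that("target sites are strand-mirror symmetric", {
  site <- make_test_site()
  rc_amp <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(site$amplicon)))
  rc_site <- target_site(rc_amp, site$spacer, site$pam)
  L <- nchar(site$amplicon)
  expect_identical(rc_site$strand, "-")
  expect_equal(rc_site$cut_center, L - site$cut_center)
  expect_equal(rc_site$window, c(L - site$window[2], L - site$window[1]))
  expect_equal(rc_site$pam_interval,
               c(L - site$pam_interval[2], L - site$pam_interval[1]))
})

test_that("spacer validation enforces the 16 nt minimum", {
  expect_true(validate_spacer(strrep("A", 18))$ok)
  expect_true(validate_spacer(strrep("A", 16))$ok)
  v <- validate_spacer(strrep("A", 15))
  expect_false(v$ok)
  expect_match(v$reason, "16")
})

test_that("anti-repeat search finds the duplex and matches exhaustive rescoring", {
  rep_seq <- "ACGUACGU"
  rc_rna <- function(x) chartr("ACGU", "UGCA",
                               paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  tracr <- paste0("AAAA", rc_rna(rep_seq), "AAAA")
  d <- find_anti_repeat(tracr, rep_seq)
  expect_equal(d$score, 16)
  expect_equal(d$tracr_interval, c(4, 12))
  expect_true(all(d$pairing == "WC"))

  # one Watson-Crick pair downgraded to a G:U wobble: repeat A pairs U;
  # change that tracr U to G keeps a (wobble) pair only if repeat base is U
  tracr2 <- paste0("AAAA", sub("C", "U", rc_rna(rep_seq)), "AAAA")
  d2 <- find_anti_repeat(tracr2, rep_seq)
  expect_equal(d2$score, 15)
  expect_equal(sum(d2$pairing == "wobble"), 1)

  expect_null(find_anti_repeat(strrep("A", 30), strrep("A", 8)))
  expect_error(find_anti_repeat("ACGT", "ACGU"), "RNA")
  expect_error(find_anti_repeat("", "ACGU"), "empty")

  set.seed(7)
  for (i in 1:20) {
    tr <- paste0(sample(c("A", "C", "G", "U"), 60, TRUE), collapse = "")
    rp <- paste0(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")
    o <- oracle_anti_repeat(tr, rp)
    d3 <- find_anti_repeat(tr, rp, min_score = -Inf)
    expect_equal(d3$score, o$score)
    expect_equal(d3$tracr_interval[1], o$tracr_start)
  }
})

test_that("sgRNA assembly concatenates components and decomposes exactly", {
  set.seed(1)
  tracr <- paste0(sample(c("A", "C", "G", "U"), 153, TRUE), collapse = "")
  rep_part <- paste0(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
  spacer <- paste0(sample(c("A", "C", "G", "U"), 18, TRUE), collapse = "")
  arch <- list(tracr = tracr, crrna_repeat = rep_part, spacer = spacer,
               linker = "GAAA")
  sg <- assemble_sgRNA(arch)
  expect_equal(nchar(sg), 153 + 4 + 20 + 18)
  # decomposition by component lengths recovers the inputs
  expect_identical(substr(sg, 1, 153), tracr)
  expect_identical(substr(sg, 154, 157), "GAAA")
  expect_identical(substr(sg, 158, 177), rep_part)
  expect_identical(substr(sg, 178, 195), spacer)
  arch$spacer <- ""
  expect_error(assemble_sgRNA(arch), "non-empty")
  arch$spacer <- spacer; arch$linker <- "GAAAA"
  expect_error(assemble_sgRNA(arch), "4 nt")
})

test_that("enriched species calling thresholds and merges pileup blocks", {
  cov <- rep(1L, 500); cov[100:149] <- 1000L
  iv <- call_enriched_species(cov)
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start, iv$end), c(99, 149))

  # two blocks separated by a 3-position gap merge at merge_gap = 5
  cov2 <- rep(1L, 300); cov2[50:79] <- 500L; cov2[83:112] <- 400L
  iv2 <- call_enriched_species(cov2)
  expect_equal(nrow(iv2), 1)
  expect_equal(c(iv2$start, iv2$end), c(49, 112))
  # but stay separate when the gap exceeds merge_gap
  iv2b <- call_enriched_species(cov2, merge_gap = 2)
  expect_equal(nrow(iv2b), 2)

  # below k x median: nothing called (direct threshold computation)
  cov3 <- rep(1L, 200); cov3[20:39] <- 5L
  expect_equal(nrow(call_enriched_species(cov3, k = 10)), 0)
  expect_equal(nrow(call_enriched_species(integer(100))), 0)
  expect_error(call_enriched_species(c(1L, -1L)), "non-negative")
})
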