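test_that("plant classification follows the ~50% / ~100% diploid bands", {
  # homozygous: both punches near 100% with the same allele
  hom <- classify_plant(fake_callset(990, 10), fake_callset(980, 20))
  expect_equal(hom$call, "homozygous")
  # heterozygous: both near 50% with the same allele
  het <- classify_plant(fake_callset(510, 490), fake_callset(480, 520))
  expect_equal(het$call, "heterozygous")
  # discordant punches: chimeric
  chi <- classify_plant(fake_callset(950, 50), fake_callset(80, 920))
  expect_equal(chi$call, "chimeric")
  # background only: wild type
  wt <- classify_plant(fake_callset(0, 1000, top_key = NA),
                       fake_callset(1, 999, top_key = NA))
  expect_equal(wt$call, "wild_type")
  # same fractions but different alleles cannot be a germline call
  mixed <- classify_plant(fake_callset(500, 500, top_key = "D:60-65"),
                          fake_callset(500, 500, top_key = "D:58-64"))
  expect_equal(mixed$call, "chimeric")
  # insufficient coverage is reported, not guessed
  low <- classify_plant(fake_callset(30, 20), fake_callset(500, 500))
  expect_equal(low$call, "insufficient_coverage")
})

test_that("widening the heterozygous band never loses het calls", {
  set.seed(61)
  narrow <- zygosity_bands(het_min = 0.40, het_max = 0.60)
  wide <- zygosity_bands(het_min = 0.30, het_max = 0.70)
  n_het <- c(narrow = 0, wide = 0)
  for (i in 1:200) {
    f <- runif(2, 0.2, 0.8)
    a <- fake_callset(round(1000 * f[1]), round(1000 * (1 - f[1])))
    b <- fake_callset(round(1000 * f[2]), round(1000 * (1 - f[2])))
    cn <- classify_plant(a, b, narrow)$call
    cw <- classify_plant(a, b, wide)$call
    if (cn == "heterozygous") expect_equal(cw, "heterozygous")
    n_het <- n_het + c(cn == "heterozygous", cw == "heterozygous")
  }
  expect_gte(n_het["wide"], n_het["narrow"])
})

test_that("cohort summaries apply the plant-count formulas", {
  calls <- c(
    lapply(1:4, function(i) classify_plant(fake_callset(990, 10),
                                           fake_callset(985, 15),
                                           plant_id = paste0("hom", i))),
    lapply(1:3, function(i) classify_plant(fake_callset(500, 500),
                                           fake_callset(510, 490),
                                           plant_id = paste0("het", i))),
    lapply(1:13, function(i) classify_plant(fake_callset(0, 1000, NA),
                                            fake_callset(0, 1000, NA),
                                            plant_id = paste0("wt", i))))
  s <- summarize_cohort(calls)
  expect_equal(s$n_plants, 20)
  expect_equal(s$n_edited, 7)
  expect_equal(s$pct_edited, 35.0)
  # proportions over edited plants
  expect_equal(unname(s$zygosity_proportions["homozygous"]), 4 / 7)
  expect_equal(unname(s$zygosity_proportions["heterozygous"]), 3 / 7)
  expect_equal(sum(s$zygosity_proportions), 1)
  # counts equal the multiset of calls (conservation)
  expect_equal(as.vector(s$counts[c("homozygous", "heterozygous",
                                    "wild_type")]), c(4L, 3L, 13L))
  expect_equal(sum(s$counts), s$n_called)

  # all wild type: 0% edited, proportions emitted empty
  wt_only <- lapply(1:5, function(i)
    classify_plant(fake_callset(0, 1000, NA), fake_callset(0, 1000, NA)))
  s0 <- summarize_cohort(wt_only)
  expect_equal(s0$pct_edited, 0)
  expect_length(s0$zygosity_proportions, 0)

  # 6 het / 4 hom -> 0.6 / 0.4
  mix <- c(lapply(1:6, function(i) classify_plant(fake_callset(500, 500),
                                                  fake_callset(500, 500))),
           lapply(1:4, function(i) classify_plant(fake_callset(995, 5),
                                                  fake_callset(990, 10))))
  sm <- summarize_cohort(mix)
  expect_equal(as.vector(sm$zygosity_proportions[c("heterozygous",
                                                   "homozygous")]),
               c(0.6, 0.4))
})

test_that("end-to-end plant calls recover simulated zygosity", {
  site <- make_test_site()
  ctl <- simulate_negative_control(site, sim_config(seed = 70, depth = 20000))
  ctl_tally <- tally_sample(ctl$reads, site)
  for (z in c("hom", "het", "chimeric", "wt")) {
    p <- simulate_plant(site, z, sim_config(seed = 71, depth = 1000))
    cs <- lapply(p$punches, function(pu)
      call_sample(pu$reads, site, ctl_tally))
    call <- classify_plant(cs[[1]], cs[[2]], plant_id = z)$call
    expected <- switch(z, hom = "homozygous", het = "heterozygous",
                       wt = "wild_type", chimeric = NULL)
    if (!is.null(expected)) expect_equal(call, expected, info = z)
    else expect_false(call == "insufficient_coverage")
  }
})
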