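test_that("rank normalization gives exact normal scores with tied handling", {
  # odd M: the median maps to zero
  expect_equal(rank_normalize(c(5, 1, 9))[1], 0)
  # M = 100: the maximum maps to qnorm(0.995) ~ 2.576
  z <- rank_normalize(seq_len(100))
  expect_equal(max(z), qnorm(0.995), tolerance = 1e-12)
  expect_equal(max(z), 2.576, tolerance = 1e-3)
  # ties share a value; order is preserved
  zt <- rank_normalize(c(1, 2, 2, 3))
  expect_equal(zt[2], zt[3])
  expect_true(all(diff(rank_normalize(sort(rnorm(50)))) >= 0))
  # moments: mean exactly 0 by symmetry, SD tends to 1
  big <- rank_normalize(rnorm(2000))
  expect_lt(abs(mean(big)), 1e-10)
  expect_equal(sd(big), 1, tolerance = 0.05)
  expect_error(rank_normalize(1), "at least 2")
})

test_that("haplotype r2 equals the hand-computed D-based formula", {
  # 4 haplotypes: x = (1,1,0,0), y = (1,0,0,0)
  haps <- cbind(c(1, 1, 0, 0), c(1, 0, 0, 0))
  panel <- tiny_panel(haps, pos = c(100L, 200L))
  pa <- 0.5; pb <- 0.25; pab <- 0.25
  d <- pab - pa * pb
  r2_hand <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  expect_equal(hap_r2(panel, "chr1:100", "chr1:200"), r2_hand)
  expect_equal(r2_hand, 1 / 3)
  # monomorphic sites have undefined r2
  haps2 <- cbind(c(1, 1, 0, 0), c(0, 0, 0, 0))
  p2 <- tiny_panel(haps2, pos = c(100L, 200L))
  expect_true(is.na(hap_r2(p2, "chr1:100", "chr1:200")))
})

test_that("LD proxy mapping prefers self, then the best in-window proxy", {
  withr::local_seed(71)
  # site 1 and 2 are perfect copies; site 3 is independent
  block <- as.integer(runif(20) < 0.5)
  haps <- cbind(block, block, as.integer(runif(20) < 0.5))
  panel <- tiny_panel(haps, pos = c(1000L, 2000L, 50000L))
  scored <- c("chr1:2000", "chr1:50000")

  # a scored trait variant maps to itself
  self_set <- tibble::tibble(variant_id = "chr1:2000", chrom = "chr1",
                             pos = 2000L)
  m1 <- ld_proxy_expand(self_set, panel, scored)
  expect_equal(m1$mapped_id, "chr1:2000")
  expect_equal(m1$r2, 1)

  # an unscored variant maps to its perfect copy, not the far independent site
  set2 <- tibble::tibble(variant_id = "chr1:1000", chrom = "chr1",
                         pos = 1000L)
  m2 <- ld_proxy_expand(set2, panel, scored)
  expect_equal(m2$mapped_id, "chr1:2000")
  expect_equal(m2$r2, 1)

  # below the r2 floor the variant is dropped and counted
  m3 <- ld_proxy_expand(set2, panel, "chr1:50000", r2_min = 0.5)
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "n_dropped"), 1L)

  # two trait variants landing on one proxy collapse to a single row
  set4 <- tibble::tibble(variant_id = c("chr1:1000", "chr1:2000"),
                         chrom = "chr1", pos = c(1000L, 2000L))
  m4 <- ld_proxy_expand(set4, panel, scored)
  expect_equal(nrow(m4), 1L)
})

test_that("the chi-square sum test matches tail probabilities and is sign-blind", {
  r0 <- chi2_sum_test(rep(0, 5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$inflation, 0)

  r1 <- chi2_sum_test(1.96)
  expect_equal(r1$statistic, 3.8416, tolerance = 1e-4)
  expect_equal(r1$p, 0.05, tolerance = 1e-3)

  # monotone: larger statistic, smaller P at fixed k
  pa <- chi2_sum_test(c(0, 0))$p
  pb <- chi2_sum_test(c(3, 3))$p
  expect_lt(pb, pa)

  # flipping every sign leaves the statistic unchanged
  withr::local_seed(72)
  zz <- rnorm(12)
  expect_equal(chi2_sum_test(zz)$statistic, chi2_sum_test(-zz)$statistic)
  expect_error(chi2_sum_test(numeric(0)), "empty")
})

test_that("multiple-testing control reproduces the fixed threshold and BH q-values", {
  mt <- multiple_testing(c(0.0001, 0.01), n_tests = 103)
  expect_equal(signif(mt$threshold[1], 2), 0.00049)
  expect_equal(mt$significant, c(TRUE, FALSE))

  # a single test keeps the nominal level
  expect_equal(multiple_testing(0.03, n_tests = 1)$threshold, 0.05)
  expect_true(multiple_testing(0.03, n_tests = 1)$significant)

  # BH step-up on a hand-computed case
  bh <- multiple_testing(c(0.01, 0.02, 0.03, 0.04), method = "bh")
  expect_equal(bh$q, rep(0.04, 4))
  expect_true(all(bh$significant))
})

test_that("trait sets inherit planted selection signal through LD proxies", {
  fx <- selected_scan_fixture()
  sds <- fx$sds
  sites <- sds[, c("variant_id", "chrom", "pos")]
  ts <- simulate_trait_sets(fx$cfg, sites, n_traits = 6, k_per_trait = 10,
                            enriched_fraction = 0.5)
  rec <- trait_enrichment_scan(ts$sets, sds, fx$sim$panel)
  expect_s3_class(rec, "enrich_tbl")
  expect_equal(nrow(rec), 6L)
  expect_true(all(rec$inflation[!is.na(rec$p)] >= 0))
  enr <- rec$trait %in% ts$truth$trait[ts$truth$enriched]
  # enriched sets carry larger mean inflation than null sets
  expect_gt(mean(rec$inflation[enr], na.rm = TRUE),
            mean(rec$inflation[!enr], na.rm = TRUE))
})

test_that("locus removal recomputes ranks and strips excluded mappings", {
  fx <- selected_scan_fixture()
  sds <- fx$sds
  sites <- sds[, c("variant_id", "chrom", "pos")]
  ts <- simulate_trait_sets(fx$cfg, sites, n_traits = 4, k_per_trait = 12,
                            enriched_fraction = 0.5)
  base <- trait_enrichment_scan(ts$sets, sds, fx$sim$panel)

  # an empty exclusion reproduces the base scan exactly
  same <- locus_removal_rerun(
    ts$sets, sds, fx$sim$panel,
    exclusion = tibble::tibble(chrom = character(), start = numeric(),
                               end = numeric())
  )
  expect_equal(as.data.frame(same), as.data.frame(base))

  # excluding the planted locus weakens the enriched traits
  excl <- tibble::tibble(chrom = "chr1", start = 1e6 - 5e4 - 1,
                         end = 1e6 + 5e4)
  cut <- locus_removal_rerun(ts$sets, sds, fx$sim$panel, exclusion = excl)
  enr <- ts$truth$trait[ts$truth$enriched]
  for (tr in enr) {
    k0 <- base$k[base$trait == tr]
    k1 <- cut$k[cut$trait == tr]
    expect_lte(k1, k0)
  }
  expect_gt(
    min(cut$p[cut$trait %in% enr], na.rm = TRUE),
    min(base$p[base$trait %in% enr], na.rm = TRUE)
  )

  # a trait living entirely inside the excluded locus is reported unmapped
  inside <- sds[sds$chrom == "chr1" & abs(sds$pos - 1e6) <= 5e4, ]
  expect_gte(nrow(inside), 3)
  only_in <- tibble::tibble(
    trait = "inside", category = "disease",
    variant_id = inside$variant_id[1:3],
    chrom = inside$chrom[1:3], pos = inside$pos[1:3]
  )
  gone <- locus_removal_rerun(only_in, sds, fx$sim$panel, exclusion = excl)
  expect_equal(gone$reason, "unmapped")
  expect_equal(gone$k, 0L)
})
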