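test_that("neutral singleton placement has Poisson moments per haplotype", {
  cfg <- sim_config(
    seed = 5, layout = toy_layout(1, 1e6, 1), sample_sizes = 50,
    n_common = 10, lambda0 = 2e-4, doubleton_fraction = 0,
    regions = tibble::tibble(region = "all", prop = 1, f = 0)
  )
  sim <- simulate_panel(cfg)
  # per-haplotype counts ~ Poisson(lambda0 * L); compare the mean over 100
  # haplotypes to the theoretical rate within 3 standard errors
  per_sample <- table(factor(sim$truth_singletons$sample_id,
                             levels = sim$panel$samples$sample_id))
  lambda_ind <- 2 * cfg$lambda0 * 1e6   # two haplotypes per individual
  se <- sqrt(lambda_ind / 50)
  expect_lt(abs(mean(per_sample) - lambda_ind), 3 * se)
})

test_that("a selected locus depletes singletons on derived haplotypes only", {
  cfg <- sim_config(
    seed = 6, layout = toy_layout(1, 2e6, 1), sample_sizes = 150,
    n_common = 20, lambda0 = 2e-4, doubleton_fraction = 0,
    selected = tibble::tibble(
      chrom = "chr1", pos = 1000000L, daf = 0.5, rho = 0.2, half_width = 2e5
    ),
    regions = tibble::tibble(region = "all", prop = 1, f = 0)
  )
  sim <- simulate_panel(cfg)
  core_j <- match("chr1:1000000", sim$panel$sites$variant_id)
  carrier_hap <- as.vector(sim$panel$haps[, core_j]) == 1
  in_win <- abs(sim$truth_singletons$pos - 1e6) <= 2e5
  # attribute each singleton to a haplotype through its carrier sample; use
  # per-sample derived-carrier status (a carrier sample holds >= 1 derived hap)
  smp <- match(sim$truth_singletons$sample_id, sim$panel$samples$sample_id)
  n_der_haps <- carrier_hap[2 * smp - 1] + carrier_hap[2 * smp]
  hom_der <- n_der_haps == 2
  hom_anc <- n_der_haps == 0
  rate_der <- sum(in_win & hom_der) / sum(in_win & hom_anc) *
    sum(hom_anc[!in_win]) / sum(hom_der[!in_win])
  # in-window singleton rate on derived-homozygote individuals is depleted
  # roughly rho-fold relative to ancestral homozygotes
  expect_lt(rate_der, 0.45)
  expect_gt(rate_der, 0.05)
  # and the empirical flanking gaps are longer for derived homozygotes
  cat_truth <- dplyr::mutate(sim$truth_singletons, retained = TRUE,
                             reason = "none")
  obs <- gap_lengths(
    sim$panel, cat_truth, "d1", cfg$layout,
    tibble::tibble(variant_id = "chr1:1000000", chrom = "chr1", pos = 1000000L)
  )
  obs <- obs[!obs$censored, ]
  expect_gt(mean(obs$gap[obs$gclass == 2]), mean(obs$gap[obs$gclass == 0]))
})

test_that("panel simulation is deterministic for a fixed seed and leaves caller RNG alone", {
  cfg <- sim_config(seed = 9, layout = toy_layout(1, 5e5, 1),
                    sample_sizes = c(5, 5), n_common = 30, lambda0 = 5e-5)
  set.seed(1); x_before <- runif(1)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$sites, b$panel$sites)
  expect_identical(as.matrix(a$panel$haps), as.matrix(b$panel$haps))
  expect_identical(a$truth_singletons, b$truth_singletons)
  set.seed(1)
  expect_identical(runif(1), x_before)
})

test_that("selected-locus windows must fit inside an arm", {
  expect_error(
    sim_config(
      layout = toy_layout(1, 1e6, 1), sample_sizes = 10,
      selected = tibble::tibble(chrom = "chr1", pos = 5000L, daf = 0.5,
                                rho = 0.5, half_width = 1e4)
    ),
    "window"
  )
})

test_that("regional counts collapse to the pooled DAF as drift vanishes", {
  cfg <- sim_config(seed = 3, layout = toy_layout(1, 1e6, 1),
                    sample_sizes = 10,
                    regions = tibble::tibble(
                      region = c("r1", "r2", "r3"), prop = c(0.5, 0.3, 0.2),
                      f = 0
                    ))
  counts <- simulate_regional_counts(cfg, daf = c(0.3, 0.8))
  freq <- counts$derived / (counts$derived + counts$ancestral)
  expected <- c(0.3, 0.8)[match(counts$variant_id, c("v1", "v2"))]
  expect_lt(max(abs(freq - expected)), 0.01)
})

test_that("degenerate pooled frequencies give degenerate regional tables", {
  cfg <- sim_config(seed = 3, layout = toy_layout(1, 1e6, 1),
                    sample_sizes = 10)
  counts <- simulate_regional_counts(cfg, daf = c(0, 1))
  c0 <- counts[counts$variant_id == "v1", ]
  c1 <- counts[counts$variant_id == "v2", ]
  expect_true(all(c0$derived == 0))
  expect_true(all(c1$ancestral == 0))
  # reproducible under the same config
  expect_identical(counts, simulate_regional_counts(cfg, daf = c(0, 1)))
})

test_that("selected variants receive inflated regional drift", {
  cfg <- sim_config(seed = 8, layout = toy_layout(1, 1e6, 1),
                    sample_sizes = 10, f_selected_multiplier = 50)
  k <- 200
  cn <- simulate_regional_counts(cfg, daf = rep(0.5, k), selected = FALSE)
  cs <- simulate_regional_counts(cfg, daf = rep(0.5, k), selected = TRUE)
  h_null <- het_index_by_variant(cn)$h
  h_sel <- het_index_by_variant(cs)$h
  expect_gt(mean(h_sel), 5 * mean(h_null))
})

test_that("simulated tracts respect the requested total length and bounds", {
  cfg <- sim_config(seed = 4, layout = toy_layout(2, 1e6, 2),
                    sample_sizes = 10)
  expect_equal(nrow(simulate_tracts(cfg, 1e5, 0)), 0L)
  tr <- simulate_tracts(cfg, 4e5, 10)
  total <- sum(tr$end - tr$start)
  expect_lte(abs(total - 4e5), 4e4)  # within one tract length
  # normalized: inside chromosome bounds and non-overlapping
  expect_true(all(tr$start >= 0))
  expect_true(all(tr$end <= 2e6))
  by_chrom <- split(tr, tr$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= head(d$end, -1)))
  }
  expect_error(simulate_tracts(cfg, 5e6, 2), "exceeds")
})

test_that("null trait sets overlap selected windows only at chance level", {
  cfg <- sim_config(
    seed = 12, layout = toy_layout(1, 2e6, 1), sample_sizes = 10,
    selected = tibble::tibble(chrom = "chr1", pos = 1000000L, daf = 0.5,
                              rho = 0.5, half_width = 1e5)
  )
  sites <- tibble::tibble(
    variant_id = paste0("chr1:", seq(1e4, 1.99e6, by = 1e4)),
    chrom = "chr1", pos = seq(1e4, 1.99e6, by = 1e4)
  )
  ts <- simulate_trait_sets(cfg, sites, n_traits = 60, k_per_trait = 10,
                            enriched_fraction = 0)
  expect_true(all(!ts$truth$enriched))
  in_win <- abs(ts$sets$pos - 1e6) <= 1e5
  p_win <- mean(abs(sites$pos - 1e6) <= 1e5)
  n <- nrow(ts$sets)
  # binomial expectation within 4 standard errors
  expect_lt(abs(sum(in_win) - n * p_win), 4 * sqrt(n * p_win * (1 - p_win)))
})

test_that("enriched trait sets concentrate in selected windows and are flagged", {
  cfg <- sim_config(
    seed = 13, layout = toy_layout(1, 2e6, 1), sample_sizes = 10,
    selected = tibble::tibble(chrom = "chr1", pos = 1000000L, daf = 0.5,
                              rho = 0.5, half_width = 1e5)
  )
  sites <- tibble::tibble(
    variant_id = paste0("chr1:", seq(1e4, 1.99e6, by = 1e4)),
    chrom = "chr1", pos = seq(1e4, 1.99e6, by = 1e4)
  )
  ts <- simulate_trait_sets(cfg, sites, n_traits = 10, k_per_trait = 10,
                            enriched_fraction = 0.5)
  expect_equal(sum(ts$truth$enriched), 5L)
  enr <- ts$sets$trait %in% ts$truth$trait[ts$truth$enriched]
  expect_gt(mean(abs(ts$sets$pos[enr] - 1e6) <= 1e5), 0.4)
})
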