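test_that("flanking gaps match hand computation and censoring rules", {
  haps <- matrix(c(0, 1, 0, 0), ncol = 1)   # variant: s1 het, s2 anc-hom
  panel <- tiny_panel(haps, pos = 4000L)
  layout <- genome_layout(tibble::tibble(chrom = "chr1", length = 20000))
  cat <- tiny_catalog(pos = c(1000, 9000, 3500), sample_id = c("s1", "s1", "s2"))
  obs <- gap_lengths(
    panel, cat, "d1", layout,
    tibble::tibble(variant_id = "chr1:4000", chrom = "chr1", pos = 4000L)
  )
  o1 <- obs[obs$sample_id == "s1", ]
  expect_equal(o1$d_up, 3000)
  expect_equal(o1$d_down, 5000)
  expect_equal(o1$gap, 8000)
  expect_equal(o1$gclass, 1L)
  expect_false(o1$censored)
  # s2 has an upstream event only: censored
  o2 <- obs[obs$sample_id == "s2", ]
  expect_true(o2$censored)
  expect_true(is.na(o2$gap))
  # variant outside every arm errors
  small <- genome_layout(tibble::tibble(chrom = "chr1", length = 20000),
                         tibble::tibble(chrom = "chr1", start = 0,
                                        end = 1000, arm = "p"))
  expect_error(
    gap_lengths(panel, cat, "d1", small,
                tibble::tibble(variant_id = "chr1:4000", chrom = "chr1",
                               pos = 4000L)),
    "outside"
  )
})

test_that("an event at the variant position is not its own flank", {
  haps <- matrix(c(1, 0), ncol = 1)
  panel <- tiny_panel(haps, pos = 5000L)
  layout <- genome_layout(tibble::tibble(chrom = "chr1", length = 20000))
  cat <- tiny_catalog(pos = c(2000, 5000, 8000), sample_id = "s1")
  obs <- gap_lengths(
    panel, cat, "d1", layout,
    tibble::tibble(variant_id = "chr1:5000", chrom = "chr1", pos = 5000L)
  )
  expect_equal(obs$d_up, 3000)   # strictly-before neighbour, not 5000 itself
  expect_equal(obs$d_down, 3000)
})

test_that("interval lookup agrees with a brute-force scan on random catalogs", {
  withr::local_seed(55)
  layout <- genome_layout(tibble::tibble(chrom = "chr1", length = 1.1e6))
  panel <- random_panel(56, n_samples = 6, n_sites = 15)
  vars <- compute_daf(panel)[, c("variant_id", "chrom", "pos")]
  cat <- tiny_catalog(
    pos = sample.int(1.1e6, 120),
    sample_id = sample(panel$samples$sample_id, 120, replace = TRUE)
  )
  obs <- gap_lengths(panel, cat, "d1", layout, vars)
  for (i in sample.int(nrow(obs), 40)) {
    row <- obs[i, ]
    v <- vars$pos[vars$variant_id == row$variant_id]
    sp <- sort(cat$pos[cat$sample_id == row$sample_id])
    up <- sp[sp < v]
    dn <- sp[sp > v]
    if (length(up) && length(dn)) {
      expect_equal(row$d_up, v - max(up))
      expect_equal(row$d_down, min(dn) - v)
    } else {
      expect_true(row$censored)
    }
  }
})

test_that("equal gaps in the two homozygote classes give a zero raw score", {
  obs <- tiny_obs(gclass = rep(c(0, 2), each = 12),
                  gap = rep(c(3000, 5000, 7000), 8))
  fit <- fit_raw_sds(obs, min_class_count = 5)
  expect_equal(fit$raw, 0, tolerance = 1e-9)
})

test_that("homozygote-only likelihood reduces to the closed form 1/mean(gap)", {
  withr::local_seed(77)
  for (rep in 1:20) {
    g_aa <- rexp(15, 1e-4)
    g_dd <- rexp(15, 5e-5)
    obs <- tiny_obs(gclass = rep(c(0, 2), each = 15), gap = c(g_aa, g_dd))
    fit <- fit_raw_sds(obs, min_class_count = 5)
    expect_equal(fit$lambda_anc, 1 / mean(g_aa), tolerance = 1e-9)
    expect_equal(fit$lambda_der, 1 / mean(g_dd), tolerance = 1e-9)
    expect_equal(fit$raw, log(1 / mean(g_aa)) - log(1 / mean(g_dd)),
                 tolerance = 1e-9)
  }
  # doubled derived gaps: raw = log 2 exactly
  obs2 <- tiny_obs(gclass = rep(c(0, 2), each = 10),
                   gap = c(rep(4000, 10), rep(8000, 10)))
  expect_equal(fit_raw_sds(obs2, min_class_count = 5)$raw, log(2),
               tolerance = 1e-9)
})

test_that("joint MLE with heterozygotes matches a dense grid search", {
  withr::local_seed(88)
  for (rep in 1:50) {
    n0 <- sample(5:20, 1); n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    la <- exp(runif(1, log(2e-5), log(5e-4)))
    ld <- exp(runif(1, log(2e-5), log(5e-4)))
    gaps <- c(rgamma(n0, 2, 2 * la), rgamma(n1, 2, la + ld),
              rgamma(n2, 2, 2 * ld))
    obs <- tiny_obs(gclass = rep(c(0, 1, 2), c(n0, n1, n2)), gap = gaps)
    fit <- fit_raw_sds(obs, min_class_count = 2)
    oracle <- grid_search_sds(obs)
    expect_lt(abs(fit$raw - oracle$raw), 1e-3)
  }
})

test_that("class-count and convergence guards produce reason codes, not scores", {
  # too few derived carriers
  obs <- tiny_obs(gclass = c(rep(0, 12), 1), gap = rexp(13, 1e-4))
  fit <- fit_raw_sds(obs, min_class_count = 5)
  expect_equal(fit$reason, "class_count")
  expect_true(is.na(fit$raw))
})

test_that("raw score grows as the derived singleton process thins", {
  withr::local_seed(99)
  raws <- vapply(c(1, 0.5, 0.2, 0.1), function(rho) {
    mean(vapply(1:30, function(i) {
      g <- c(rgamma(20, 2, 2e-4), rgamma(20, 2, 1e-4 + 1e-4 * rho),
             rgamma(20, 2, 2e-4 * rho))
      fit_raw_sds(
        tiny_obs(gclass = rep(c(0, 1, 2), each = 20), gap = g),
        min_class_count = 5
      )$raw
    }, 0.0))
  }, 0.0)
  expect_true(all(diff(raws) > 0))
  expect_lt(abs(raws[1]), 0.15)
})

test_that("bin standardization centres each DAF bin and is location invariant", {
  sc <- tibble::tibble(variant_id = c("a", "b"), raw = c(-1, 1),
                       daf = c(0.5, 0.502))
  out <- bin_standardize(sc, bin_scheme(min_occupancy = 1))
  expect_equal(out$z, c(-1, 1))

  withr::local_seed(21)
  sc2 <- tibble::tibble(
    variant_id = paste0("v", 1:400),
    raw = rnorm(400), daf = runif(400, 0.02, 0.98)
  )
  a <- bin_standardize(sc2, bin_scheme())
  b <- bin_standardize(dplyr::mutate(sc2, raw = raw + 5), bin_scheme())
  expect_equal(a$z, b$z, tolerance = 1e-12)
  # per-bin moments match direct recomputation, and occupancy respects the
  # minimum after merging
  chk <- dplyr::summarise(
    dplyr::group_by(a, bin),
    n = dplyr::n(), m = mean(z), s = sd(z)
  )
  expect_true(all(chk$n >= 20))
  expect_true(all(abs(chk$m) < 1e-12))
  # z was scaled by the population SD, so the sample SD is sqrt(n / (n - 1))
  expect_true(all(abs(chk$s - sqrt(chk$n / (chk$n - 1))) < 1e-12))
  # oracle: recompute one bin by hand from the raw values
  b1 <- a[a$bin == a$bin[1], ]
  expect_equal(b1$z,
               (b1$raw - mean(b1$raw)) /
                 sqrt(mean((b1$raw - mean(b1$raw))^2)))
})

test_that("the DAF bin scheme uses 0.005-wide tails and 0.01-wide middle bins", {
  e <- bin_scheme()$edges
  expect_equal(min(e), 0)
  expect_equal(max(e), 1)
  widths <- diff(e)
  tails <- e[-length(e)] < 0.1 - 1e-9 | e[-length(e)] >= 0.9 - 1e-9
  expect_true(all(abs(widths[tails] - 0.005) < 1e-9))
  expect_true(all(abs(widths[!tails] - 0.01) < 1e-9))
})

test_that("sqrt-n-weighted meta z matches closed forms and the P conversion", {
  # three equal datasets, z = (1, 1, 1): meta z = sqrt(3)
  m1 <- meta_analyze(matrix(1, 1, 3), n = c(50, 50, 50))
  expect_equal(m1$meta_z, sqrt(3), tolerance = 1e-12)
  # two equal datasets, z = (2, 0): meta z = sqrt(2)
  m2 <- meta_analyze(matrix(c(2, 0), 1, 2), n = c(100, 100))
  expect_equal(m2$meta_z, sqrt(2), tolerance = 1e-12)
  # a final z of -5.80 corresponds to a two-tailed P of 6.6e-9
  m3 <- meta_analyze(matrix(-5.80, 1, 1), n = 1)
  expect_equal(signif(m3$p, 2), 6.6e-9)
  expect_true(m3$significant)  # 6.6e-9 clears the genome-wide threshold
  # and 5.80 the same by symmetry
  expect_equal(m3$p, meta_analyze(matrix(5.80, 1, 1), n = 1)$p)
})

test_that("final z is the genome-wide re-standardized meta z with its P", {
  withr::local_seed(66)
  z <- matrix(rnorm(300), ncol = 3)
  out <- meta_analyze(z, n = c(120, 50, 40))
  w <- sqrt(c(120, 50, 40))
  meta <- as.vector(z %*% w) / sqrt(sum(w^2))
  expect_equal(out$meta_z, meta)
  expect_equal(mean(out$final_z), 0, tolerance = 1e-12)
  expect_equal(sd(out$final_z), 1, tolerance = 1e-12)
  expect_equal(out$p, 2 * pnorm(-abs(out$final_z)))
  expect_equal(out$significant, out$p < 5e-8)
})

test_that("the scan reports a variant only when it is scored in every dataset", {
  fx <- selected_scan_fixture()
  sds <- fx$sds
  expect_true(all(c("raw_d1", "raw_d2", "raw_d3", "z_d1", "z_d2", "z_d3",
                    "meta_z", "final_z", "p", "significant") %in% names(sds)))
  expect_true(all(stats::complete.cases(
    sds[, c("raw_d1", "raw_d2", "raw_d3")]
  )))
  # re-standardization holds genome-wide
  expect_equal(mean(sds$final_z), 0, tolerance = 1e-9)
  expect_equal(sd(sds$final_z), 1, tolerance = 1e-9)
  # the planted locus carries a clearly elevated score
  core <- sds$final_z[sds$variant_id == "chr1:1000000"]
  expect_gt(core, quantile(sds$final_z, 0.99) - 1e-9)
})
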