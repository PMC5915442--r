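#' Flanking-singleton gap observations for common variants
#'
#' For each individual of a dataset and each candidate variant, finds the
#' nearest retained rare event (singleton or private doubleton) carried by
#' that individual strictly upstream and strictly downstream of the variant
#' within the same chromosome arm. Individuals missing a flanking event on
#' either side are censored and excluded from the likelihood. Recently risen
#' derived alleles sit on haplotypes with shortened tip branches, so their
#' carriers' gaps are systematically longer.
#'
#' @param panel A [haplotype_panel()].
#' @param catalog Singleton catalog (filtered; only `retained` entries are
#'   used).
#' @param dataset Dataset label.
#' @param layout A [genome_layout()].
#' @param variants Tibble of candidate variants (`variant_id`, `chrom`,
#'   `pos`); they must be panel sites lying inside an arm.
#' @return Tibble: `variant_id`, `sample_id`, `gclass` (derived-allele count
#'   0/1/2), `d_up`, `d_down`, `gap`, `censored`.
#' @export
gap_lengths <- function(panel, catalog, dataset, layout, variants) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(layout, "genome_layout"))
  variants <- as_tibble(variants)
  ds_samples <- panel$samples$sample_id[panel$samples$dataset == dataset]
  if (length(ds_samples) == 0) abort(paste0("unknown dataset label: ", dataset))
  a_idx <- arm_index(layout, variants$chrom, variants$pos)
  if (anyNA(a_idx)) abort("variant outside every chromosome arm")
  cat_r <- catalog[catalog$retained & catalog$dataset == dataset, ]
  sing_by_sample <- split(
    cat_r[, c("chrom", "pos")],
    factor(cat_r$sample_id, levels = ds_samples)
  )

  # genotype classes at the candidate variants
  vcol <- match(variants$variant_id, panel$sites$variant_id)
  if (anyNA(vcol)) abort("variant not present in panel")
  rows <- hap_rows(panel, ds_samples)
  M <- panel$haps[rows, vcol, drop = FALSE]
  odd <- seq(1, nrow(M), by = 2)
  G <- as.matrix(M[odd, , drop = FALSE] + M[odd + 1, , drop = FALSE])

  n_var <- nrow(variants)
  n_smp <- length(ds_samples)
  d_up <- matrix(NA_real_, n_var, n_smp)
  d_down <- matrix(NA_real_, n_var, n_smp)
  arms <- layout$arms
  for (a in sort(unique(a_idx))) {
    vi <- which(a_idx == a)
    vpos <- variants$pos[vi]
    for (s in seq_len(n_smp)) {
      sp <- sing_by_sample[[s]]
      sp <- sp$pos[sp$chrom == arms$chrom[a] & (sp$pos - 1) >= arms$start[a] &
                     (sp$pos - 1) < arms$end[a]]
      if (length(sp) == 0) next
      sp <- sort(sp)
      iu <- findInterval(vpos - 1, sp)      # last event strictly before
      id <- findInterval(vpos, sp) + 1      # first event strictly after
      up <- ifelse(iu >= 1, vpos - sp[pmax(iu, 1)], NA_real_)
      dn <- ifelse(id <= length(sp), sp[pmin(id, length(sp))] - vpos, NA_real_)
      d_up[vi, s] <- up
      d_down[vi, s] <- dn
    }
  }
  out <- tibble(
    variant_id = rep(variants$variant_id, n_smp),
    sample_id = rep(ds_samples, each = n_var),
    gclass = as.integer(t(G)),  # -> variant-fastest, matching d_up/d_down
    d_up = as.vector(d_up),
    d_down = as.vector(d_down)
  )
  out$gap <- out$d_up + out$d_down
  out$censored <- is.na(out$gap)
  out
}

#' Fit the raw singleton-density score for gap observations
#'
#' Each haplotype contributes an independent Poisson singleton process, so an
#' individual's per-side nearest-event distance is exponential with the summed
#' rate and the total gap is Gamma(shape 2, rate
#' `n_anc * lambda_anc + n_der * lambda_der`), where `n_anc + n_der = 2` is
#' the individual's genotype split. The joint likelihood over non-censored
#' individuals is maximized in `(lambda_anc, lambda_der)` by coordinate
#' ascent, each coordinate update being the positive root of a quadratic
#' (exact, so the objective increases monotonically); homozygote-only data
#' reduce to the closed form `lambda = 1 / mean(gap)`. The raw score is
#' `log(lambda_anc) - log(lambda_der)`: positive when derived haplotypes are
#' singleton-poor, i.e. under a recent rise of the derived allele.
#'
#' @param obs Gap observations from [gap_lengths()] (one variant or many;
#'   censored rows are dropped internally).
#' @param min_class_count Minimum non-censored individuals carrying at least
#'   one ancestral and at least one derived haplotype, respectively.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Iteration cap.
#' @return Tibble per variant: `variant_id`, `n_used`, `lambda_anc`,
#'   `lambda_der`, `raw`, `reason` (`"ok"`, `"class_count"`,
#'   `"no_convergence"`, `"rate_cap"`).
#' @export
fit_raw_sds <- function(obs, min_class_count = 10, tol = 1e-10,
                        max_iter = 200) {
  obs <- as_tibble(obs)
  used <- obs[!obs$censored, ]
  stats <- used %>%
    group_by(.data$variant_id) %>%
    summarise(
      n_used = n(),
      N0 = sum(.data$gclass == 0), S0 = sum(.data$gap[.data$gclass == 0]),
      N1 = sum(.data$gclass == 1), S1 = sum(.data$gap[.data$gclass == 1]),
      N2 = sum(.data$gclass == 2), S2 = sum(.data$gap[.data$gclass == 2])
    )
  # keep ids with zero usable observations visible
  all_ids <- unique(obs$variant_id)
  stats <- tibble(variant_id = all_ids) %>%
    left_join(stats, by = "variant_id") %>%
    mutate(dplyr::across(
      c("n_used", "N0", "S0", "N1", "S1", "N2", "S2"),
      ~ tidyr::replace_na(.x, 0)
    ))
  fit <- fit_sds_stats(stats, min_class_count, tol, max_iter)
  fit
}

# Vectorized coordinate-ascent MLE on per-variant sufficient statistics
# (class counts N0/N1/N2 and gap sums S0/S1/S2).
fit_sds_stats <- function(stats, min_class_count = 10, tol = 1e-10,
                          max_iter = 200, cap = c(1e-12, 1e12)) {
  N0 <- stats$N0; N1 <- stats$N1; N2 <- stats$N2
  S0 <- stats$S0; S1 <- stats$S1; S2 <- stats$S2
  k <- length(N0)
  ok <- (N0 + N1) >= min_class_count & (N1 + N2) >= min_class_count
  reason <- ifelse(ok, "ok", "class_count")

  c1 <- 2 * S0 + S1   # total gap weight on lambda_anc
  c2 <- 2 * S2 + S1
  # start from homozygote closed forms, falling back to the pooled rate
  pooled <- 2 * (N0 + N1 + N2) / pmax(S0 + S1 + S2, .Machine$double.xmin)
  la <- ifelse(N0 > 0 & S0 > 0, N0 / S0, pooled)
  ld <- ifelse(N2 > 0 & S2 > 0, N2 / S2, pooled)
  la <- pmin(pmax(la, cap[1]), cap[2])
  ld <- pmin(pmax(ld, cap[1]), cap[2])

  ll <- function(la, ld) {
    2 * N0 * log(2 * la) * (N0 > 0) + 2 * N1 * log(la + ld) * (N1 > 0) +
      2 * N2 * log(2 * ld) * (N2 > 0) - c1 * la - c2 * ld
  }
  # positive root of  c * x^2 + (c * other - 2*Nown - 2*N1) * x - 2*Nown*other = 0
  coord <- function(c_own, n_own, other) {
    b <- c_own * other - 2 * n_own - 2 * N1
    disc <- b^2 + 8 * c_own * n_own * other
    x <- (-b + sqrt(pmax(disc, 0))) / (2 * c_own)
    x[c_own == 0] <- cap[2]
    x
  }
  active <- ok
  prev <- ll(la, ld)
  converged <- !ok  # skipped variants need no iterations
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    la[active] <- pmin(pmax(coord(c1, N0, ld)[active], cap[1]), cap[2])
    ld[active] <- pmin(pmax(coord(c2, N2, la)[active], cap[1]), cap[2])
    cur <- ll(la, ld)
    done <- active & abs(cur - prev) < tol
    converged[done] <- TRUE
    active <- active & !done
    prev <- cur
  }
  capped <- ok & (la <= cap[1] | la >= cap[2] | ld <= cap[1] | ld >= cap[2])
  reason[ok & !converged] <- "no_convergence"
  reason[capped] <- "rate_cap"
  tibble(
    variant_id = stats$variant_id,
    n_used = N0 + N1 + N2,
    lambda_anc = ifelse(reason == "ok", la, NA_real_),
    lambda_der = ifelse(reason == "ok", ld, NA_real_),
    raw = ifelse(reason == "ok", log(la) - log(ld), NA_real_),
    reason = reason
  )
}

#' DAF bin scheme for score standardization
#'
#' Bin edges partition (0, 1): width 0.005 where DAF < 0.1 or DAF > 0.9 and
#' width 0.01 for 0.1 <= DAF <= 0.9; bins are half-open `[lo, hi)`.
#'
#' @param min_occupancy Minimum scores per bin before standardization;
#'   under-filled bins are merged with their nearest neighbor.
#' @return A `bin_scheme` list with `edges` and `min_occupancy`.
#' @export
bin_scheme <- function(min_occupancy = 20) {
  edges <- sort(unique(round(c(
    seq(0, 0.1, by = 0.005), seq(0.1, 0.9, by = 0.01), seq(0.9, 1, by = 0.005)
  ), 6)))
  structure(
    list(edges = edges, min_occupancy = min_occupancy),
    class = "bin_scheme"
  )
}

#' Standardize raw scores within DAF bins
#'
#' Within each DAF bin (after merging bins below the occupancy minimum with
#' their nearest neighbor), scores are centered and scaled to mean 0, SD 1.
#' Binning absorbs the strong dependence of raw-score scale on derived allele
#' frequency.
#'
#' @param scores Tibble with `variant_id`, `raw`, `daf`.
#' @param scheme A [bin_scheme()].
#' @return Input with added `bin` (id after merging) and `z`.
#' @export
bin_standardize <- function(scores, scheme = bin_scheme()) {
  scores <- as_tibble(scores)
  scores <- scores[!is.na(scores$raw), ]
  if (nrow(scores) < 2) abort("fewer than 2 scores to standardize")
  edges <- scheme$edges
  bin <- findInterval(scores$daf, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), length(edges) - 1L)
  # merge under-occupied bins with the nearest occupied neighbor
  repeat {
    tab <- table(bin)
    small <- as.integer(names(tab)[tab < scheme$min_occupancy])
    if (length(small) == 0 || length(tab) == 1) break
    b <- small[1]
    others <- setdiff(as.integer(names(tab)), b)
    nb <- others[which.min(abs(others - b))]
    bin[bin == b] <- nb
  }
  out <- scores
  out$bin <- bin
  out %>%
    group_by(.data$bin) %>%
    mutate(z = {
      m <- mean(.data$raw)
      s <- sqrt(mean((.data$raw - m)^2))  # population SD: {-1, 1} -> {-1, 1}
      if (is.na(s) || s == 0) rep(0, n()) else (.data$raw - m) / s
    }) %>%
    ungroup()
}

#' Sample-size-weighted z meta-analysis and genome-wide re-normalization
#'
#' Combines per-dataset standardized scores with weights proportional to the
#' square root of sample size, re-standardizes the meta z genome-wide
#' (single mean/SD), and reports the two-tailed normal P with the conventional
#' genome-wide significance flag.
#'
#' @param z Matrix (variants x datasets) of standardized scores, or a tibble
#'   of `z_*` columns.
#' @param n Per-dataset sample sizes (length = number of datasets).
#' @param sig_threshold Genome-wide significance level on P.
#' @return Tibble `meta_z`, `final_z`, `p`, `significant`.
#' @export
meta_analyze <- function(z, n, sig_threshold = 5e-8) {
  z <- as.matrix(z)
  stopifnot(ncol(z) == length(n), all(n > 0))
  w <- sqrt(n)
  meta <- as.vector(z %*% w) / sqrt(sum(w^2))
  if (length(meta) > 1 && sd(meta) > 0) {
    final <- (meta - mean(meta)) / sd(meta)
  } else {
    final <- meta
  }
  p <- 2 * pnorm(-abs(final))
  tibble(
    meta_z = meta, final_z = final, p = p,
    significant = p < sig_threshold
  )
}

#' Genome-wide singleton-density selection scan
#'
#' End-to-end per-variant scoring: candidate common variants (per-dataset
#' MAF >= `maf_min`) are scored separately per chromosome arm and dataset
#' from flanking-singleton gaps, standardized within DAF bins per dataset,
#' restricted to variants scored in every dataset, meta-analyzed with
#' sqrt(sample size) weights, re-normalized genome-wide, and flagged at the
#' genome-wide significance threshold. Variants closer than one median gap to
#' an arm end are skipped (their gaps are censoring-biased).
#'
#' @param panel A [haplotype_panel()].
#' @param catalog Combined singleton catalog covering every dataset (already
#'   mask- and density-filtered).
#' @param layout A [genome_layout()].
#' @param maf_min Minimum per-dataset minor allele frequency.
#' @param scheme A [bin_scheme()].
#' @param min_class_count Passed to [fit_raw_sds()].
#' @param sig_threshold Genome-wide significance level.
#' @return An `sds_tbl` tibble: `variant_id`, `chrom`, `pos`, `daf` (pooled),
#'   per-dataset `raw_*` and `z_*`, `meta_z`, `final_z`, `p`, `significant`.
#' @export
sds_scan <- function(panel, catalog, layout, maf_min = 0.01,
                     scheme = bin_scheme(), min_class_count = 10,
                     sig_threshold = 5e-8) {
  stopifnot(inherits(panel, "haplotype_panel"))
  datasets <- unique(panel$samples$dataset)
  n_by_ds <- table(panel$samples$dataset)[datasets]
  pooled <- compute_daf(panel)

  per_ds <- list()
  for (ds in datasets) {
    ids <- panel$samples$sample_id[panel$samples$dataset == ds]
    daf_ds <- compute_daf(panel, ids)
    maf <- pmin(daf_ds$daf, 1 - daf_ds$daf)
    cand <- daf_ds[maf >= maf_min, c("variant_id", "chrom", "pos", "daf")]
    cand <- cand[!is.na(arm_index(layout, cand$chrom, cand$pos)), ]
    if (nrow(cand) == 0) next
    obs <- gap_lengths(panel, catalog, ds, layout, cand)
    # skip variants within one median gap of an arm end
    med_gap <- median(obs$gap, na.rm = TRUE)
    if (is.finite(med_gap)) {
      a <- layout$arms[arm_index(layout, cand$chrom, cand$pos), ]
      edge <- (cand$pos - 1 - a$start) < med_gap |
        (a$end - (cand$pos - 1)) < med_gap
      cand <- cand[!edge, ]
      obs <- obs[obs$variant_id %in% cand$variant_id, ]
    }
    if (nrow(cand) == 0) next
    fit <- fit_raw_sds(obs, min_class_count = min_class_count)
    fit <- left_join(fit, cand, by = "variant_id")
    scored <- fit[fit$reason == "ok", ]
    if (nrow(scored) < 2) next
    std <- bin_standardize(
      scored[, c("variant_id", "raw", "daf")], scheme
    )
    per_ds[[ds]] <- std %>%
      select("variant_id", "raw", "z") %>%
      rename(!!paste0("raw_", ds) := "raw", !!paste0("z_", ds) := "z")
  }
  if (length(per_ds) < length(datasets)) {
    abort("a dataset produced no scored variants")
  }
  joined <- purrr::reduce(
    per_ds, ~ dplyr::inner_join(.x, .y, by = "variant_id")
  )
  if (nrow(joined) < 2) abort("fewer than 2 variants scored in all datasets")
  zmat <- as.matrix(joined[, paste0("z_", datasets)])
  meta <- meta_analyze(zmat, as.numeric(n_by_ds), sig_threshold)
  out <- pooled %>%
    select("variant_id", "chrom", "pos", "daf") %>%
    dplyr::inner_join(bind_cols(joined, meta), by = "variant_id") %>%
    arrange(.data$chrom, .data$pos)
  class(out) <- c("sds_tbl", class(out))
  out
}
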