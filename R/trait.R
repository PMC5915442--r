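#' Rank-based normalization of selection z-scores
#'
#' Maps the genome-wide final z to exact normal scores:
#' `qnorm((rank - 0.5) / M)` with average ranks for ties. Order-preserving;
#' robust to heavy tails of the raw score distribution.
#'
#' @param z Numeric vector (length >= 2).
#' @return Numeric vector of normalized scores.
#' @export
rank_normalize <- function(z) {
  if (length(z) < 2) abort("need at least 2 values to rank-normalize")
  r <- rank(z, ties.method = "average")
  qnorm((r - 0.5) / length(z))
}

#' Squared haplotype correlation between two panel sites
#'
#' r^2 computed from phased haplotypes: with haplotype frequencies
#' `D = p_AB - p_A p_B`, `r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`, which
#' equals the squared Pearson correlation of the two 0/1 haplotype vectors.
#'
#' @param panel A [haplotype_panel()].
#' @param id_a,id_b Variant ids.
#' @return Scalar r^2 (NA if either site is monomorphic).
#' @export
hap_r2 <- function(panel, id_a, id_b) {
  ja <- match(id_a, panel$sites$variant_id)
  jb <- match(id_b, panel$sites$variant_id)
  if (is.na(ja) || is.na(jb)) abort("variant not in panel")
  x <- as.vector(panel$haps[, ja])
  y <- as.vector(panel$haps[, jb])
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Map trait variants onto scored variants via LD proxies
#'
#' Each trait-associated variant maps to itself when it is scored; otherwise
#' to the scored variant with maximal haplotype r^2 within `window_bp`,
#' provided `r^2 > r2_min`. Unmapped variants are dropped (count attached as
#' attribute `n_dropped`); trait variants landing on the same proxy are
#' collapsed to one to avoid double counting.
#'
#' @param set Tibble of trait variants: `variant_id`, `chrom`, `pos`.
#' @param panel A [haplotype_panel()] providing the haplotypes for r^2.
#' @param scored_ids Ids of scored variants.
#' @param r2_min Minimum r^2 (exclusive) for a proxy.
#' @param window_bp Proxy search window around the trait variant.
#' @return Tibble `variant_id` (trait), `mapped_id`, `r2`; attribute
#'   `n_dropped`.
#' @export
ld_proxy_expand <- function(set, panel, scored_ids, r2_min = 0.5,
                            window_bp = 1e6) {
  set <- distinct(as_tibble(set))
  sites <- panel$sites
  scored <- sites[sites$variant_id %in% scored_ids, ]
  res <- purrr::map_dfr(seq_len(nrow(set)), function(i) {
    vid <- set$variant_id[i]
    if (vid %in% scored_ids) {
      return(tibble(variant_id = vid, mapped_id = vid, r2 = 1))
    }
    j <- match(vid, sites$variant_id)
    if (is.na(j)) return(NULL)  # not in panel: cannot compute LD
    near <- scored[scored$chrom == set$chrom[i] &
                     abs(scored$pos - set$pos[i]) <= window_bp, ]
    if (nrow(near) == 0) return(NULL)
    x <- as.vector(panel$haps[, j])
    if (sd(x) == 0) return(NULL)
    jn <- match(near$variant_id, sites$variant_id)
    Y <- as.matrix(panel$haps[, jn, drop = FALSE])
    r2 <- suppressWarnings(as.vector(cor(x, Y))^2)
    r2[is.na(r2)] <- 0
    best <- which.max(r2)
    if (r2[best] <= r2_min) return(NULL)
    tibble(variant_id = vid, mapped_id = near$variant_id[best], r2 = r2[best])
  })
  if (nrow(res) > 0) {
    res <- res %>%
      group_by(.data$mapped_id) %>%
      slice(1) %>%
      ungroup()
  }
  attr(res, "n_dropped") <- nrow(set) - nrow(res)
  res
}

#' Chi-square sum test for one trait variant set
#'
#' The statistic is the sum of squared rank-normalized z over the trait's
#' mapped variants, compared to a chi-square distribution with k degrees of
#' freedom (k = number of variants). `inflation = S / k` is 1 under the null;
#' the test is indifferent to the sign of z (enrichment regardless of allelic
#' direction).
#'
#' @param zprime Rank-normalized z values of the mapped set (k >= 1).
#' @param trait Trait label.
#' @param category Trait category label.
#' @return One-row tibble: `trait`, `category`, `k`, `statistic`,
#'   `inflation`, `p`.
#' @export
chi2_sum_test <- function(zprime, trait = "trait", category = NA_character_) {
  if (length(zprime) < 1) abort("empty variant set")
  s <- sum(zprime^2)
  k <- length(zprime)
  tibble(
    trait = trait, category = category, k = k, statistic = s,
    inflation = s / k, p = pchisq(s, df = k, lower.tail = FALSE)
  )
}

#' Multiple-testing control across traits
#'
#' Bonferroni flags significance at `alpha / n_tests` (the fixed-threshold
#' rule); Benjamini-Hochberg returns step-up q-values with significance at
#' `q < alpha`.
#'
#' @param p P-values.
#' @param n_tests Number of tests (defaults to `length(p)`).
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha Family-wise level.
#' @return Tibble `p`, `significant`, plus `threshold` (bonferroni) or `q`
#'   (bh).
#' @export
multiple_testing <- function(p, n_tests = length(p),
                             method = c("bonferroni", "bh"), alpha = 0.05) {
  stopifnot(n_tests >= 1)
  method <- match.arg(method)
  if (method == "bonferroni") {
    thr <- alpha / n_tests
    tibble(p = p, significant = p < thr, threshold = thr)
  } else {
    q <- p.adjust(p, method = "BH", n = n_tests)
    tibble(p = p, significant = q < alpha, q = q)
  }
}

#' Selection-signature enrichment scan over trait variant sets
#'
#' Rank-normalizes the genome-wide final z, maps each trait set onto scored
#' variants via LD proxies, applies the chi-square sum test per trait, and
#' attaches Bonferroni flags (threshold `alpha / n_traits`) and BH q-values.
#'
#' @param sets Tibble `trait`, `category`, `variant_id`, `chrom`, `pos`.
#' @param sds An `sds_tbl` from [sds_scan()].
#' @param panel A [haplotype_panel()] for LD proxies.
#' @param r2_min,window_bp Proxy parameters (see [ld_proxy_expand()]).
#' @param alpha Family-wise level.
#' @param exclude Optional interval tibble: scored variants inside are
#'   removed before rank normalization and mapped variants inside are
#'   dropped (the locus-removal sensitivity analysis).
#' @return An `enrich_tbl` tibble: one row per testable trait with `k`,
#'   `statistic`, `inflation`, `p`, `bonferroni_significant`, `q`,
#'   `fdr_significant`; traits with no mapped variants are reported with
#'   `reason = "unmapped"`.
#' @export
trait_enrichment_scan <- function(sets, sds, panel, r2_min = 0.5,
                                  window_bp = 1e6, alpha = 0.05,
                                  exclude = NULL) {
  sets <- as_tibble(sets)
  sds <- as_tibble(sds)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    keep <- !position_in_intervals(sds$chrom, sds$pos, exclude)
    sds <- sds[keep, ]
  }
  if (nrow(sds) < 2) abort("fewer than 2 scored variants")
  zp <- tibble(
    variant_id = sds$variant_id,
    zprime = rank_normalize(sds$final_z)
  )
  traits <- unique(sets$trait)
  recs <- purrr::map_dfr(traits, function(tr) {
    st <- sets[sets$trait == tr, ]
    mapped <- ld_proxy_expand(
      st[, c("variant_id", "chrom", "pos")], panel, zp$variant_id,
      r2_min = r2_min, window_bp = window_bp
    )
    if (nrow(mapped) == 0) {
      return(tibble(
        trait = tr, category = st$category[1], k = 0L,
        statistic = NA_real_, inflation = NA_real_, p = NA_real_,
        reason = "unmapped"
      ))
    }
    z <- zp$zprime[match(mapped$mapped_id, zp$variant_id)]
    chi2_sum_test(z, trait = tr, category = st$category[1]) %>%
      mutate(reason = "ok")
  })
  tested <- !is.na(recs$p)
  recs$bonferroni_significant <- NA
  recs$bonferroni_threshold <- NA_real_
  recs$q <- NA_real_
  recs$fdr_significant <- NA
  if (any(tested)) {
    bonf <- multiple_testing(
      recs$p[tested], n_tests = sum(tested), method = "bonferroni",
      alpha = alpha
    )
    bh <- multiple_testing(
      recs$p[tested], n_tests = sum(tested), method = "bh", alpha = alpha
    )
    recs$bonferroni_significant[tested] <- bonf$significant
    recs$bonferroni_threshold <- bonf$threshold[1]
    recs$q[tested] <- bh$q
    recs$fdr_significant[tested] <- bh$significant
  }
  class(recs) <- c("enrich_tbl", class(recs))
  recs
}

#' Locus-removal sensitivity rerun
#'
#' Re-runs the trait enrichment scan with the given genomic loci excluded:
#' scored variants inside the exclusion intervals are removed, rank
#' normalization is recomputed on the remaining genome-wide variants, mapped
#' variants inside the loci are dropped, and BH control is applied.
#'
#' @param sets,sds,panel,r2_min,window_bp,alpha As in
#'   [trait_enrichment_scan()].
#' @param exclusion Interval tibble of loci to remove.
#' @return An `enrich_tbl` tibble.
#' @export
locus_removal_rerun <- function(sets, sds, panel, exclusion, r2_min = 0.5,
                                window_bp = 1e6, alpha = 0.05) {
  trait_enrichment_scan(
    sets, sds, panel, r2_min = r2_min, window_bp = window_bp,
    alpha = alpha, exclude = exclusion
  )
}
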