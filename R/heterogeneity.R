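#' Derived allele frequency heterogeneity index
#'
#' Pearson's chi-square statistic of the subpopulation x {derived, ancestral}
#' allele-count table divided by the total allele count N. The index ranges
#' from 0 (identical frequencies everywhere) to 1 (complete separation);
#' for a 2x2 table it equals the squared phi coefficient, and the Cramer
#' bound with df = 1 keeps it <= 1 for any number of subpopulations.
#'
#' @param counts Tibble with columns `subpop`, `derived`, `ancestral`
#'   (non-negative integer allele counts). Rows with zero total alleles are
#'   dropped with a warning. Monomorphic tables return 0 by convention.
#' @return The heterogeneity index, a scalar in [0, 1].
#' @export
heterogeneity_index <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("subpop", "derived", "ancestral") %in% names(counts)))
  if (any(counts$derived < 0) || any(counts$ancestral < 0))
    abort("negative allele count")
  tot <- counts$derived + counts$ancestral
  if (any(tot == 0)) {
    warn("dropping subpopulation(s) with zero total alleles")
    counts <- counts[tot > 0, ]
  }
  n_all <- sum(counts$derived) + sum(counts$ancestral)
  if (n_all == 0) abort("empty contingency table")
  if (sum(counts$derived) == 0 || sum(counts$ancestral) == 0) return(0)
  if (nrow(counts) < 2) return(0)
  chi2 <- suppressWarnings(
    chisq.test(cbind(counts$derived, counts$ancestral), correct = FALSE)
  )$statistic
  unname(chi2) / n_all
}

#' Frequency-matched empirical null for the heterogeneity index
#'
#' The null for a focal variant is the set of heterogeneity indices of all
#' scored variants whose pooled DAF lies within `half_width` of the focal DAF
#' (closed interval), excluding the focal variant itself. Sparse bins are
#' widened symmetrically in `half_width` steps until `min_null` variants are
#' available; the widening is flagged.
#'
#' @param pool Tibble of scored variants: `variant_id`, `daf` (pooled), `h`.
#' @param focal_daf Pooled DAF of the focal variant.
#' @param focal_id Optional id excluded from the null.
#' @param half_width DAF bin half-width.
#' @param min_null Minimum null size.
#' @return List: `h` (null values), `half_width_used`, `widened`.
#' @export
binned_null <- function(pool, focal_daf, focal_id = NULL,
                        half_width = 0.005, min_null = 100) {
  pool <- as_tibble(pool)
  if (!is.null(focal_id)) pool <- pool[pool$variant_id != focal_id, ]
  hw <- half_width
  repeat {
    sel <- abs(pool$daf - focal_daf) <= hw + 1e-12
    if (sum(sel) >= min_null || hw >= 1) break
    hw <- hw + half_width
  }
  list(
    h = pool$h[sel],
    half_width_used = hw,
    widened = hw > half_width
  )
}

#' Heterogeneity enrichment against an empirical null
#'
#' Fold change is the observed index over the null mean; the one-tailed
#' enrichment P is the add-one empirical exceedance probability, with ties
#' (null >= observed) counting against enrichment.
#'
#' @param h_obs Observed heterogeneity index.
#' @param null Numeric vector of null indices (non-empty).
#' @return Tibble `fold`, `p`, `null_n`, `null_mean`.
#' @export
enrichment <- function(h_obs, null) {
  if (length(null) == 0) abort("empty null distribution")
  nm <- mean(null)
  tibble(
    fold = if (nm > 0) h_obs / nm else NA_real_,
    p = (1 + sum(null >= h_obs)) / (1 + length(null)),
    null_n = length(null),
    null_mean = nm
  )
}

#' Heterogeneity indices for many variants at once
#'
#' @param counts_long Long tibble `variant_id`, `subpop`, `derived`,
#'   `ancestral`.
#' @return Tibble `variant_id`, `daf` (pooled across subpopulations), `h`.
#' @export
het_index_by_variant <- function(counts_long) {
  counts_long <- as_tibble(counts_long)
  counts_long %>%
    group_by(.data$variant_id) %>%
    summarise(
      daf = sum(.data$derived) / sum(.data$derived + .data$ancestral),
      h = heterogeneity_index(dplyr::pick("subpop", "derived", "ancestral"))
    )
}

#' DAF heterogeneity enrichment test for focal variants
#'
#' For each focal variant (typically a genome-wide-significant selection hit)
#' computes the heterogeneity index, the frequency-matched null, the fold
#' change over the null mean, and the one-tailed enrichment P.
#'
#' @param pool Tibble `variant_id`, `daf`, `h` for all scored variants
#'   (e.g. from [het_index_by_variant()]).
#' @param focal_ids Variant ids to test (must be in `pool`).
#' @param half_width DAF bin half-width.
#' @param min_null Minimum null size before widening.
#' @return A `het_tbl` tibble: `variant_id`, `daf`, `h`, `null_n`,
#'   `null_mean`, `half_width_used`, `widened`, `fold`, `p`.
#' @export
daf_heterogeneity_test <- function(pool, focal_ids, half_width = 0.005,
                                   min_null = 100) {
  pool <- as_tibble(pool)
  if (!all(focal_ids %in% pool$variant_id))
    abort("focal variant absent from the scored pool")
  out <- purrr::map_dfr(focal_ids, function(id) {
    row <- pool[pool$variant_id == id, ][1, ]
    nl <- binned_null(pool, row$daf, focal_id = id,
                      half_width = half_width, min_null = min_null)
    er <- enrichment(row$h, nl$h)
    tibble(
      variant_id = id, daf = row$daf, h = row$h,
      null_n = er$null_n, null_mean = er$null_mean,
      half_width_used = nl$half_width_used, widened = nl$widened,
      fold = er$fold, p = er$p
    )
  })
  class(out) <- c("het_tbl", class(out))
  out
}
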