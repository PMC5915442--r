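#' Identify singletons and private doubletons in one dataset
#'
#' A singleton is a site whose derived allele occurs on exactly one haplotype
#' of the dataset; a private doubleton occurs twice with both copies in one
#' individual (homozygous derived). Both are treated as one rare event at one
#' position on one individual by every downstream step. Entries are never
#' deleted by the filters, only flagged, so the catalog's cardinality is
#' constant through the module.
#'
#' @param panel A [haplotype_panel()].
#' @param dataset Dataset label to scan.
#' @return Singleton catalog tibble: `chrom`, `pos`, `sample_id`, `class`,
#'   `dataset`, `retained`, `reason`.
#' @export
extract_singletons <- function(panel, dataset) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ds_samples <- panel$samples$sample_id[panel$samples$dataset == dataset]
  if (length(ds_samples) == 0)
    abort(paste0("unknown dataset label: ", dataset))
  rows <- hap_rows(panel, ds_samples)
  M <- panel$haps[rows, , drop = FALSE]
  ac <- Matrix::colSums(M)
  cand <- which(ac == 1 | ac == 2)
  if (length(cand) == 0) return(empty_catalog())
  trip <- Matrix::summary(M[, cand, drop = FALSE])
  trip$sample <- (trip$i + 1L) %/% 2L
  by_col <- split(trip$sample, trip$j)
  col_ids <- as.integer(names(by_col))
  cls <- vapply(by_col, function(s) {
    if (length(s) == 1) return("singleton")
    if (length(s) == 2 && s[1] == s[2]) return("private-doubleton")
    ""
  }, "")
  keep <- nzchar(cls)
  if (!any(keep)) return(empty_catalog())
  carrier <- vapply(by_col[keep], `[[`, 0L, 1L)
  site_idx <- cand[col_ids[keep]]
  tibble(
    chrom = panel$sites$chrom[site_idx],
    pos = panel$sites$pos[site_idx],
    sample_id = ds_samples[carrier],
    class = unname(cls[keep]),
    dataset = dataset,
    retained = TRUE,
    reason = "none"
  ) %>% arrange(.data$chrom, .data$pos)
}

empty_catalog <- function() {
  tibble(
    chrom = character(), pos = integer(), sample_id = character(),
    class = character(), dataset = character(), retained = logical(),
    reason = character()
  )
}

#' Flag catalog entries inside an exclusion mask
#'
#' Entries whose position falls in the mask (0-based half-open intervals, so a
#' 1-based position at `start + 1` is removed and one at `end + 1` retained)
#' get `retained = FALSE`, `reason = "mask"`. Retained + removed always equals
#' the catalog total.
#'
#' @param catalog A singleton catalog.
#' @param mask Interval tibble.
#' @return The catalog with updated flags.
#' @export
apply_mask <- function(catalog, mask) {
  if (nrow(catalog) == 0) return(catalog)
  hit <- position_in_intervals(catalog$chrom, catalog$pos, mask)
  flag <- hit & catalog$retained
  catalog$retained[flag] <- FALSE
  catalog$reason[flag] <- "mask"
  catalog
}

#' Remove singletons in abnormally dense windows
#'
#' Counts retained entries in half-overlapping sliding windows (window length
#' twice the step, tiled from 0 over every window intersecting an analyzable
#' arm), computes the per-dataset mean and SD over all such windows (empty
#' ones included), and flags entries lying in any window whose count strictly
#' exceeds `mean + k_sd * SD`. Such pileups are the footprint of
#' variant-calling artifacts rather than genuine rare variation.
#'
#' @param catalog A singleton catalog (mask-filtered).
#' @param layout A [genome_layout()].
#' @param window_bp Window length (bp).
#' @param step_bp Step; defaults to `window_bp / 2` (half-overlap).
#' @param k_sd SD multiplier for the one-sided high-tail threshold.
#' @param fixed_threshold Optional named numeric (per dataset) or scalar: use
#'   these thresholds instead of recomputing mean/SD, e.g. to re-apply a
#'   previous run's cutoffs (the filter is then idempotent).
#' @return List: `catalog` (updated flags) and `report`, a `density_report`
#'   with per-window counts and the per-dataset summary
#'   (`threshold = mean + k_sd * SD` exactly when recomputed).
#' @export
density_filter <- function(catalog, layout, window_bp = 20000,
                           step_bp = window_bp / 2, k_sd = 4.0,
                           fixed_threshold = NULL) {
  if (window_bp <= 0) abort("window_bp must be positive")
  stopifnot(inherits(layout, "genome_layout"), step_bp > 0)
  grid <- window_grid(layout, window_bp, step_bp)
  datasets <- unique(catalog$dataset)
  windows <- NULL
  summaries <- NULL
  for (ds in datasets) {
    ent <- catalog[catalog$dataset == ds & catalog$retained, ]
    counts <- rep(0L, nrow(grid))
    if (nrow(ent) > 0) {
      for (cm in unique(ent$chrom)) {
        gi <- which(grid$chrom == cm)
        if (!length(gi)) next
        p0 <- ent$pos[ent$chrom == cm] - 1  # 0-based
        # window k covers [k*step, k*step + window); entry hits windows
        # floor(p0/step) down to floor((p0 - window)/step) + 1
        hi <- floor(p0 / step_bp)
        lo <- pmax(0, floor((p0 - window_bp) / step_bp) + 1)
        ks <- unlist(purrr::map2(lo, hi, seq))
        tab <- table(factor(ks, levels = grid$window_id[gi]))
        counts[gi] <- counts[gi] + as.integer(tab)
      }
    }
    mu <- mean(counts)
    sdev <- sd(counts)
    if (is.null(fixed_threshold)) {
      thr <- mu + k_sd * sdev
    } else if (!is.null(names(fixed_threshold))) {
      thr <- unname(fixed_threshold[ds])
    } else {
      thr <- fixed_threshold[1]
    }
    flagged <- counts > thr
    windows <- bind_rows(windows, mutate(
      grid, dataset = ds, count = counts, flagged = flagged
    ))
    summaries <- bind_rows(summaries, tibble(
      dataset = ds, window_bp = window_bp, step_bp = step_bp, k_sd = k_sd,
      n_windows = nrow(grid), mean = mu, sd = sdev, threshold = thr,
      n_flagged = sum(flagged)
    ))
    # flag entries covered by >= 1 over-threshold window
    if (any(flagged) && nrow(ent) > 0) {
      bad <- grid[flagged, ]
      idx <- which(catalog$dataset == ds & catalog$retained)
      hit <- position_in_intervals(
        catalog$chrom[idx], catalog$pos[idx],
        bad %>% select("chrom", "start", "end")
      )
      catalog$retained[idx[hit]] <- FALSE
      catalog$reason[idx[hit]] <- "density"
    }
  }
  report <- structure(
    list(windows = windows, summary = summaries),
    class = "density_report"
  )
  list(catalog = catalog, report = report)
}

# all windows (tiled from 0 at the given step) that intersect any arm
window_grid <- function(layout, window_bp, step_bp) {
  purrr::map_dfr(unique(layout$arms$chrom), function(cm) {
    arms <- layout$arms[layout$arms$chrom == cm, ]
    len <- layout$chromosomes$length[layout$chromosomes$chrom == cm]
    k_max <- floor((len - 1) / step_bp)
    k <- 0:k_max
    start <- k * step_bp
    end <- pmin(start + window_bp, len)
    keep <- purrr::map_lgl(seq_along(k), function(i) {
      any(start[i] < arms$end & end[i] > arms$start)
    })
    tibble(
      chrom = cm, window_id = k[keep], start = start[keep], end = end[keep]
    )
  })
}

#' @export
#' @method print density_report
print.density_report <- function(x, ...) {
  cat("<density_report>\n")
  print(x$summary)
  invisible(x)
}

#' @export
#' @method tidy density_report
tidy.density_report <- function(x, ...) x$windows

#' @export
#' @method glance density_report
glance.density_report <- function(x, ...) x$summary
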