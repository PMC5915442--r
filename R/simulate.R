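#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The generator emulates
#' the statistical structure that the singleton-density machinery assumes:
#' several WGS datasets of unequal size; common variants with known derived
#' allele frequencies and independently assigned haplotypes; singletons placed
#' along each haplotype as a Poisson process whose rate drops by a factor
#' `rho < 1` around a selected locus, but only on haplotypes carrying the
#' derived core allele (the tip-branch shortening a recent allele-frequency
#' rise produces); regional allele-frequency structure under Balding-Nichols
#' drift; introgression tract sets; and trait-associated variant sets
#' optionally concentrated at selected loci.
#'
#' Defaults mirror the study design the package emulates: three datasets of
#' 1276, 492 and 466 samples; seven geographic regions with cohort proportions
#' 7910, 10907, 95272, 9390, 26160, 15818 and 5719 out of 171,176; drift
#' F = 0.0047 (the observed differentiation between the two major clusters).
#' The per-haplotype singleton rate `lambda0` = 5e-5 / bp and the 100-kb
#' selected-window half-width are desk-scale choices discussed in the
#' methods vignette.
#'
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @param layout A [genome_layout()].
#' @param sample_sizes Per-dataset sample counts (datasets are labelled
#'   `d1`, `d2`, ...). Each must be >= 2.
#' @param n_common Number of common variants to place.
#' @param lambda0 Baseline singleton rate per bp per haplotype.
#' @param selected Tibble of selected loci: `chrom`, `pos`, `daf`,
#'   `rho` (rate multiplier in (0, 1]), `half_width` (bp).
#' @param regions Tibble `region`, `prop`, `f` (drift parameter in [0, 1)).
#' @param f_selected_multiplier Drift inflation factor applied to selected
#'   variants in [simulate_regional_counts()] (capped so F < 1).
#' @param gwas_n Total genotyped cohort size regional counts are drawn for.
#' @param daf_range Range of the uniform ancestral DAF distribution for
#'   common sites.
#' @param doubleton_fraction Fraction of rare events emitted as private
#'   doubletons (both haplotypes of one individual) instead of singletons.
#' @param ld_copy_prob Within a selected-locus window, each haplotype copies
#'   its core-site allele onto the window's other common sites with this
#'   probability (else the site keeps its independent draw). This is the
#'   generator's only source of linkage: it gives window variants an expected
#'   r^2 of about `ld_copy_prob^2` with the core allele, so LD-proxy lookup
#'   and trait-set enrichment have real structure to find. Set to 0 for fully
#'   independent sites.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(seed = 1,
                       layout = toy_layout(),
                       sample_sizes = c(1276, 492, 466),
                       n_common = 2000,
                       lambda0 = 5e-5,
                       selected = NULL,
                       regions = japan_regions(),
                       f_selected_multiplier = 10,
                       gwas_n = 171176,
                       daf_range = c(0.05, 0.95),
                       doubleton_fraction = 0.02,
                       ld_copy_prob = 0.9) {
  if (is.null(selected)) {
    selected <- tibble(
      chrom = character(), pos = integer(), daf = numeric(),
      rho = numeric(), half_width = numeric()
    )
  }
  selected <- as_tibble(selected)
  regions <- as_tibble(regions)
  stopifnot(
    inherits(layout, "genome_layout"),
    all(sample_sizes >= 2),
    n_common >= 0, lambda0 > 0,
    all(selected$rho > 0 & selected$rho <= 1),
    all(regions$f >= 0 & regions$f < 1),
    abs(sum(regions$prop) - 1) < 1e-8,
    daf_range[1] > 0, daf_range[2] < 1, daf_range[1] < daf_range[2],
    doubleton_fraction >= 0, doubleton_fraction < 1,
    ld_copy_prob >= 0, ld_copy_prob <= 1
  )
  if (nrow(selected) > 0) {
    a <- arm_index(layout, selected$chrom, selected$pos)
    if (anyNA(a)) abort("selected locus outside every chromosome arm")
    arms <- layout$arms[a, ]
    if (any(selected$pos - 1 - selected$half_width < arms$start) ||
        any(selected$pos - 1 + selected$half_width >= arms$end))
      abort("selected-locus window exceeds its chromosome arm")
  }
  structure(
    list(
      seed = as.integer(seed), layout = layout,
      sample_sizes = as.integer(sample_sizes), n_common = as.integer(n_common),
      lambda0 = lambda0, selected = selected, regions = regions,
      f_selected_multiplier = f_selected_multiplier, gwas_n = gwas_n,
      daf_range = daf_range, doubleton_fraction = doubleton_fraction,
      ld_copy_prob = ld_copy_prob
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
japan_regions <- function() {
  n <- c(
    Hokkaido = 7910, Tohoku = 10907, `Kanto-Koshinetsu` = 95272,
    `Chubu-Hokuriku` = 9390, Kinki = 26160, Kyushu = 15818, Okinawa = 5719
  )
  tibble(region = names(n), prop = as.numeric(n) / sum(n), f = 0.0047)
}

#' Simulate a phased haplotype panel with planted singleton structure
#'
#' Common sites are drawn at configured DAFs with haplotypes assigned
#' independently; singletons are placed on each haplotype as a Poisson process
#' with rate `lambda0`, thinned to `rho * lambda0` inside the window of a
#' selected locus on haplotypes carrying the derived core allele. A fraction
#' of rare events is emitted as private doubletons. Deterministic for a fixed
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List: `panel` (the [haplotype_panel()]), `truth_singletons`
#'   (tibble of planted rare events: `chrom`, `pos`, `sample_id`, `class`,
#'   `dataset`), `truth` (tibble of selected loci with their true parameters).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "panel"), {
    layout <- config$layout
    arms <- layout$arms
    n_tot <- sum(config$sample_sizes)
    datasets <- rep(
      paste0("d", seq_along(config$sample_sizes)), config$sample_sizes
    )
    samples <- tibble(
      sample_id = sprintf("s%04d", seq_len(n_tot)),
      dataset = datasets,
      region = sample(
        config$regions$region, n_tot, replace = TRUE,
        prob = config$regions$prop
      )
    )

    # ---- common sites ----
    arm_len <- arms$end - arms$start
    n_per_arm <- as.vector(
      stats::rmultinom(1, config$n_common, arm_len / sum(arm_len))
    )
    common <- purrr::map_dfr(seq_len(nrow(arms)), function(a) {
      k <- n_per_arm[a]
      if (k == 0) return(NULL)
      tibble(
        chrom = arms$chrom[a],
        pos = sort(sample.int(arm_len[a], k)) + as.integer(arms$start[a])
      )
    })
    common$daf <- runif(nrow(common), config$daf_range[1], config$daf_range[2])
    common$core <- FALSE
    if (nrow(config$selected) > 0) {
      sel <- config$selected %>%
        mutate(core = TRUE) %>%
        select("chrom", "pos", "daf", "core")
      common <- common %>%
        dplyr::anti_join(sel, by = c("chrom", "pos")) %>%
        bind_rows(sel) %>%
        arrange(.data$chrom, .data$pos)
    }
    m_common <- nrow(common)
    hap_draw <- matrix(
      runif(2 * n_tot * m_common) < rep(common$daf, each = 2 * n_tot),
      nrow = 2 * n_tot
    )
    # haplotype-block copying inside selected windows induces LD with the core
    if (nrow(config$selected) > 0 && config$ld_copy_prob > 0) {
      for (s in seq_len(nrow(config$selected))) {
        loc <- config$selected[s, ]
        core_j <- which(common$chrom == loc$chrom & common$pos == loc$pos)
        wj <- which(common$chrom == loc$chrom &
                      abs(common$pos - loc$pos) <= loc$half_width &
                      !common$core)
        if (!length(wj)) next
        copy <- matrix(
          runif(2 * n_tot * length(wj)) < config$ld_copy_prob,
          nrow = 2 * n_tot
        )
        hap_draw[, wj][copy] <- hap_draw[, core_j][row(copy)[copy]]
      }
    }

    # ---- singleton processes, per haplotype per arm ----
    hap_ds <- rep(datasets, each = 2)
    events <- purrr::map_dfr(seq_len(nrow(arms)), function(a) {
      counts <- rpois(2 * n_tot, config$lambda0 * arm_len[a])
      k <- sum(counts)
      if (k == 0) return(NULL)
      tibble(
        hap = rep(seq_len(2 * n_tot), counts),
        chrom = arms$chrom[a],
        pos = as.integer(floor(runif(k, arms$start[a], arms$end[a]))) + 1L
      )
    })
    # thinning inside selected windows for derived-core carriers
    if (nrow(config$selected) > 0 && nrow(events) > 0) {
      drop <- rep(FALSE, nrow(events))
      for (s in seq_len(nrow(config$selected))) {
        loc <- config$selected[s, ]
        j <- which(common$chrom == loc$chrom & common$pos == loc$pos)
        carriers <- which(hap_draw[, j])
        inw <- events$chrom == loc$chrom &
          abs(events$pos - loc$pos) <= loc$half_width &
          events$hap %in% carriers
        drop[inw] <- drop[inw] | (runif(nrow(events))[inw] >= loc$rho)
      }
      events <- events[!drop, , drop = FALSE]
    }
    if (nrow(events) > 0) {
      # unique site positions; avoid collisions with common sites
      events <- events %>%
        dplyr::anti_join(common, by = c("chrom", "pos")) %>%
        distinct(.data$chrom, .data$pos, .keep_all = TRUE)
      events$class <- ifelse(
        runif(nrow(events)) < config$doubleton_fraction,
        "private-doubleton", "singleton"
      )
      events$sample <- (events$hap + 1L) %/% 2L
    }

    # ---- assemble sparse haplotype matrix ----
    sites <- bind_rows(
      common %>% mutate(kind = "common"),
      events %>% select("chrom", "pos") %>% mutate(kind = "rare")
    ) %>%
      arrange(.data$chrom, .data$pos)
    site_key <- paste0(sites$chrom, ":", sites$pos)
    col_of <- setNames(seq_len(nrow(sites)), site_key)

    ci <- which(hap_draw, arr.ind = TRUE)
    common_cols <- col_of[paste0(common$chrom, ":", common$pos)]
    trip_i <- ci[, 1]
    trip_j <- common_cols[ci[, 2]]
    if (nrow(events) > 0) {
      ev_col <- col_of[paste0(events$chrom, ":", events$pos)]
      sing <- events$class == "singleton"
      trip_i <- c(
        trip_i, events$hap[sing],
        2L * events$sample[!sing] - 1L, 2L * events$sample[!sing]
      )
      trip_j <- c(trip_j, ev_col[sing], ev_col[!sing], ev_col[!sing])
    }
    haps <- Matrix::sparseMatrix(
      i = trip_i, j = trip_j, x = 1,
      dims = c(2 * n_tot, nrow(sites))
    )
    panel <- haplotype_panel(
      sites = tibble(
        chrom = sites$chrom, pos = sites$pos, anc = "A", der = "G"
      ),
      haps = haps, samples = samples
    )
    truth_singletons <- if (nrow(events) > 0) {
      tibble(
        chrom = events$chrom, pos = events$pos,
        sample_id = samples$sample_id[events$sample],
        class = events$class,
        dataset = samples$dataset[events$sample]
      ) %>% arrange(.data$chrom, .data$pos)
    } else {
      tibble(
        chrom = character(), pos = integer(), sample_id = character(),
        class = character(), dataset = character()
      )
    }
    truth <- config$selected %>%
      mutate(variant_id = paste0(.data$chrom, ":", .data$pos))
    list(panel = panel, truth_singletons = truth_singletons, truth = truth)
  })
}

#' Simulate subpopulation allele counts under Balding-Nichols drift
#'
#' Per region, the derived allele frequency is drawn from
#' `Beta(daf (1 - F) / F, (1 - daf)(1 - F) / F)` around the pooled `daf`
#' (`F -> 0` collapses to `daf` itself) and allele counts are binomial given
#' region sizes. Variants flagged `selected` use drift inflated by
#' `f_selected_multiplier`, emulating the regionally heterogeneous frequency
#' spectra selection leaves behind. `daf` of 0 or 1 yields the degenerate
#' all-ancestral / all-derived table.
#'
#' @param config A [sim_config()].
#' @param daf Pooled derived allele frequency (vectorized).
#' @param selected Logical (recycled): inflate drift for these variants.
#' @param variant_id Optional ids (default `v1`, `v2`, ...).
#' @return Long tibble: `variant_id`, `subpop`, `derived`, `ancestral`.
#' @export
simulate_regional_counts <- function(config, daf, selected = FALSE,
                                     variant_id = NULL) {
  stopifnot(inherits(config, "sim_config"), all(daf >= 0 & daf <= 1))
  k <- length(daf)
  selected <- rep_len(selected, k)
  if (is.null(variant_id)) variant_id <- paste0("v", seq_len(k))
  regions <- config$regions
  sizes <- round(regions$prop * config$gwas_n)
  with_seed(stage_seed(config$seed, "regional_counts"), {
    purrr::map_dfr(seq_len(nrow(regions)), function(r) {
      f <- ifelse(
        selected,
        pmin(regions$f[r] * config$f_selected_multiplier, 0.999),
        regions$f[r]
      )
      p <- ifelse(
        daf %in% c(0, 1) | f == 0,
        daf,
        rbeta(k, daf * (1 - f) / f, (1 - daf) * (1 - f) / f)
      )
      derived <- rbinom(k, 2 * sizes[r], p)
      # degenerate pooled frequencies stay degenerate
      derived[daf == 0] <- 0L
      derived[daf == 1] <- 2L * sizes[r]
      tibble(
        variant_id = variant_id, subpop = regions$region[r],
        derived = as.integer(derived),
        ancestral = as.integer(2 * sizes[r] - derived)
      )
    }) %>% arrange(match(.data$variant_id, variant_id), .data$subpop)
  })
}

#' Simulate non-overlapping introgression-like tracts
#'
#' Places `n_tracts` equal-length, uniform-random, non-overlapping tracts
#' totalling `total_bp` on the concatenated genome, then maps them back to
#' per-chromosome BED-style intervals.
#'
#' @param config A [sim_config()].
#' @param total_bp Total tract length requested.
#' @param n_tracts Number of tracts.
#' @return Interval tibble (`chrom`, `start`, `end`), normalized.
#' @export
simulate_tracts <- function(config, total_bp, n_tracts) {
  stopifnot(inherits(config, "sim_config"), n_tracts >= 0)
  L <- config$layout$total_bp
  if (total_bp > L) abort("requested tract bp exceeds genome length")
  if (n_tracts == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  len <- floor(total_bp / n_tracts)
  stopifnot(len >= 1)
  with_seed(stage_seed(config$seed, "tracts"), {
    # sample non-overlapping starts: distribute the free space among gaps
    free <- L - n_tracts * len
    cuts <- sort(sample.int(free + 1, n_tracts, replace = TRUE) - 1)
    starts <- cuts + (seq_len(n_tracts) - 1) * len
    glob <- tibble(gstart = starts, gend = starts + len)
    # map global [gstart, gend) back to chromosome intervals (may split)
    off <- layout_offsets(config$layout)
    lens <- config$layout$chromosomes$length
    purrr::map_dfr(seq_len(nrow(glob)), function(i) {
      s <- glob$gstart[i]; e <- glob$gend[i]
      out <- NULL
      while (s < e) {
        ci <- findInterval(s, off$offset)
        cend <- off$offset[ci] + lens[ci]
        piece_end <- min(e, cend)
        out <- bind_rows(out, tibble(
          chrom = off$chrom[ci],
          start = s - off$offset[ci], end = piece_end - off$offset[ci]
        ))
        s <- piece_end
      }
      out
    }) %>% normalize_intervals()
  })
}

#' Simulate trait-associated variant sets
#'
#' Draws `n_traits` sets of `k_per_trait` variants from the scored common
#' variants; a fraction of the sets is "enriched": half of an enriched set's
#' variants are drawn from within the selected-locus windows, emulating
#' trait-associated variants tagging selected haplotypes.
#'
#' @param config A [sim_config()].
#' @param sites Tibble of candidate variants (`variant_id`, `chrom`, `pos`).
#' @param n_traits Number of trait sets.
#' @param k_per_trait Variants per set.
#' @param enriched_fraction Fraction of sets seeded at selected loci.
#' @return List: `sets` (tibble `trait`, `category`, `variant_id`, `chrom`,
#'   `pos`) and `truth` (tibble `trait`, `enriched`).
#' @export
simulate_trait_sets <- function(config, sites, n_traits, k_per_trait,
                                enriched_fraction = 0) {
  stopifnot(
    inherits(config, "sim_config"), n_traits >= 0, k_per_trait >= 1,
    enriched_fraction >= 0, enriched_fraction <= 1
  )
  sites <- as_tibble(sites)
  in_window <- rep(FALSE, nrow(sites))
  if (nrow(config$selected) > 0) {
    for (s in seq_len(nrow(config$selected))) {
      loc <- config$selected[s, ]
      in_window <- in_window |
        (sites$chrom == loc$chrom & abs(sites$pos - loc$pos) <= loc$half_width)
    }
  }
  n_enr <- round(n_traits * enriched_fraction)
  with_seed(stage_seed(config$seed, "trait_sets"), {
    sets <- purrr::map_dfr(seq_len(n_traits), function(t) {
      enriched <- t <= n_enr && any(in_window)
      if (enriched) {
        k_in <- min(ceiling(k_per_trait / 2), sum(in_window))
        idx <- c(
          sample(which(in_window), k_in),
          sample(which(!in_window), k_per_trait - k_in)
        )
      } else {
        idx <- sample.int(nrow(sites), k_per_trait)
      }
      tibble(
        trait = sprintf("trait%03d", t),
        category = if (enriched) "quantitative" else "disease",
        variant_id = sites$variant_id[idx],
        chrom = sites$chrom[idx], pos = sites$pos[idx]
      )
    })
    truth <- tibble(
      trait = sprintf("trait%03d", seq_len(n_traits)),
      enriched = seq_len(n_traits) <= n_enr
    )
    list(sets = distinct(sets), truth = truth)
  })
}
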