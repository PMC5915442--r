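#' Run configuration for the full pipeline
#'
#' Collects every stage parameter with its conventional default: 20-kbp
#' half-overlapping density windows with a +4 SD cutoff, MAF >= 0.01, the
#' 0.005/0.01 DAF bin scheme, genome-wide significance at 5e-8, +/- 0.005
#' heterogeneity bins, 10,000 rotations in increments of 0.01% of the
#' concatenated genome, LD proxies at r^2 > 0.5, and alpha = 0.05. One run
#' seed drives every stage through [stage_seed()], so toggling a stage never
#' shifts another stage's random stream.
#'
#' @param sim A [sim_config()] (its seed is the run seed).
#' @param mask Exclusion-mask interval tibble (default: none).
#' @param stages Character vector of stages to run, in dependency order
#'   among `"simulate"`, `"singletons"`, `"sds"`, `"dafhet"`,
#'   `"introgression"`, `"trait_enrich"`.
#' @param window_bp,step_bp,k_sd Density-filter parameters.
#' @param maf_min Minimum per-dataset MAF for scoring.
#' @param min_class_count Minimum genotype-class occupancy for the score fit.
#' @param sig_threshold Genome-wide significance level.
#' @param het_half_width,het_min_null Heterogeneity-null parameters.
#' @param n_het_pool Number of variants drawn for the regional-count pool.
#' @param tract_total_bp,n_tracts Simulated tract-set size.
#' @param iterations,increment_fraction Rotation-permutation schedule.
#' @param n_traits,k_per_trait,enriched_fraction Simulated trait sets.
#' @param r2_min,ld_window_bp LD-proxy parameters.
#' @param alpha Family-wise level for trait enrichment.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       mask = NULL,
                       stages = c("simulate", "singletons", "sds", "dafhet",
                                  "introgression", "trait_enrich"),
                       window_bp = 20000, step_bp = window_bp / 2, k_sd = 4,
                       maf_min = 0.01, min_class_count = 10,
                       sig_threshold = 5e-8,
                       het_half_width = 0.005, het_min_null = 100,
                       n_het_pool = 2000,
                       tract_total_bp = NULL, n_tracts = 20,
                       iterations = 10000, increment_fraction = 1e-4,
                       n_traits = 10, k_per_trait = 20,
                       enriched_fraction = 0,
                       r2_min = 0.5, ld_window_bp = 1e6, alpha = 0.05) {
  stopifnot(inherits(sim, "sim_config"))
  if (is.null(mask)) {
    mask <- tibble(chrom = character(), start = numeric(), end = numeric())
  }
  if (is.null(tract_total_bp)) {
    tract_total_bp <- round(0.05 * sim$layout$total_bp)
  }
  structure(
    list(
      sim = sim, mask = mask, stages = stages, seed = sim$seed,
      window_bp = window_bp, step_bp = step_bp, k_sd = k_sd,
      maf_min = maf_min, min_class_count = min_class_count,
      sig_threshold = sig_threshold, het_half_width = het_half_width,
      het_min_null = het_min_null, n_het_pool = n_het_pool,
      tract_total_bp = tract_total_bp, n_tracts = n_tracts,
      iterations = iterations, increment_fraction = increment_fraction,
      n_traits = n_traits, k_per_trait = k_per_trait,
      enriched_fraction = enriched_fraction, r2_min = r2_min,
      ld_window_bp = ld_window_bp, alpha = alpha
    ),
    class = "run_config"
  )
}

config_hash <- function(config) {
  stable_hash(paste(deparse(config[setdiff(names(config), "sim")]),
                    deparse(unclass(config$sim)[setdiff(
                      names(config$sim), "layout"
                    )]),
                    collapse = ""))
}

log_line <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  invisible(line)
}

#' Run the full scan-and-enrichment pipeline into a directory
#'
#' Executes the enabled stages in dependency order (simulate, singleton
#' identification and filtering, selection scan, DAF-heterogeneity
#' enrichment, introgression rotation permutation, trait enrichment), writing
#' one TSV per stage plus a plain-text log with timestamps, the seed, a
#' parameter hash, and a verbatim config echo. Re-running with an identical
#' config reproduces identical outputs. A disabled upstream stage makes
#' downstream stages fail fast with an error naming the missing stage.
#'
#' @param config A [run_config()].
#' @param dir Output directory (created if needed).
#' @param panel Optional pre-built [haplotype_panel()] (replaces the simulate
#'   stage for real data).
#' @return Invisibly, a named list of stage results and file paths.
#' @export
run_pipeline <- function(config, dir, panel = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(dir, "run.log")
  cat("", file = log_path)
  log_line(log_path, "run start; seed=", config$seed,
           " param_hash=", config_hash(config))
  for (ln in deparse(config[setdiff(names(config), c("sim", "mask"))])) {
    log_line(log_path, "config: ", ln)
  }
  out <- list(dir = dir, config = config)
  stages <- config$stages

  if ("simulate" %in% stages) {
    sim <- simulate_panel(config$sim)
    out$panel <- sim$panel
    out$truth <- sim$truth
    write_table(sim$truth_singletons, file.path(dir, "truth_singletons.tsv"))
    write_table(sim$truth, file.path(dir, "truth_selected.tsv"))
    g <- glance(sim$panel)
    log_line(log_path, "simulate: ", g$n_samples, " samples, ",
             g$n_sites, " sites")
  } else if (!is.null(panel)) {
    out$panel <- panel
    log_line(log_path, "simulate: skipped (external panel)")
  }

  if ("singletons" %in% stages) {
    if (is.null(out$panel)) abort("stage 'singletons' needs stage 'simulate'")
    catalog <- purrr::map_dfr(
      unique(out$panel$samples$dataset),
      ~ extract_singletons(out$panel, .x)
    )
    catalog <- apply_mask(catalog, config$mask)
    df <- density_filter(
      catalog, config$sim$layout,
      window_bp = config$window_bp, step_bp = config$step_bp,
      k_sd = config$k_sd
    )
    out$catalog <- df$catalog
    out$density_report <- df$report
    write_table(df$catalog, file.path(dir, "singletons.tsv"))
    write_table(glance(df$report), file.path(dir, "density_report.tsv"))
    log_line(log_path, "singletons: ", nrow(df$catalog), " entries, ",
             sum(!df$catalog$retained), " removed")
  }

  if ("sds" %in% stages) {
    if (is.null(out$catalog)) abort("stage 'sds' needs stage 'singletons'")
    out$sds <- sds_scan(
      out$panel, out$catalog, config$sim$layout,
      maf_min = config$maf_min, min_class_count = config$min_class_count,
      sig_threshold = config$sig_threshold
    )
    write_table(out$sds, file.path(dir, "sds.tsv"))
    log_line(log_path, "sds: ", nrow(out$sds), " variants scored, ",
             sum(out$sds$significant), " genome-wide significant")
  }

  if ("dafhet" %in% stages) {
    if (is.null(out$sds)) abort("stage 'dafhet' needs stage 'sds'")
    focal <- out$sds$variant_id[out$sds$significant]
    n_pool <- min(config$n_het_pool, nrow(out$sds))
    keep_ids <- union(head(out$sds$variant_id, n_pool), focal)
    pool_var <- out$sds[out$sds$variant_id %in% keep_ids, ]
    sel_flag <- pool_var$variant_id %in% focal
    counts <- simulate_regional_counts(
      config$sim, pool_var$daf, selected = sel_flag,
      variant_id = pool_var$variant_id
    )
    pool <- het_index_by_variant(counts)
    if (length(focal) > 0) {
      out$dafhet <- daf_heterogeneity_test(
        pool, focal,
        half_width = config$het_half_width, min_null = config$het_min_null
      )
    } else {
      out$dafhet <- daf_heterogeneity_test(
        pool, pool$variant_id[1],
        half_width = config$het_half_width, min_null = config$het_min_null
      )
    }
    write_table(out$dafhet, file.path(dir, "daf_heterogeneity.tsv"))
    log_line(log_path, "dafhet: ", nrow(out$dafhet), " focal variants")
  }

  if ("introgression" %in% stages) {
    if (is.null(out$sds)) abort("stage 'introgression' needs stage 'sds'")
    tracts <- simulate_tracts(
      config$sim, config$tract_total_bp, config$n_tracts
    )
    out$tracts <- tracts
    write_bed(tracts, file.path(dir, "tracts.bed"))
    out$introgression <- rotation_permutation(
      tracts, out$sds, config$sim$layout,
      iterations = config$iterations,
      increment_fraction = config$increment_fraction,
      tract_set = "simulated"
    )
    write_table(tidy(out$introgression), file.path(dir, "introgression.tsv"))
    log_line(log_path, "introgression: P=", out$introgression$p_value)
  }

  if ("trait_enrich" %in% stages) {
    if (is.null(out$sds)) abort("stage 'trait_enrich' needs stage 'sds'")
    ts <- simulate_trait_sets(
      config$sim,
      out$sds[, c("variant_id", "chrom", "pos")],
      n_traits = config$n_traits, k_per_trait = config$k_per_trait,
      enriched_fraction = config$enriched_fraction
    )
    out$trait_sets <- ts$sets
    out$trait_truth <- ts$truth
    out$trait_enrich <- trait_enrichment_scan(
      ts$sets, out$sds, out$panel,
      r2_min = config$r2_min, window_bp = config$ld_window_bp,
      alpha = config$alpha
    )
    write_table(out$trait_enrich, file.path(dir, "trait_enrichment.tsv"))
    log_line(log_path, "trait_enrich: ", nrow(out$trait_enrich), " traits, ",
             sum(out$trait_enrich$bonferroni_significant, na.rm = TRUE),
             " Bonferroni-significant")
  }
  log_line(log_path, "run complete")
  invisible(out)
}

#' Re-run the pipeline on a sample subset
#'
#' Confines the panel to samples from the given regions and re-executes the
#' pipeline (the sensitivity-analysis pattern: do the significant loci
#' survive restriction to one population cluster?). Emits a comparison of
#' genome-wide-significant loci between the full and subset runs.
#'
#' @param config A [run_config()]; its panel comes from the simulate stage.
#' @param dir Output directory for the subset run.
#' @param regions Region labels to keep.
#' @param full_run Optional result of [run_pipeline()] on the full panel; if
#'   missing, the full run is executed first in `file.path(dir, "full")`.
#' @return Invisibly, the subset-run list plus `comparison`.
#' @export
subset_rerun <- function(config, dir, regions, full_run = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(full_run)) {
    full_run <- run_pipeline(config, file.path(dir, "full"))
  }
  panel <- full_run$panel
  keep <- panel$samples$region %in% regions
  if (!any(keep)) abort("empty sample subset")
  sub_ids <- panel$samples$sample_id[keep]
  sub_panel <- haplotype_panel(
    sites = panel$sites[, c("chrom", "pos", "anc", "der", "variant_id")],
    haps = panel$haps[hap_rows(panel, sub_ids), , drop = FALSE],
    samples = panel$samples[keep, ]
  )
  sub_config <- config
  sub_config$stages <- setdiff(config$stages, c("simulate", "dafhet",
                                                "introgression",
                                                "trait_enrich"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub <- run_pipeline(sub_config, file.path(dir, "subset"), panel = sub_panel)
  log_line(file.path(dir, "subset", "run.log"),
           "subset: regions=", paste(regions, collapse = ","),
           " n=", length(sub_ids), " of ", nrow(panel$samples))
  comparison <- dplyr::full_join(
    full_run$sds %>%
      filter(.data$significant) %>%
      select("variant_id", full_final_z = "final_z"),
    sub$sds %>%
      filter(.data$significant) %>%
      select("variant_id", subset_final_z = "final_z"),
    by = "variant_id"
  )
  write_table(comparison, file.path(dir, "comparison.tsv"))
  sub$comparison <- comparison
  invisible(sub)
}
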