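# Heavy shared fixtures, computed once per test run.

.sdscan_test_cache <- new.env(parent = emptyenv())

# Full scan of a neutral panel (no selected loci, one region) at the
# calibration design: three datasets of 200 samples, ~2400 common variants on
# a 10-Mb genome. Shared by the null-calibration and type-I tests.
null_scan_fixture <- function() {
  if (!exists("null_scan", envir = .sdscan_test_cache)) {
    cfg <- sim_config(
      seed = 101, layout = toy_layout(1, 5e6, 2),
      sample_sizes = c(200, 200, 200), n_common = 2400,
      regions = tibble::tibble(region = "all", prop = 1, f = 0.0047)
    )
    sim <- simulate_panel(cfg)
    catalog <- dplyr::bind_rows(lapply(
      unique(sim$panel$samples$dataset),
      function(d) extract_singletons(sim$panel, d)
    ))
    flt <- density_filter(catalog, cfg$layout)
    sds <- sds_scan(sim$panel, flt$catalog, cfg$layout)
    assign("null_scan", list(cfg = cfg, sim = sim, sds = sds),
           envir = .sdscan_test_cache)
  }
  get("null_scan", envir = .sdscan_test_cache)
}

# One scan with a planted selected locus (rho = 0.2, DAF 0.5, 50-kb window)
# at moderate size; shared by sign-convention and locus-removal tests.
selected_scan_fixture <- function() {
  if (!exists("sel_scan", envir = .sdscan_test_cache)) {
    cfg <- sim_config(
      seed = 202, layout = toy_layout(1, 2e6, 2),
      sample_sizes = c(100, 100, 100), n_common = 600, lambda0 = 1e-4,
      selected = tibble::tibble(
        chrom = "chr1", pos = 1000000L, daf = 0.5, rho = 0.2,
        half_width = 5e4
      )
    )
    sim <- simulate_panel(cfg)
    catalog <- dplyr::bind_rows(lapply(
      unique(sim$panel$samples$dataset),
      function(d) extract_singletons(sim$panel, d)
    ))
    flt <- density_filter(catalog, cfg$layout)
    sds <- sds_scan(sim$panel, flt$catalog, cfg$layout)
    assign("sel_scan", list(cfg = cfg, sim = sim, sds = sds),
           envir = .sdscan_test_cache)
  }
  get("sel_scan", envir = .sdscan_test_cache)
}
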