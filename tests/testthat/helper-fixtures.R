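# Small fixture builders shared across test files.

# Panel from an explicit haplotype matrix: `haps` has 2 rows per sample
# (rows 2i-1, 2i belong to sample i), one column per site.
tiny_panel <- function(haps, pos = NULL, chrom = "chr1", dataset = "d1",
                       region = "all") {
  haps <- as.matrix(haps)
  n <- nrow(haps) / 2
  m <- ncol(haps)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  haplotype_panel(
    sites = tibble::tibble(
      chrom = chrom, pos = as.integer(pos), anc = "A", der = "G"
    ),
    haps = haps,
    samples = tibble::tibble(
      sample_id = paste0("s", seq_len(n)),
      dataset = rep_len(dataset, n),
      region = rep_len(region, n)
    )
  )
}

# Random dense panel: each site's DAF drawn uniform, haplotypes independent.
random_panel <- function(seed, n_samples = 6, n_sites = 20, chrom = "chr1",
                         dataset = "d1") {
  withr::with_seed(seed, {
    daf <- runif(n_sites, 0.05, 0.95)
    haps <- matrix(
      as.integer(runif(2 * n_samples * n_sites) <
                   rep(daf, each = 2 * n_samples)),
      nrow = 2 * n_samples
    )
    tiny_panel(haps, pos = sort(sample.int(1e6, n_sites)), chrom = chrom,
               dataset = dataset)
  })
}

# Minimal phased VCF text on disk; body rows are full tab-separated records.
write_tiny_vcf <- function(body_rows, sample_ids = c("s1", "s2")) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"),
    body_rows
  ), path)
  path
}

# Catalog tibble shorthand for singleton/gap tests.
tiny_catalog <- function(pos, sample_id, chrom = "chr1", dataset = "d1",
                         class = "singleton") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), sample_id = sample_id,
    class = class, dataset = dataset, retained = TRUE, reason = "none"
  )
}

# Gap observation tibble from explicit per-individual classes and gaps.
tiny_obs <- function(gclass, gap, variant_id = "v1") {
  tibble::tibble(
    variant_id = variant_id,
    sample_id = paste0("s", seq_along(gclass)),
    gclass = as.integer(gclass),
    d_up = gap / 2, d_down = gap / 2, gap = gap,
    censored = FALSE
  )
}

# Dense two-stage grid search over (lambda_anc, lambda_der); the independent
# oracle for the gap-likelihood MLE.
grid_search_sds <- function(obs, steps = 60) {
  used <- obs[!obs$censored, ]
  n_anc <- 2 - used$gclass
  n_der <- used$gclass
  ll <- function(la, ld) {
    lam <- n_anc * la + n_der * ld
    sum(2 * log(lam) - lam * used$gap)
  }
  centre <- log(2 * nrow(used) / sum(used$gap))
  lo1 <- lo2 <- centre - 4
  hi1 <- hi2 <- centre + 4
  best <- c(exp(centre), exp(centre))
  for (stage in 1:3) {
    g1 <- exp(seq(lo1, hi1, length.out = steps))
    g2 <- exp(seq(lo2, hi2, length.out = steps))
    vals <- outer(g1, g2, Vectorize(ll))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    best <- c(g1[ix[1]], g2[ix[2]])
    w1 <- (hi1 - lo1) / steps * 2
    w2 <- (hi2 - lo2) / steps * 2
    lo1 <- log(best[1]) - w1; hi1 <- log(best[1]) + w1
    lo2 <- log(best[2]) - w2; hi2 <- log(best[2]) + w2
  }
  list(lambda_anc = best[1], lambda_der = best[2],
       raw = log(best[1]) - log(best[2]))
}
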