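#' Construct a phased haplotype panel
#'
#' The substrate of every selection statistic: a site table, a sparse 0/1
#' haplotype matrix (two rows per sample: sample `i` owns rows `2i - 1` and
#' `2i`), and a sample table carrying dataset and region labels. Sites are
#' polarized: matrix entries count the *derived* allele, positions are 1-based
#' and strictly increasing within a chromosome.
#'
#' @param sites Tibble with `chrom`, `pos` (1-based), `anc`, `der` alleles.
#' @param haps `2 * n_samples` x `n_sites` matrix (coercible to sparse) with
#'   entries in {0, 1}.
#' @param samples Tibble with `sample_id` (unique), `dataset`, `region`.
#' @return A `haplotype_panel` object.
#' @export
haplotype_panel <- function(sites, haps, samples) {
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  stopifnot(all(c("chrom", "pos", "anc", "der") %in% names(sites)))
  stopifnot(all(c("sample_id", "dataset") %in% names(samples)))
  if (!"region" %in% names(samples)) samples$region <- "all"
  if (anyDuplicated(samples$sample_id) > 0) abort("duplicate sample_id")
  haps <- Matrix::Matrix(haps * 1, sparse = TRUE)
  if (nrow(haps) != 2 * nrow(samples))
    abort("haplotype matrix must have 2 rows per sample")
  if (ncol(haps) != nrow(sites))
    abort("haplotype matrix must have one column per site")
  if (length(haps@x) && !all(haps@x %in% c(0, 1)))
    abort("haplotype values must be 0/1")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, ]
  haps <- haps[, ord, drop = FALSE]
  dup <- sites %>% count(.data$chrom, .data$pos) %>% filter(n > 1)
  if (nrow(dup) > 0) abort("duplicate site positions within a chromosome")
  if (!"variant_id" %in% names(sites)) {
    sites$variant_id <- paste0(sites$chrom, ":", sites$pos)
  }
  structure(
    list(sites = sites, haps = haps, samples = samples),
    class = "haplotype_panel"
  )
}

#' @export
#' @method print haplotype_panel
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$samples), " samples (",
      paste0(unique(x$samples$dataset), collapse = ", "), "), ",
      nrow(x$sites), " sites\n", sep = "")
  invisible(x)
}

#' @export
#' @method glance haplotype_panel
glance.haplotype_panel <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    n_sites = nrow(x$sites),
    n_datasets = dplyr::n_distinct(x$samples$dataset),
    n_regions = dplyr::n_distinct(x$samples$region)
  )
}

#' @export
#' @method tidy haplotype_panel
tidy.haplotype_panel <- function(x, ...) {
  mutate(x$sites, daf = compute_daf(x)$daf)
}

# row indices of the two haplotypes of the given samples
hap_rows <- function(panel, sample_ids) {
  idx <- match(sample_ids, panel$samples$sample_id)
  if (anyNA(idx)) abort("unknown sample_id")
  as.vector(rbind(2 * idx - 1, 2 * idx))
}

#' Derived allele frequency per site
#'
#' DAF = derived allele count / (2 x number of samples), optionally over a
#' sample subset.
#'
#' @param panel A [haplotype_panel()].
#' @param samples Optional character vector of sample ids.
#' @return Tibble `variant_id`, `chrom`, `pos`, `dac` (derived allele count),
#'   `daf`.
#' @export
compute_daf <- function(panel, samples = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(samples)) {
    rows <- seq_len(nrow(panel$haps))
  } else {
    if (length(samples) == 0) abort("empty sample subset")
    rows <- hap_rows(panel, samples)
  }
  dac <- Matrix::colSums(panel$haps[rows, , drop = FALSE])
  tibble(
    variant_id = panel$sites$variant_id,
    chrom = panel$sites$chrom,
    pos = panel$sites$pos,
    dac = as.integer(dac),
    daf = dac / length(rows)
  )
}

#' Site frequency spectrum of derived alleles
#'
#' Histogram of segregating sites by derived allele count 1 .. 2n - 1;
#' monomorphic sites contribute nothing.
#'
#' @param panel A [haplotype_panel()].
#' @param samples Optional sample-id subset.
#' @return Tibble `derived_count`, `n_sites` covering 1 .. 2n - 1.
#' @export
site_frequency_spectrum <- function(panel, samples = NULL) {
  daf <- compute_daf(panel, samples)
  n_hap <- if (is.null(samples)) nrow(panel$haps) else 2 * length(samples)
  seg <- daf$dac[daf$dac >= 1 & daf$dac <= n_hap - 1]
  tibble(
    derived_count = seq_len(n_hap - 1),
    n_sites = as.integer(tabulate(seg, nbins = n_hap - 1))
  )
}

#' Read a phased VCF into a polarized haplotype panel
#'
#' Biallelic SNVs with a phased GT field are retained; the ancestral allele is
#' taken from an INFO key (default `AA`) and each site is oriented so the
#' matrix counts derived alleles (sites whose ancestral allele equals ALT are
#' flipped). Sites whose ancestral allele is missing or matches neither REF
#' nor ALT are dropped, not guessed; drop counts are attached as the
#' `"report"` attribute. Ancestral annotations are assumed to already be on
#' the reference strand.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param polarity_field INFO key holding the ancestral allele.
#' @param samples Optional tibble `sample_id`, `dataset`, `region` to label
#'   samples; defaults to a single dataset `"d1"`.
#' @return A [haplotype_panel()] with attribute `report` (tibble of drop
#'   counts).
#' @export
read_panel <- function(path, polarity_field = "AA", samples = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read VCF: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) abort("VCF has no genotype columns")
  sample_ids <- colnames(gt)[-1]
  n_in <- nrow(fix)
  aa <- toupper(vcfR::extract.info(v, element = polarity_field))
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  has_aa <- !is.na(aa) & (aa == toupper(fix$REF) | aa == toupper(fix$ALT))
  keep <- biallelic & has_aa
  gt_body <- gt[, -1, drop = FALSE]
  gt_calls <- matrix(sub(":.*$", "", gt_body), nrow = nrow(gt_body))
  unphased <- matrix(grepl("/", gt_calls), nrow = nrow(gt_calls))
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1, ]
    abort(paste0(
      "unphased genotype at ", fix$CHROM[bad[1]], ":", fix$POS[bad[1]],
      " sample ", sample_ids[bad[2]]
    ))
  }
  if (!any(keep)) {
    panel <- haplotype_panel(
      sites = tibble(
        chrom = character(), pos = integer(),
        anc = character(), der = character()
      ),
      haps = Matrix::sparseMatrix(
        i = integer(), j = integer(), x = numeric(),
        dims = c(2 * length(sample_ids), 0)
      ),
      samples = panel_samples(sample_ids, samples)
    )
  } else {
    fix <- fix[keep, , drop = FALSE]
    aa <- aa[keep]
    gt_calls <- gt_calls[keep, , drop = FALSE]
    h1 <- matrix(
      as.integer(substr(gt_calls, 1, 1)),
      nrow = nrow(gt_calls)
    )
    h2 <- matrix(
      as.integer(substr(gt_calls, 3, 3)),
      nrow = nrow(gt_calls)
    )
    flip <- aa == toupper(fix$ALT)
    h1[flip, ] <- 1L - h1[flip, ]
    h2[flip, ] <- 1L - h2[flip, ]
    der <- ifelse(flip, fix$REF, fix$ALT)
    # interleave: rows 2i-1, 2i are sample i; sites come in as matrix rows
    haps <- matrix(0L, nrow = 2 * length(sample_ids), ncol = nrow(fix))
    haps[seq(1, nrow(haps), by = 2), ] <- t(h1)
    haps[seq(2, nrow(haps), by = 2), ] <- t(h2)
    panel <- haplotype_panel(
      sites = tibble(
        chrom = fix$CHROM, pos = as.integer(fix$POS),
        anc = aa, der = der
      ),
      haps = haps,
      samples = panel_samples(sample_ids, samples)
    )
  }
  attr(panel, "report") <- tibble(
    n_input = n_in,
    n_kept = nrow(panel$sites),
    n_dropped_polarity = sum(biallelic & !has_aa),
    n_dropped_multiallelic = sum(!biallelic)
  )
  panel
}

panel_samples <- function(sample_ids, samples) {
  if (is.null(samples)) {
    return(tibble(sample_id = sample_ids, dataset = "d1", region = "all"))
  }
  samples <- as_tibble(samples)
  if (!all(sample_ids %in% samples$sample_id))
    abort("sample metadata missing for some VCF samples")
  samples[match(sample_ids, samples$sample_id), ]
}

#' Write a haplotype panel as a plain-text phased VCF
#'
#' Emits the dialect [read_panel()] reads (phased GT, ancestral allele in the
#' INFO field), with the site written on its original REF/ALT orientation:
#' the ancestral allele is REF and the derived allele ALT.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path.
#' @param polarity_field INFO key for the ancestral allele.
#' @export
write_panel_vcf <- function(panel, path, polarity_field = "AA") {
  stopifnot(inherits(panel, "haplotype_panel"))
  ids <- panel$samples$sample_id
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=", polarity_field,
           ",Number=1,Type=String,Description=\"Ancestral allele\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  m <- as.matrix(panel$haps)
  h1 <- m[seq(1, nrow(m), by = 2), , drop = FALSE]
  h2 <- m[seq(2, nrow(m), by = 2), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = ncol(m))
  rows <- vapply(seq_len(nrow(panel$sites)), function(i) {
    paste(c(panel$sites$chrom[i], panel$sites$pos[i],
            panel$sites$variant_id[i], panel$sites$anc[i],
            panel$sites$der[i], ".", "PASS",
            paste0(polarity_field, "=", panel$sites$anc[i]),
            "GT", gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
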