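#' Mean selection z-score inside a tract set
#'
#' Arithmetic mean of the final z over variants whose position lies in any
#' tract (half-open membership on the 0-based intervals).
#'
#' @param tracts Interval tibble (`chrom`, `start`, `end`).
#' @param sds An `sds_tbl` from [sds_scan()] (needs `chrom`, `pos`,
#'   `final_z`).
#' @param tract_set Label used in error messages and results.
#' @return Tibble `mean_z`, `n_variants`.
#' @export
tract_mean_z <- function(tracts, sds, tract_set = "tracts") {
  sds <- as_tibble(sds)
  inside <- position_in_intervals(sds$chrom, sds$pos, tracts)
  if (!any(inside))
    abort(paste0("no scored variant inside tract set: ", tract_set))
  tibble(mean_z = mean(sds$final_z[inside]), n_variants = sum(inside))
}

#' Rotation permutation of a tract set along the concatenated genome
#'
#' The paper-style null for "is the mean selection score inside these tracts
#' unusual": chromosomes are concatenated into a circle of length L, and for
#' j = 1..iterations every tract is shifted by `j * increment_fraction * L`
#' (mod L, wrap-around tracts split in two). Variants never move - only the
#' tract flags rotate - so local autocorrelation of the z field is preserved.
#' The two-sided P centers the observed statistic at the mean of the null
#' means. The rotation schedule is systematic, hence bit-reproducible with no
#' seed. Rotations covering zero variants are excluded from the null and
#' counted.
#'
#' @param tracts Interval tibble.
#' @param sds An `sds_tbl` (needs `chrom`, `pos`, `final_z`).
#' @param layout A [genome_layout()].
#' @param iterations Number of rotations.
#' @param increment_fraction Shift per rotation as a fraction of L.
#' @param tract_set Label for the result.
#' @return A `rotation_permutation` object: list with `tract_set`,
#'   `n_tracts`, `n_variants`, `observed_mean`, `null_means`, `null_center`,
#'   `p_value`, `increment_bp`, `iterations` (evaluated), `n_zero_rotations`.
#' @export
rotation_permutation <- function(tracts, sds, layout, iterations = 10000,
                                 increment_fraction = 1e-4,
                                 tract_set = "tracts") {
  stopifnot(inherits(layout, "genome_layout"), iterations >= 1)
  sds <- as_tibble(sds)
  tracts <- normalize_intervals(tracts)
  if (nrow(tracts) == 0) abort("empty tract set")
  L <- layout$total_bp
  gpos <- to_global(layout, sds$chrom, sds$pos)
  z <- sds$final_z
  gt_start <- to_global(layout, tracts$chrom, tracts$start + 1)  # 0-based
  gt_end <- gt_start + (tracts$end - tracts$start)
  ord <- order(gt_start)
  bounds <- as.vector(rbind(gt_start[ord], gt_end[ord]))
  inside0 <- findInterval(gpos, bounds) %% 2 == 1
  if (!any(inside0))
    abort(paste0("no scored variant inside tract set: ", tract_set))
  m_obs <- mean(z[inside0])

  inc <- increment_fraction * L
  null_means <- vapply(seq_len(iterations), function(j) {
    s <- round(j * inc) %% L
    v <- (gpos - s) %% L
    inside <- findInterval(v, bounds) %% 2 == 1
    if (!any(inside)) return(NA_real_)
    mean(z[inside])
  }, 0.0)
  evaluated <- !is.na(null_means)
  nm <- null_means[evaluated]
  mu <- mean(nm)
  p <- (1 + sum(abs(nm - mu) >= abs(m_obs - mu))) / (1 + length(nm))
  structure(
    list(
      tract_set = tract_set, n_tracts = nrow(tracts),
      n_variants = sum(inside0), observed_mean = m_obs,
      null_means = nm, null_center = mu, p_value = p,
      increment_bp = round(inc), iterations = length(nm),
      n_zero_rotations = sum(!evaluated)
    ),
    class = "rotation_permutation"
  )
}

#' @export
#' @method print rotation_permutation
print.rotation_permutation <- function(x, ...) {
  cat(
    "<rotation_permutation> ", x$tract_set, ": ", x$n_tracts, " tracts, ",
    x$n_variants, " variants\n  observed mean z = ",
    signif(x$observed_mean, 4), ", null center = ",
    signif(x$null_center, 4), ", two-sided P = ", signif(x$p_value, 3),
    " (", x$iterations, " rotations)\n", sep = ""
  )
  invisible(x)
}

#' @export
#' @method tidy rotation_permutation
tidy.rotation_permutation <- function(x, ...) {
  tibble(
    tract_set = x$tract_set, n_tracts = x$n_tracts,
    n_variants = x$n_variants, observed_mean = x$observed_mean,
    null_center = x$null_center, p_value = x$p_value,
    increment_bp = x$increment_bp, iterations = x$iterations,
    n_zero_rotations = x$n_zero_rotations
  )
}

#' @export
#' @method glance rotation_permutation
glance.rotation_permutation <- function(x, ...) tidy(x)
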