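#' Define a genome layout of chromosomes and arms
#'
#' A genome layout records chromosome lengths and the chromosome-arm intervals
#' on which selection scores are computed (scores are fitted separately per
#' arm, and the rotation permutation runs on the concatenated chromosomes).
#'
#' @param chromosomes Tibble with columns `chrom` (unique names) and `length`
#'   (bp).
#' @param arms Optional tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `arm` label. Defaults to one arm spanning each chromosome.
#' @return A `genome_layout` object: list with tibbles `chromosomes` and
#'   `arms`, and `total_bp`, the concatenated length L.
#' @examples
#' genome_layout(tibble::tibble(chrom = "chr1", length = 1e6))
#' @export
genome_layout <- function(chromosomes, arms = NULL) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$chrom) > 0)
    abort("chromosome names must be unique")
  if (!all(chromosomes$length > 0) || sum(chromosomes$length) <= 0)
    abort("chromosome lengths must be positive")
  if (is.null(arms)) {
    arms <- tibble(
      chrom = chromosomes$chrom, start = 0,
      end = chromosomes$length, arm = "p"
    )
  }
  arms <- as_tibble(arms)
  stopifnot(all(c("chrom", "start", "end", "arm") %in% names(arms)))
  if (!all(arms$chrom %in% chromosomes$chrom))
    abort("arm interval on unknown chromosome")
  lens <- setNames(chromosomes$length, chromosomes$chrom)
  if (any(arms$start < 0) || any(arms$end > lens[arms$chrom]) ||
      any(arms$start >= arms$end))
    abort("arm intervals must satisfy 0 <= start < end <= chromosome length")
  # non-overlap within chromosome
  chk <- arms %>%
    arrange(.data$chrom, .data$start) %>%
    group_by(.data$chrom) %>%
    summarise(ok = all(.data$start[-1] >= head(.data$end, -1)) || n() == 1)
  if (!all(chk$ok)) abort("arm intervals overlap within a chromosome")
  structure(
    list(
      chromosomes = chromosomes,
      arms = arrange(arms, match(.data$chrom, chromosomes$chrom), .data$start),
      total_bp = sum(chromosomes$length)
    ),
    class = "genome_layout"
  )
}

#' @export
#' @method print genome_layout
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$arms), " arm(s), L = ", format(x$total_bp, big.mark = ","),
      " bp\n", sep = "")
  invisible(x)
}

#' Small multi-arm layout for simulations and examples
#'
#' @param n_chrom Number of chromosomes.
#' @param arm_bp Length of each arm in bp.
#' @param arms_per_chrom Arms per chromosome (labelled "p", "q", ...).
#' @return A [genome_layout()].
#' @export
toy_layout <- function(n_chrom = 2, arm_bp = 5e6, arms_per_chrom = 2) {
  stopifnot(n_chrom >= 1, arm_bp > 0, arms_per_chrom >= 1)
  chroms <- tibble(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = arm_bp * arms_per_chrom
  )
  arm_names <- c("p", "q", paste0("a", seq_len(max(0, arms_per_chrom - 2))))
  arms <- tidyr::expand_grid(
    chrom = chroms$chrom,
    idx = seq_len(arms_per_chrom)
  ) %>%
    mutate(
      start = (.data$idx - 1) * arm_bp,
      end = .data$idx * arm_bp,
      arm = arm_names[.data$idx]
    ) %>%
    select("chrom", "start", "end", "arm")
  genome_layout(chroms, arms)
}

#' Concatenated-genome coordinate map
#'
#' Chromosomes are laid end to end in layout order; a 1-based position on a
#' chromosome maps to a 0-based offset in `[0, L)` on the concatenated genome.
#'
#' @param layout A [genome_layout()].
#' @return Tibble with `chrom` and its 0-based `offset`.
#' @export
layout_offsets <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  tibble(
    chrom = layout$chromosomes$chrom,
    offset = cumsum(c(0, head(layout$chromosomes$length, -1)))
  )
}

#' @rdname layout_offsets
#' @param chrom,pos Parallel vectors of chromosome names and 1-based positions.
#' @return `to_global()`: 0-based global offsets; `from_global()`: a tibble
#'   with `chrom` and 1-based `pos`.
#' @export
to_global <- function(layout, chrom, pos) {
  off <- layout_offsets(layout)
  idx <- match(chrom, off$chrom)
  if (anyNA(idx)) abort("position on a chromosome absent from the layout")
  lens <- layout$chromosomes$length[idx]
  if (any(pos < 1 | pos > lens)) abort("position outside chromosome bounds")
  off$offset[idx] + pos - 1
}

#' @rdname layout_offsets
#' @param gpos 0-based positions on the concatenated genome.
#' @export
from_global <- function(layout, gpos) {
  if (any(gpos < 0 | gpos >= layout$total_bp)) abort("global offset out of range")
  off <- layout_offsets(layout)
  idx <- findInterval(gpos, off$offset)
  tibble(chrom = off$chrom[idx], pos = as.integer(gpos - off$offset[idx] + 1))
}

# arm lookup: returns row index into layout$arms for each (chrom, pos), NA if
# the position lies outside every arm.
arm_index <- function(layout, chrom, pos) {
  arms <- layout$arms
  idx <- rep(NA_integer_, length(chrom))
  for (a in seq_len(nrow(arms))) {
    hit <- chrom == arms$chrom[a] & (pos - 1) >= arms$start[a] &
      (pos - 1) < arms$end[a]
    idx[hit] <- a
  }
  idx
}
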