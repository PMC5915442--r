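#' Interval sets (0-based, half-open)
#'
#' Exclusion masks and introgression tract sets are plain tibbles with columns
#' `chrom`, `start`, `end` in BED convention: 0-based, half-open `[start, end)`.
#' `normalize_intervals()` sorts and merges overlapping/adjacent-overlapping
#' intervals per chromosome; `read_bed()`/`write_bed()` round-trip the BED
#' dialect. Variant positions everywhere else are 1-based (VCF convention);
#' [position_in_intervals()] owns the off-by-one conversion.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @return `normalize_intervals()`: a tibble of sorted, merged, non-overlapping
#'   intervals.
#' @export
normalize_intervals <- function(intervals) {
  intervals <- as_tibble(intervals)[, c("chrom", "start", "end")]
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (any(intervals$start >= intervals$end)) abort("interval with end <= start")
  if (any(intervals$start < 0)) abort("negative interval start")
  out <- intervals %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      # IRanges is 1-based closed; shift BED [start, end) -> [start+1, end]
      ir <- IRanges::reduce(IRanges::IRanges(df$start + 1, df$end))
      tibble(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start)
  out
}

#' @rdname normalize_intervals
#' @param path BED file path (>= 3 tab-separated columns, no header).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read BED file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "\t| +")
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad)) abort(paste0("BED line ", bad[1], " has fewer than 3 fields"))
  out <- tibble(
    chrom = vapply(parts, `[[`, "", 1),
    start = as.numeric(vapply(parts, `[[`, "", 2)),
    end = as.numeric(vapply(parts, `[[`, "", 3))
  )
  bad <- which(!(out$start < out$end))
  if (length(bad)) abort(paste0("BED line ", bad[1], ": end <= start"))
  normalize_intervals(out)
}

#' @rdname normalize_intervals
#' @export
write_bed <- function(intervals, path) {
  df <- as_tibble(intervals)[, c("chrom", "start", "end")]
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Test 1-based positions for membership in an interval set
#'
#' @param chrom,pos Parallel vectors; `pos` is 1-based (VCF convention).
#' @param intervals Interval tibble (0-based half-open). Position `p` is inside
#'   `[start, end)` iff `start <= p - 1 < end`, so a position exactly at
#'   `start + 1` is inside and one at `end + 1` is not.
#' @return Logical vector.
#' @export
position_in_intervals <- function(chrom, pos, intervals) {
  intervals <- normalize_intervals(intervals)
  inside <- logical(length(chrom))
  if (nrow(intervals) == 0) return(inside)
  for (cm in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == cm, ]
    sel <- which(chrom == cm)
    if (!length(sel)) next
    # merged, disjoint: position is inside iff findInterval over the flattened
    # boundary vector lands on an odd index
    bounds <- as.vector(rbind(iv$start, iv$end))
    inside[sel] <- findInterval(pos[sel] - 1, bounds) %% 2 == 1
  }
  inside
}

#' Write a records table as TSV
#'
#' Thin wrapper with a stable column order and round-trip-stable formatting,
#' used for every stage output.
#'
#' @param records A data frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  readr::write_tsv(as_tibble(records), path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
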