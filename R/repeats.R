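#' Filter repeat hits by confidence thresholds
#'
#' Keeps hits that satisfy both confidence filters: alignment length of at
#' least `min_length` bp and Smith-Waterman score of at least `min_sw`. The
#' two thresholds are conjunctive and the input order is preserved, so the
#' filter is idempotent and its output is always a subset of its input.
#'
#' @param hits Repeat-hit tibble (see [read_repeatmasker_out()]).
#' @param min_length Minimum hit length in bp (default 140).
#' @param min_sw Minimum Smith-Waterman score (default 450).
#' @return The surviving rows, order preserved.
#' @export
filter_repeat_hits <- function(hits, min_length = 140L, min_sw = 450L) {
  stopifnot(all(c("length", "sw_score") %in% names(hits)))
  hits[hits$length >= min_length & hits$sw_score >= min_sw, ]
}

#' Windowed repeat-density track
#'
#' Fraction of bases in each window covered by the union of the supplied
#' repeat hits (overlapping hits are merged before counting, so duplicated or
#' split hits do not inflate the density). The final window is clipped to the
#' chromosome end and its fraction is relative to its clipped width.
#'
#' @param hits Repeat hits for one chromosome (`start`, `end`).
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp.
#' @param chrom Chromosome name for the output track (default taken from the
#'   hits, or `"chr"` if empty).
#' @return A coverage-track tibble of `ceiling(chrom_length / window)` rows
#'   with per-window covered fractions in `[0, 1]`.
#' @export
repeat_density <- function(hits, chrom_length, window, chrom = NULL) {
  stopifnot(window > 0, chrom_length > 0)
  if (is.null(chrom)) {
    chrom <- if (nrow(hits) > 0L) hits$chrom[1] else "chr"
  }
  if (nrow(hits) > 0L && any(hits$end > chrom_length | hits$start < 1L)) {
    abort("repeat hit outside chromosome bounds", class = "mycomine_validation_error")
  }
  n_win <- as.integer(ceiling(chrom_length / window))
  win_start <- (seq_len(n_win) - 1L) * window + 1L
  win_end <- pmin(seq_len(n_win) * window, chrom_length)
  if (nrow(hits) == 0L) {
    return(coverage_track(chrom, rep(0, n_win)))
  }
  merged <- IRanges::reduce(IRanges::IRanges(start = hits$start, end = hits$end))
  wins <- IRanges::IRanges(start = win_start, end = win_end)
  ov <- IRanges::findOverlaps(wins, merged)
  covered <- rep(0, n_win)
  if (length(ov) > 0L) {
    qs <- S4Vectors::queryHits(ov)
    inter <- pmin(IRanges::end(merged)[S4Vectors::subjectHits(ov)], win_end[qs]) -
      pmax(IRanges::start(merged)[S4Vectors::subjectHits(ov)], win_start[qs]) + 1L
    covered <- as.numeric(rowsum(inter, qs, reorder = TRUE))
    idx <- sort(unique(qs))
    full <- rep(0, n_win)
    full[idx] <- covered
    covered <- full
  }
  coverage_track(chrom, covered / (win_end - win_start + 1L))
}

#' Count hits of a repeat family
#'
#' Case-insensitive substring match against the class/family string, so
#' `"gypsy"` counts both `"LTR/Gypsy"` and `"LTR/GYPSY"` hits.
#'
#' @param hits Repeat-hit tibble.
#' @param family Family name to count (e.g. `"Gypsy"`).
#' @return Integer count.
#' @export
family_census <- function(hits, family) {
  if (nrow(hits) == 0L) return(0L)
  sum(stringr::str_detect(hits$family, stringr::fixed(family, ignore_case = TRUE)))
}
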