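#' Build a windowed coverage track
#'
#' @param chrom Chromosome name.
#' @param depths Numeric vector of non-negative per-window mean depths,
#'   ordered along the chromosome.
#' @return A tibble with columns `chrom`, `window_index` (1-based) and
#'   `depth`.
#' @export
coverage_track <- function(chrom, depths) {
  if (any(depths < 0)) {
    abort("coverage depths must be non-negative", class = "mycomine_validation_error")
  }
  tibble(chrom = chrom, window_index = seq_along(depths), depth = as.numeric(depths))
}

#' Read a depth track TSV
#'
#' @param path TSV with columns `chrom`, `window_index`, `depth` (a
#'   `mean_depth` column is accepted as an alias).
#' @return A coverage-track tibble.
#' @export
read_depth_track <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("depth track not found: ", path), class = "mycomine_io_error")
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if ("mean_depth" %in% names(df) && !"depth" %in% names(df)) {
    names(df)[names(df) == "mean_depth"] <- "depth"
  }
  if (!all(c("chrom", "window_index", "depth") %in% names(df))) {
    abort("depth track needs columns chrom, window_index, depth",
          class = "mycomine_io_error")
  }
  tibble::as_tibble(df[c("chrom", "window_index", "depth")])
}

# mean depth over a 1-based inclusive interval, weighting each window by its
# overlap with the interval; `window` is the window size in bp
interval_mean_depth <- function(track, chrom, start, end, window) {
  tr <- track[track$chrom == chrom, ]
  if (nrow(tr) == 0L || end < start) return(NA_real_)
  win_start <- (tr$window_index - 1L) * window + 1L
  win_end <- tr$window_index * window
  ov <- pmax(0L, pmin(end, win_end) - pmax(start, win_start) + 1L)
  if (sum(ov) == 0L) return(NA_real_)
  sum(tr$depth * ov) / sum(ov)
}

#' Relative copy number from read-depth coverage
#'
#' Estimates the copy number of a target locus (e.g. the tandem 45S rDNA
#' array) relative to single-copy regions as the ratio of mean read depth
#' over the target intervals to mean depth over the single-copy intervals.
#' Window depths are weighted by their overlap with the intervals, so the
#' estimate is invariant under uniform scaling of the whole track.
#'
#' @param track Coverage track (`chrom`, `window_index`, `depth`).
#' @param target_intervals Tibble of intervals (`chrom`, `start`, `end`,
#'   1-based inclusive) covering the locus of interest.
#' @param single_copy_intervals Tibble of intervals over single-copy regions.
#' @param window Window size of the track in bp.
#' @return The fold ratio (a single number).
#' @export
copy_ratio <- function(track, target_intervals, single_copy_intervals, window) {
  if (nrow(target_intervals) == 0L || nrow(single_copy_intervals) == 0L) {
    abort("interval sets must be non-empty", class = "mycomine_validation_error")
  }
  mean_over <- function(iv) {
    num <- 0; den <- 0
    for (k in seq_len(nrow(iv))) {
      tr <- track[track$chrom == iv$chrom[k], ]
      if (nrow(tr) == 0L) {
        abort(paste0("interval chromosome absent from track: ", iv$chrom[k]),
              class = "mycomine_validation_error")
      }
      win_start <- (tr$window_index - 1L) * window + 1L
      win_end <- tr$window_index * window
      ov <- pmax(0L, pmin(iv$end[k], win_end) - pmax(iv$start[k], win_start) + 1L)
      num <- num + sum(tr$depth * ov)
      den <- den + sum(ov)
    }
    if (den == 0) abort("interval outside track", class = "mycomine_validation_error")
    num / den
  }
  single <- mean_over(single_copy_intervals)
  if (single == 0) {
    abort("zero depth over single-copy intervals", class = "mycomine_validation_error")
  }
  mean_over(target_intervals) / single
}
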