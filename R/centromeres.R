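#' Call centromere candidates as the longest ORF-free interval
#'
#' Operationalises the centromere definition used for repeat-rich fungal
#' assemblies: on each chromosome the candidate is the single longest
#' interval containing no protein-coding gene (the intervals considered are
#' those between consecutive protein-coding genes, plus the two terminal
#' intervals before the first and after the last gene; ties broken leftmost).
#' Non-coding gene models (tRNA/rRNA/lncRNA) do not break an interval. Each
#' candidate is annotated with:
#'
#' * `rt_fraction` — fraction of the interval covered by the union of the
#'   supplied (already confidence-filtered) repeat hits, the "mostly contains
#'   retrotransposons" evidence; no threshold is applied, but `rt_dominant`
#'   flags `rt_fraction >= 0.5`.
#' * `expr_ratio` — mean transcriptional read depth inside the interval
#'   divided by the mean over two equal-length flanking regions (clipped to
#'   the chromosome), the "reduced transcriptional activity" evidence.
#'
#' @param genes Gene table with `kind` column.
#' @param repeats Repeat-hit tibble (pass the output of
#'   [filter_repeat_hits()]); may be `NULL`.
#' @param expr_track Coverage track of RNA-seq depth (`chrom`,
#'   `window_index`, `depth`); may be `NULL`.
#' @param chrom_lengths Tibble with `chrom` and `length` (bp).
#' @param window Window size of `expr_track` in bp (default 1000).
#' @param flank Flank length in bp for the expression comparison; default
#'   (`NULL`) uses the candidate's own length per flank.
#' @param include_terminal Consider the pre-first-gene and post-last-gene
#'   intervals as candidates (default `TRUE`); telomere-proximal candidates
#'   are flagged in the `terminal` column either way.
#' @return A tibble with one row per chromosome: `chrom`, `start`, `end`,
#'   `length`, `rt_fraction`, `rt_dominant`, `expr_ratio`, `terminal`.
#' @export
find_centromere_candidates <- function(genes, repeats = NULL, expr_track = NULL,
                                       chrom_lengths, window = 1000L,
                                       flank = NULL, include_terminal = TRUE) {
  stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
  purrr::map(seq_len(nrow(chrom_lengths)), function(k) {
    ch <- chrom_lengths$chrom[k]
    L <- chrom_lengths$length[k]
    pc <- genes |>
      filter(.data$chrom == ch, .data$kind == "protein_coding") |>
      arrange(.data$start, .data$end)
    if (nrow(pc) == 0L) {
      abort(paste0("no protein-coding gene on chromosome ", ch),
            class = "mycomine_validation_error")
    }
    # ORF-free intervals between consecutive protein-coding genes
    bounds_lo <- c(if (include_terminal) 1L, pc$end + 1L)
    bounds_hi <- c(if (include_terminal) pc$start[1] - 1L, pc$start[-1L] - 1L,
                   if (include_terminal) L)
    if (!include_terminal) bounds_lo <- bounds_lo[-length(bounds_lo)]
    iv <- tibble(start = bounds_lo, end = bounds_hi) |>
      mutate(len = .data$end - .data$start + 1L) |>
      filter(.data$len > 0L)
    if (nrow(iv) == 0L) {
      abort(paste0("no ORF-free interval on chromosome ", ch),
            class = "mycomine_validation_error")
    }
    best <- iv[which.max(iv$len), ]   # which.max takes the leftmost maximum
    rt_fraction <- 0
    if (!is.null(repeats) && nrow(repeats) > 0L) {
      rh <- repeats[repeats$chrom == ch &
                      repeats$end >= best$start & repeats$start <= best$end, ]
      if (nrow(rh) > 0L) {
        clipped <- IRanges::restrict(
          IRanges::reduce(IRanges::IRanges(rh$start, rh$end)),
          start = best$start, end = best$end
        )
        rt_fraction <- sum(IRanges::width(clipped)) / best$len
      }
    }
    expr_ratio <- NA_real_
    if (!is.null(expr_track)) {
      fl <- if (is.null(flank)) best$len else as.integer(flank)
      inside <- interval_mean_depth(expr_track, ch, best$start, best$end, window)
      left <- interval_mean_depth(expr_track, ch, max(1L, best$start - fl),
                                  best$start - 1L, window)
      right <- interval_mean_depth(expr_track, ch, best$end + 1L,
                                   min(L, best$end + fl), window)
      flank_mean <- mean(c(left, right), na.rm = TRUE)
      if (is.finite(flank_mean) && flank_mean > 0) expr_ratio <- inside / flank_mean
    }
    tibble(
      chrom = ch, start = best$start, end = best$end, length = best$len,
      rt_fraction = rt_fraction, rt_dominant = rt_fraction >= 0.5,
      expr_ratio = expr_ratio,
      terminal = best$start == 1L || best$end == L
    )
  }) |> bind_rows()
}
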