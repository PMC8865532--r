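#' Detect telomeric repeat arrays at chromosome termini
#'
#' Scans the terminal windows of each chromosome for tandem arrays of the
#' telomere motif: the motif itself (default `TTAGGG`, the fungal/vertebrate
#' telomeric repeat) within the last `terminal_window` bp of the 3' terminus,
#' and its reverse complement (`CCCTAA`) within the first `terminal_window`
#' bp of the 5' terminus. The reported copy number is the longest run of
#' exact tandem motif copies inside the window; a terminus is called present
#' when that run reaches `min_copies`.
#'
#' @param chromosomes Chromosome table with columns `chrom` and `sequence`
#'   (as from [read_genome_fasta()]).
#' @param motif Telomere motif as read on the 3' strand end (default
#'   `"TTAGGG"`).
#' @param terminal_window Window size in bp scanned at each terminus
#'   (default 200).
#' @param min_copies Minimum tandem copies for a positive call (default 3).
#' @return A tibble with two rows per chromosome and columns `chrom`,
#'   `terminus` (`"5prime"`/`"3prime"`), `motif` (the motif searched at that
#'   terminus), `tandem_copies` and `present`.
#' @export
detect_telomeres <- function(chromosomes, motif = "TTAGGG",
                             terminal_window = 200L, min_copies = 3L) {
  stopifnot(all(c("chrom", "sequence") %in% names(chromosomes)))
  if (any(nchar(chromosomes$sequence) < nchar(motif))) {
    abort("chromosome sequence shorter than one motif copy",
          class = "mycomine_validation_error")
  }
  rc <- revcomp(motif)
  purrr::map2(chromosomes$chrom, chromosomes$sequence, function(nm, seq) {
    n <- nchar(seq)
    w <- min(terminal_window, n)
    head_win <- substr(seq, 1L, w)
    tail_win <- substr(seq, n - w + 1L, n)
    copies <- c(max_tandem_copies(head_win, rc),
                max_tandem_copies(tail_win, motif))
    tibble(
      chrom = nm,
      terminus = c("5prime", "3prime"),
      motif = c(rc, motif),
      tandem_copies = copies
    )
  }) |>
    bind_rows() |>
    mutate(present = .data$tandem_copies >= min_copies)
}

# longest run of exact tandem copies of `motif` within `x`
max_tandem_copies <- function(x, motif) {
  m <- gregexpr(paste0("(?:", motif, ")+"), x)[[1]]
  if (m[1] == -1L) return(0L)
  as.integer(max(attr(m, "match.length")) %/% nchar(motif))
}
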