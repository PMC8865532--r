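#' Compare two mitogenome sequences
#'
#' Aligns two near-identical nucleotide sequences (e.g. the circular
#' mitochondrial genomes of sibling monokaryons) by banded global
#' edit-distance alignment and reports the difference decomposition and the
#' per-base difference rate, the quantity used to bound an assembly's error
#' rate when the two sequences are expected to be identical.
#'
#' `per_base_rate = (substitutions + insertions + deletions) / max(len_a,
#' len_b)`; `display_rate` rounds it to 3 significant digits (so one
#' difference over 115,207 bp prints as 8.68e-06).
#'
#' For circular genomes (`circular = TRUE`, the default) the second sequence
#' is first canonicalised by rotating it to the offset at which the leading
#' 1 kb of the first sequence matches best (exact match first, then up to 100
#' mismatches); if no anchor is found the sequences are compared as given,
#' with a warning.
#'
#' @param seq_a,seq_b Nucleotide sequences (single character strings).
#' @param band Alignment band half-width; must be at least the length
#'   difference. Default: `max(32, 4 * |len_a - len_b|)`.
#' @param circular Canonicalise rotation of `seq_b` before aligning
#'   (default `TRUE`).
#' @return A one-row tibble: `substitutions`, `insertions`, `deletions`,
#'   `distance`, `aligned_length`, `per_base_rate`, `display_rate`.
#' @export
mito_compare <- function(seq_a, seq_b, band = NULL, circular = TRUE) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (la == 0L || lb == 0L) {
    abort("empty sequence", class = "mycomine_validation_error")
  }
  if (is.null(band)) band <- max(32L, 4L * abs(la - lb))
  if (band < abs(la - lb)) {
    abort("band too narrow to align (band < length difference)",
          class = "mycomine_validation_error")
  }
  if (circular && la > 2000L && lb > 2000L) {
    seq_b <- canonical_rotation(seq_a, seq_b)
  }
  res <- banded_edit_alignment(seq_a, seq_b, as.integer(band))
  rate <- (res$substitutions + res$insertions + res$deletions) / max(la, lb)
  tibble(
    substitutions = res$substitutions,
    insertions = res$insertions,
    deletions = res$deletions,
    distance = res$distance,
    aligned_length = res$aligned_length,
    per_base_rate = rate,
    display_rate = signif(rate, 3)
  )
}

# rotate seq_b so that the first 1 kb of seq_a anchors at its start
canonical_rotation <- function(seq_a, seq_b) {
  anchor <- Biostrings::DNAString(substr(seq_a, 1L, 1000L))
  doubled <- Biostrings::DNAString(paste0(seq_b, seq_b))
  off <- NULL
  for (mm in c(0L, 20L, 100L)) {
    hits <- Biostrings::matchPattern(anchor, doubled, max.mismatch = mm)
    hits <- hits[Biostrings::start(hits) <= nchar(seq_b)]
    if (length(hits) > 0L) {
      off <- Biostrings::start(hits)[1]
      break
    }
  }
  if (is.null(off)) {
    warn("no rotation anchor found; comparing sequences as given")
    return(seq_b)
  }
  if (off == 1L) return(seq_b)
  paste0(substr(seq_b, off, nchar(seq_b)), substr(seq_b, 1L, off - 1L))
}

#' Per-base difference rate, display form
#'
#' The display arithmetic used when reporting assembly error bounds: the
#' number of differences divided by the longer sequence length, rounded to 3
#' significant digits.
#'
#' @param differences Total differences (substitutions + indel bases).
#' @param length Length of the longer sequence in bp.
#' @return Numeric rate rounded to 3 significant digits.
#' @export
per_base_rate <- function(differences, length) {
  stopifnot(length > 0)
  signif(differences / length, 3)
}
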