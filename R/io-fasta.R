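#' Read a genome FASTA file
#'
#' Reads every record of a FASTA file into a chromosome table. Sequences are
#' upper-cased; record names are taken from the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `chrom`, `length`
#'   (bp) and `sequence` (character, upper case, alphabet `A`/`C`/`G`/`T`/`N`).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT"), fa)
#' read_genome_fasta(fa)
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "mycomine_io_error")
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(paste0("failed to parse FASTA: ", conditionMessage(e)),
                              class = "mycomine_io_error")
  )
  if (length(seqs) == 0L) {
    abort("no records in FASTA file", class = "mycomine_io_error")
  }
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA headers: ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
          class = "mycomine_io_error")
  }
  tibble(
    chrom = nm,
    length = unname(Biostrings::width(seqs)),
    sequence = unname(toupper(as.character(seqs)))
  )
}

#' Write a chromosome table to FASTA
#'
#' Inverse of [read_genome_fasta()]. Sequences are wrapped at 60 columns, so
#' read/write round-trips are byte-identical for files in the same layout.
#'
#' @param chromosomes Tibble with columns `chrom` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(chromosomes, path) {
  stopifnot(all(c("chrom", "sequence") %in% names(chromosomes)))
  x <- Biostrings::DNAStringSet(chromosomes$sequence)
  names(x) <- chromosomes$chrom
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
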