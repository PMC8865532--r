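#' Read gene models from a GFF3 file
#'
#' Extracts `gene`-type features (any feature whose type ends in "gene") into
#' a gene table. The gene kind is taken from the `gene_biotype` attribute when
#' present, otherwise inferred from the feature type, defaulting to
#' `protein_coding`.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `kind` (one of `protein_coding`, `lncRNA`, `rRNA`,
#'   `tRNA`, `other`) and `length_nt`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GFF3 file not found: ", path), class = "mycomine_io_error")
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(paste0("failed to parse GFF3: ", conditionMessage(e)),
                              class = "mycomine_io_error")
  )
  is_gene <- grepl("gene$", as.character(gr$type))
  gr <- gr[is_gene]
  if (length(gr) == 0L) {
    abort("no gene features in GFF3 file", class = "mycomine_io_error")
  }
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    abort("gene feature without ID attribute", class = "mycomine_io_error")
  }
  if (anyDuplicated(ids)) {
    abort("duplicate gene IDs in GFF3", class = "mycomine_io_error")
  }
  kind <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$gene_biotype)
  } else {
    rep(NA_character_, length(gr))
  }
  type_kind <- dplyr::case_match(
    as.character(gr$type),
    "ncRNA_gene" ~ "lncRNA",
    "rRNA_gene" ~ "rRNA",
    "tRNA_gene" ~ "tRNA",
    .default = "protein_coding"
  )
  kind <- ifelse(is.na(kind) | kind == "", type_kind, kind)
  known <- c("protein_coding", "lncRNA", "rRNA", "tRNA", "other")
  kind[!kind %in% known] <- "other"
  genes <- tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind,
    length_nt = GenomicRanges::width(gr)
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (any(genes$start < 1L) || any(genes$end < genes$start)) {
    abort("invalid gene coordinates (need 1 <= start <= end)",
          class = "mycomine_io_error")
  }
  gene_ranks(genes)
}

#' Write a gene table to GFF3
#'
#' Inverse of [read_gff3()]: each row becomes one `gene` feature carrying
#' `ID` and `gene_biotype` attributes, so read -> write -> read reproduces the
#' gene table exactly.
#'
#' @param genes Gene table as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand", "kind") %in% names(genes)))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$source <- "mycomine"
  gr$ID <- genes$gene_id
  gr$gene_biotype <- genes$kind
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Assign deterministic gene ranks along each chromosome
#'
#' Genes are ranked within each chromosome by start, with ties broken by end
#' and then lexicographic `gene_id`, so ranks are reproducible regardless of
#' input order. Overlapping neighbours are permitted but flagged.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, ...).
#' @return The gene table sorted by chromosome and rank, with added columns
#'   `rank` (1-based position in the chromosome's gene order) and
#'   `overlaps_neighbour` (logical).
#' @export
gene_ranks <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    abort("gene_id values must be unique genome-wide", class = "mycomine_validation_error")
  }
  genes |>
    arrange(.data$chrom, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(
      rank = row_number(),
      overlaps_neighbour =
        (!is.na(lag(.data$end)) & .data$start <= lag(.data$end)) |
        (!is.na(lead(.data$start)) & .data$end >= lead(.data$start))
    ) |>
    ungroup()
}

#' Write genomic intervals to BED
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open convention.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  nm <- if ("name" %in% names(intervals)) intervals$name else
    paste0("iv", seq_len(nrow(intervals)))
  bed <- data.frame(
    chrom = intervals$chrom,
    start = intervals$start - 1L,
    end = intervals$end,
    name = nm
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
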