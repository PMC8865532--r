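#' Read a gene signature table
#'
#' A signature table assigns each annotated gene a functional role used by the
#' cluster caller: `cazyme` (carbohydrate-active enzyme, optionally carrying
#' family tags such as GH5, AA9, CBM1), `transporter`, `transcription_factor`
#' or `other`. Roles are exclusive: a gene tagged both CAZyme and transporter
#' counts as CAZyme only (precedence cazyme > transporter >
#' transcription_factor > other), so no gene is double-counted toward both
#' membership thresholds.
#'
#' @param path TSV with columns `gene_id`, `role` and optionally `families`
#'   (comma-separated family tags).
#' @return A tibble with columns `gene_id`, `role`, `families` (one row per
#'   gene).
#' @export
read_signature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("signature table not found: ", path), class = "mycomine_io_error")
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "role") %in% names(df))) {
    abort("signature table needs columns gene_id, role", class = "mycomine_io_error")
  }
  if (!"families" %in% names(df)) df$families <- ""
  normalise_signatures(tibble::as_tibble(df[c("gene_id", "role", "families")]))
}

role_levels <- c("cazyme", "transporter", "transcription_factor", "other")

normalise_signatures <- function(signatures) {
  signatures$role <- tolower(gsub("[ -]", "_", signatures$role))
  bad <- setdiff(unique(signatures$role), role_levels)
  if (length(bad)) {
    abort(paste0("unknown signature role(s): ", paste(bad, collapse = ", ")),
          class = "mycomine_validation_error")
  }
  if (!"families" %in% names(signatures)) signatures$families <- ""
  signatures$families[is.na(signatures$families)] <- ""
  if (nrow(signatures) == 0L) return(signatures)
  # collapse duplicate rows with role precedence (CAZyme wins)
  signatures |>
    mutate(.prec = match(.data$role, role_levels)) |>
    group_by(.data$gene_id) |>
    summarise(
      role = role_levels[min(.data$.prec)],
      families = paste(unique(unlist(strsplit(.data$families[.data$families != ""], ","))),
                       collapse = ","),
      .groups = "drop"
    )
}

# role per gene in annotation order; genes absent from the table are "other"
roles_for <- function(genes, signatures) {
  signatures <- normalise_signatures(signatures)
  unknown <- setdiff(signatures$gene_id, genes$gene_id)
  if (length(unknown)) {
    abort(paste0("signature table references unknown gene_id(s): ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "mycomine_validation_error")
  }
  role <- signatures$role[match(genes$gene_id, signatures$gene_id)]
  role[is.na(role)] <- "other"
  role
}

ensure_ranked <- function(genes) {
  if (!"rank" %in% names(genes)) genes <- gene_ranks(genes) else {
    genes <- arrange(genes, .data$chrom, .data$rank)
  }
  genes
}

#' Count intergenic gaps between two genes
#'
#' The number of intergenic distances crossed walking along the chromosome's
#' gene order from one gene to the other, i.e. the absolute difference of
#' their gene ranks. Adjacent genes are one gap apart; a gene is zero gaps
#' from itself. This is the distance on which the cluster linkage rule
#' ("within two intergenic distances") operates.
#'
#' @param genes Gene table (ranks are computed if absent).
#' @param gene_a,gene_b Gene identifiers; must lie on the same chromosome.
#' @return Integer gap count.
#' @export
intergenic_gap_count <- function(genes, gene_a, gene_b) {
  genes <- ensure_ranked(genes)
  ia <- match(gene_a, genes$gene_id)
  ib <- match(gene_b, genes$gene_id)
  if (anyNA(c(ia, ib))) {
    abort("unknown gene_id", class = "mycomine_validation_error")
  }
  if (genes$chrom[ia] != genes$chrom[ib]) {
    abort("genes lie on different chromosomes", class = "mycomine_validation_error")
  }
  abs(genes$rank[ia] - genes$rank[ib])
}

# intergenic bp distance between ranks i < j on one chromosome:
# sum of the lengths of the intergenic intervals crossed
bp_gap_sum <- function(starts, ends, i, j) {
  if (i == j) return(0)
  idx <- seq(min(i, j), max(i, j) - 1L)
  sum(pmax(0L, starts[idx + 1L] - ends[idx] - 1L))
}

#' Predict CAZyme gene clusters
#'
#' Calls CAZyme gene clusters (CAZ-GCs, akin to polysaccharide utilization
#' loci) from a gene annotation and a signature table. Two genes are linked
#' when at least one is a CAZyme, the other is a CAZyme or signature gene
#' (transporter / transcription factor), and they lie within `max_gap`
#' intergenic distances of each other along the gene order. Linkage is closed
#' transitively into connected components, and a component is reported as a
#' cluster when it contains at least three CAZyme genes, or at least two
#' CAZyme genes together with at least one signature gene. Signature genes
#' contribute only when linked (directly, within `max_gap` gaps) to a member
#' CAZyme. Clusters never span chromosomes.
#'
#' @param genes Gene table (all annotated genes of any kind count toward gene
#'   ranks; ranks are computed if absent).
#' @param signatures Signature table (`gene_id`, `role`, optional `families`);
#'   genes absent from it have role `other`.
#' @param max_gap Maximum intergenic-distance linkage (default 2, i.e. at most
#'   one intervening gene).
#' @param gap_mode `"rank"` (default) measures the distance in intergenic
#'   gaps along gene order; `"bp"` measures the summed lengths of the
#'   intergenic intervals crossed and links genes when that sum is at most
#'   `max_bp`.
#' @param max_bp Base-pair linkage threshold for `gap_mode = "bp"`; defaults
#'   to `max_gap` times the chromosome's median intergenic distance.
#' @return A tibble with one row per cluster: `cluster_id` (`<chrom>:CGC<n>`
#'   in coordinate order), `chrom`, `start`, `end` (span over members),
#'   `n_members`, `n_cazyme`, `n_signature` and a `members` list-column of
#'   member `gene_id`s in gene order.
#' @export
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = paste0("g", 1:6), chrom = "c1",
#'   start = seq(1, by = 1000, length.out = 6),
#'   end = seq(500, by = 1000, length.out = 6),
#'   strand = "+", kind = "protein_coding"
#' )
#' sig <- tibble::tibble(gene_id = c("g2", "g3", "g4"),
#'                       role = c("cazyme", "cazyme", "cazyme"))
#' predict_cazgc(genes, sig)
predict_cazgc <- function(genes, signatures, max_gap = 2L,
                          gap_mode = c("rank", "bp"), max_bp = NULL) {
  gap_mode <- match.arg(gap_mode)
  if (nrow(genes) == 0L) return(empty_cazgc())
  genes <- ensure_ranked(genes)
  genes$role <- roles_for(genes, signatures)
  out <- genes |>
    group_by(.data$chrom) |>
    dplyr::group_map(~ cazgc_one_chrom(.x, .y$chrom, max_gap, gap_mode, max_bp)) |>
    bind_rows()
  if (nrow(out) == 0L) return(empty_cazgc())
  out <- arrange(out, .data$chrom, .data$start)
  out |>
    group_by(.data$chrom) |>
    mutate(cluster_id = paste0(.data$chrom, ":CGC", row_number())) |>
    ungroup() |>
    select("cluster_id", "chrom", "start", "end",
           "n_members", "n_cazyme", "n_signature", "members")
}

cazgc_one_chrom <- function(ch, chrom, max_gap, gap_mode, max_bp) {
  ch <- arrange(ch, .data$rank)
  special <- which(ch$role != "other")
  caz <- ch$role == "cazyme"
  if (sum(caz) < 2L) return(NULL)
  if (gap_mode == "bp" && is.null(max_bp)) {
    gaps <- pmax(0L, ch$start[-1L] - ch$end[-nrow(ch)] - 1L)
    max_bp <- max_gap * stats::median(gaps)
  }
  # union-find over special genes; edges need >=1 CAZyme endpoint
  parent <- seq_len(nrow(ch))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  linked <- function(i, j) {
    if (gap_mode == "rank") (ch$rank[j] - ch$rank[i]) <= max_gap
    else bp_gap_sum(ch$start, ch$end, i, j) <= max_bp
  }
  for (a in seq_along(special)) {
    i <- special[a]
    b <- a + 1L
    while (b <= length(special)) {
      j <- special[b]
      if (gap_mode == "rank" && (ch$rank[j] - ch$rank[i]) > max_gap) break
      if ((caz[i] || caz[j]) && linked(i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      b <- b + 1L
    }
  }
  comp <- vapply(special, find, integer(1))
  purrr::map(split(special, comp), function(idx) {
    n_caz <- sum(caz[idx])
    n_sig <- sum(!caz[idx])
    if (!(n_caz >= 3L || (n_caz >= 2L && n_sig >= 1L))) return(NULL)
    tibble(
      chrom = chrom,
      start = min(ch$start[idx]), end = max(ch$end[idx]),
      n_members = length(idx), n_cazyme = n_caz, n_signature = n_sig,
      members = list(ch$gene_id[sort(idx)])
    )
  }) |> bind_rows()
}

empty_cazgc <- function() {
  tibble(
    cluster_id = character(), chrom = character(),
    start = integer(), end = integer(),
    n_members = integer(), n_cazyme = integer(), n_signature = integer(),
    members = list()
  )
}

#' Brute-force CAZ-GC reference caller
#'
#' An exhaustive re-derivation of [predict_cazgc()] intended for verification
#' on small instances: it builds the full pairwise linkage graph by computing
#' every intergenic gap from coordinates alone and extracts connected
#' components with `igraph`, an entirely separate code path from the scanning
#' union-find of the production caller.
#'
#' @inheritParams predict_cazgc
#' @return Same shape as [predict_cazgc()].
#' @export
cazgc_oracle <- function(genes, signatures, max_gap = 2L) {
  if (nrow(genes) == 0L) return(empty_cazgc())
  for (n_chr in table(genes$chrom)) {
    if (n_chr > 20L) {
      abort("cazgc_oracle is restricted to <= 20 genes per chromosome",
            class = "mycomine_validation_error")
    }
  }
  genes <- ensure_ranked(genes)
  genes$role <- roles_for(genes, signatures)
  res <- lapply(split(genes, genes$chrom), function(ch) {
    ord <- order(ch$start, ch$end, ch$gene_id)
    ch <- ch[ord, ]
    n <- nrow(ch)
    # gap(i, j) derived from coordinates: number of genes strictly between + 1
    between <- function(i, j) {
      lo <- min(i, j); hi <- max(i, j)
      if (lo == hi) return(0L)
      sum(seq_len(n) > lo & seq_len(n) < hi) + 1L
    }
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      ri <- ch$role[i]; rj <- ch$role[j]
      if (ri == "other" || rj == "other") next
      if (!(ri == "cazyme" || rj == "cazyme")) next
      if (between(i, j) <= max_gap) adj[i, j] <- TRUE
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
    memb <- igraph::components(g)$membership
    out <- NULL
    for (m in unique(memb)) {
      idx <- which(memb == m & ch$role != "other")
      if (!length(idx)) next
      n_caz <- sum(ch$role[idx] == "cazyme")
      n_sig <- sum(ch$role[idx] != "cazyme")
      if (n_caz >= 3L || (n_caz >= 2L && n_sig >= 1L)) {
        out <- bind_rows(out, tibble(
          chrom = ch$chrom[1], start = min(ch$start[idx]), end = max(ch$end[idx]),
          n_members = length(idx), n_cazyme = n_caz, n_signature = n_sig,
          members = list(ch$gene_id[idx])
        ))
      }
    }
    out
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) return(empty_cazgc())
  out <- arrange(out, .data$chrom, .data$start)
  out |>
    group_by(.data$chrom) |>
    mutate(cluster_id = paste0(.data$chrom, ":CGC", row_number())) |>
    ungroup() |>
    select("cluster_id", "chrom", "start", "end",
           "n_members", "n_cazyme", "n_signature", "members")
}

#' Validate called clusters against their own invariants
#'
#' Post-hoc checker, independent of the caller: verifies for each reported
#' cluster that it has at least two CAZymes, satisfies the membership rule
#' (>=3 CAZymes or >=2 CAZymes plus >=1 signature gene), that every signature
#' member is within `max_gap` intergenic distances of some member CAZyme, that
#' members all lie on the reported chromosome, and that the span equals the
#' min start / max end over members.
#'
#' @param clusters Output of [predict_cazgc()].
#' @inheritParams predict_cazgc
#' @return A tibble with one row per cluster and logical check columns plus
#'   an overall `valid` flag.
#' @export
validate_cazgc <- function(clusters, genes, signatures, max_gap = 2L) {
  genes <- ensure_ranked(genes)
  genes$role <- roles_for(genes, signatures)
  purrr::map(seq_len(nrow(clusters)), function(k) {
    mem <- clusters$members[[k]]
    g <- genes[match(mem, genes$gene_id), ]
    caz <- g$gene_id[g$role == "cazyme"]
    sig <- g$gene_id[g$role %in% c("transporter", "transcription_factor")]
    sig_ok <- all(vapply(sig, function(s) {
      any(vapply(caz, function(cz) intergenic_gap_count(genes, s, cz) <= max_gap,
                 logical(1)))
    }, logical(1)))
    tibble(
      cluster_id = clusters$cluster_id[k],
      same_chrom = all(g$chrom == clusters$chrom[k]),
      membership_rule = length(caz) >= 3L || (length(caz) >= 2L && length(sig) >= 1L),
      min_two_cazymes = length(caz) >= 2L,
      signature_linked = sig_ok,
      span_exact = clusters$start[k] == min(g$start) && clusters$end[k] == max(g$end),
      counts_match = clusters$n_cazyme[k] == length(caz) &&
        clusters$n_signature[k] == length(sig)
    )
  }) |>
    bind_rows() |>
    mutate(valid = .data$same_chrom & .data$membership_rule & .data$min_two_cazymes &
             .data$signature_linked & .data$span_exact & .data$counts_match)
}

#' Count predicted clusters across genomes
#'
#' Benchmark mode: runs the cluster caller on each supplied genome annotation
#' plus signature table and tallies predicted clusters per genome. Intended
#' for externally obtained annotations (e.g. deposited assemblies) as well as
#' simulated ones.
#'
#' @param genomes A named list; each element is a list with components
#'   `genes` (gene table or GFF3 path) and `signatures` (signature tibble or
#'   TSV path).
#' @param out Optional path for a TSV report.
#' @inheritParams predict_cazgc
#' @return A tibble with columns `genome`, `n_clusters`.
#' @export
benchmark_cazgc <- function(genomes, out = NULL, max_gap = 2L) {
  res <- purrr::imap(genomes, function(g, nm) {
    genes <- if (is.character(g$genes)) read_gff3(g$genes) else g$genes
    sigs <- if (is.character(g$signatures)) read_signature_table(g$signatures) else g$signatures
    tibble(genome = nm, n_clusters = nrow(predict_cazgc(genes, sigs, max_gap = max_gap)))
  }) |> bind_rows()
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
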