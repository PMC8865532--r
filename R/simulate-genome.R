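#' Specification for a simulated annotated genome
#'
#' Describes a scaled-down multi-chromosome fungal genome that retains every
#' structural feature the feature-calling functions operate on: terminal
#' telomeric tandem arrays, one long ORF-free retrotransposon-dense gap per
#' chromosome (the planted centromere), interspersed class I/II repeat hits
#' whose lengths and scores straddle the confidence filters, and gene tables
#' carrying planted CAZyme gene clusters alongside decoys that each violate
#' exactly one cluster rule.
#'
#' Planted cluster and decoy templates are character vectors of roles at
#' consecutive gene ranks (`"other"` marks a spacer gene). The default
#' plants four valid clusters (three adjacent CAZymes; three CAZymes with one
#' spacer; two CAZymes flanking a transporter; two CAZymes plus a
#' transcription factor two gaps away) and three decoys (two adjacent CAZymes
#' with no signature gene — membership violation; two CAZymes three gaps
#' apart — spacing violation; one CAZyme with two signature genes —
#' membership violation).
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_chromosomes Number of chromosomes (default 3).
#' @param genes_per_chrom Genes per chromosome (default 60).
#' @param mean_gene_len Mean gene length in bp (default 1500).
#' @param mean_intergenic Mean intergenic distance in bp (default 500).
#' @param telomere_motif 3'-terminal telomere motif (default `"TTAGGG"`).
#' @param telomere_copies Optional 2-column matrix (5', 3') of tandem copy
#'   numbers per chromosome; default draws 3-9 per terminus.
#' @param centromere_gap Length of the planted ORF-free gap in bp
#'   (default 30000).
#' @param centromere_rt_fill Fraction of the gap tiled by retrotransposon
#'   hits (default 0.8).
#' @param repeats_per_chrom Background repeat hits per chromosome
#'   (default 120).
#' @param clusters,decoys Lists of role templates (see above).
#' @param expr_window Window size of the simulated expression depth track
#'   (default 1000).
#' @param expr_depth Mean RNA-seq depth outside the centromere (default 50).
#' @return A `genome_sim_spec` list.
#' @export
genome_sim_spec <- function(seed = 1L, n_chromosomes = 3L, genes_per_chrom = 60L,
                            mean_gene_len = 1500L, mean_intergenic = 500L,
                            telomere_motif = "TTAGGG", telomere_copies = NULL,
                            centromere_gap = 30000L, centromere_rt_fill = 0.8,
                            repeats_per_chrom = 120L,
                            clusters = default_cluster_templates(),
                            decoys = default_decoy_templates(),
                            expr_window = 1000L, expr_depth = 50) {
  structure(
    list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
         genes_per_chrom = as.integer(genes_per_chrom),
         mean_gene_len = mean_gene_len, mean_intergenic = mean_intergenic,
         telomere_motif = telomere_motif, telomere_copies = telomere_copies,
         centromere_gap = as.integer(centromere_gap),
         centromere_rt_fill = centromere_rt_fill,
         repeats_per_chrom = as.integer(repeats_per_chrom),
         clusters = clusters, decoys = decoys,
         expr_window = as.integer(expr_window), expr_depth = expr_depth),
    class = "genome_sim_spec"
  )
}

#' @rdname genome_sim_spec
#' @export
default_cluster_templates <- function() {
  list(
    c("cazyme", "cazyme", "cazyme"),
    c("cazyme", "other", "cazyme", "cazyme"),
    c("cazyme", "transporter", "cazyme"),
    c("cazyme", "other", "cazyme", "other", "transcription_factor")
  )
}

#' @rdname genome_sim_spec
#' @export
default_decoy_templates <- function() {
  list(
    c("cazyme", "cazyme"),                              # no 3rd CAZyme, no signature
    c("cazyme", "other", "other", "cazyme"),            # 3 intergenic gaps apart
    c("cazyme", "transporter", "transcription_factor")  # only one CAZyme
  )
}

#' Simulate an annotated genome with planted ground truth
#'
#' Generates chromosome sequences, gene models, repeat hits, a signature
#' table and an expression depth track according to a [genome_sim_spec()],
#' together with machine-readable truth tables for every planted feature.
#' Output is deterministic for a given spec (same spec, same seed, identical
#' output); the caller's RNG state is untouched.
#'
#' Background sequence is i.i.d. uniform ACGT; repeat hits are
#' coordinate-tagged rather than sequence-realistic, since no downstream
#' stage reads repeat sequence content. Depth windows overlapping the planted
#' centromere are set to zero, so the true expression ratio of the planted
#' interval is exactly 0.
#'
#' @param spec A `genome_sim_spec`.
#' @return A `sim_genome` list: `chromosomes`, `genes`, `repeats`,
#'   `signatures`, `expr_track` (plus `expr_window`), and `truth` (a list of
#'   tibbles: `telomeres`, `centromeres`, `clusters`, and `repeats` carries a
#'   `passes_filter` column).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  with_seed_(spec$seed, simulate_genome_impl(spec))
}

simulate_genome_impl <- function(spec) {
  n_chr <- spec$n_chromosomes
  chrom_names <- paste0("Ch", as.character(utils::as.roman(seq_len(n_chr))))
  telo <- spec$telomere_copies
  if (is.null(telo)) {
    telo <- cbind(sample(3:9, n_chr, replace = TRUE),
                  sample(3:9, n_chr, replace = TRUE))
  }
  motif <- spec$telomere_motif
  rc <- revcomp(motif)
  mlen <- nchar(motif)

  # assign planted structures round-robin across chromosomes
  structs <- c(lapply(spec$clusters, function(x) list(roles = x, type = "cluster")),
               lapply(spec$decoys, function(x) list(roles = x, type = "decoy")))
  chrom_of_struct <- if (length(structs)) ((seq_along(structs) - 1L) %% n_chr) + 1L
                     else integer()

  chroms <- list(); genes <- list(); repeats <- list(); sigs <- list()
  truth_tel <- list(); truth_cen <- list(); truth_clu <- list(); expr <- list()

  for (ci in seq_len(n_chr)) {
    ch <- chrom_names[ci]
    n_g <- spec$genes_per_chrom

    # role template along gene ranks
    role <- rep("other", n_g)
    struct_ids <- which(chrom_of_struct == ci)
    pos <- 5L
    memberships <- list()
    for (si in struct_ids) {
      tpl <- structs[[si]]$roles
      if (pos + length(tpl) + 4L > n_g) {
        abort("genes_per_chrom too small for the requested planted structures",
              class = "mycomine_validation_error")
      }
      role[pos:(pos + length(tpl) - 1L)] <- tpl
      memberships[[length(memberships) + 1L]] <-
        list(ranks = pos - 1L + which(tpl != "other"), type = structs[[si]]$type,
             template = paste(tpl, collapse = ","))
      pos <- pos + length(tpl) + sample(4:7, 1L)
    }

    # gene layout: lengths and intergenic gaps, one gap replaced by the
    # centromere gap (placed after the last planted structure)
    g_len <- pmax(200L, round(stats::rlnorm(n_g, log(spec$mean_gene_len), 0.35)))
    gaps <- round(stats::rexp(n_g - 1L, 1 / spec$mean_intergenic)) + 100L
    cen_after <- max(pos, floor(n_g * 0.6))
    cen_after <- min(cen_after, n_g - 2L)
    gaps[cen_after] <- spec$centromere_gap
    g_len <- as.integer(g_len)
    lead_pad <- telo[ci, 1] * mlen + sample(1000:2000, 1L)
    start <- as.integer(lead_pad + cumsum(c(0L, g_len[-n_g] + gaps)))
    end <- start + g_len - 1L
    tail_pad <- sample(1000:2000, 1L) + telo[ci, 2] * mlen
    L <- end[n_g] + tail_pad

    kind <- rep("protein_coding", n_g)
    nc <- which(role == "other")
    nc <- setdiff(nc, c(cen_after, cen_after + 1L))
    nc <- sample(nc, max(0L, round(0.05 * n_g)))
    kind[nc] <- sample(c("tRNA", "rRNA", "lncRNA"), length(nc), replace = TRUE)
    kind[c(cen_after, cen_after + 1L)] <- "protein_coding"

    gid <- sprintf("%s_g%03d", ch, seq_len(n_g))
    genes[[ci]] <- tibble(
      gene_id = gid, chrom = ch, start = start, end = end,
      strand = sample(c("+", "-"), n_g, replace = TRUE),
      kind = kind, length_nt = g_len
    )
    special <- role != "other"
    if (any(special)) {
      fams <- ifelse(role[special] == "cazyme",
                     sample(c("GH5", "GH105", "AA9", "CBM1", "GT2", "CE4", "PL1"),
                            sum(special), replace = TRUE), "")
      sigs[[ci]] <- tibble(gene_id = gid[special], role = role[special],
                           families = fams)
    }
    truth_clu[[ci]] <- purrr::map(memberships, function(m) {
      tibble(chrom = ch, type = m$type, template = m$template,
             members = list(gid[m$ranks]))
    }) |> bind_rows()

    # centromere truth interval and its retrotransposon tiling
    cen_start <- end[cen_after] + 1L
    cen_end <- start[cen_after + 1L] - 1L
    cen_len <- cen_end - cen_start + 1L
    n_tile <- 20L
    spacing <- cen_len %/% n_tile
    tile_len <- as.integer(round(spec$centromere_rt_fill * spacing))
    tiles <- tibble(
      chrom = ch,
      start = cen_start + (seq_len(n_tile) - 1L) * spacing,
      end = cen_start + (seq_len(n_tile) - 1L) * spacing + tile_len - 1L,
      sw_score = as.integer(round(runif(n_tile, 800, 2500))),
      repeat_name = "Gypsy-1", family = "LTR/Gypsy"
    )
    rt_fraction_true <- n_tile * tile_len / cen_len
    truth_cen[[ci]] <- tibble(chrom = ch, start = cen_start, end = cen_end,
                              length = cen_len, rt_fraction = rt_fraction_true,
                              expr_ratio = 0)

    # background repeat hits straddling the confidence filters, kept out of
    # the centromere interval so its repeat fraction stays exact
    n_bg <- spec$repeats_per_chrom
    fam_pool <- c("LTR/Gypsy", "LTR/Copia", "LINE/L1", "SINE/tRNA",
                  "DNA/TcMar-Tc1", "DNA/hAT", "Simple_repeat", "Unknown")
    bg_len <- integer(0); bg_start <- integer(0)
    while (length(bg_start) < n_bg) {
      need <- n_bg - length(bg_start)
      len <- as.integer(round(runif(need, 60, 400)))
      st <- as.integer(floor(runif(need, 1, L - len)))
      ok <- st + len - 1L < cen_start - 1L | st > cen_end + 1L
      bg_len <- c(bg_len, len[ok]); bg_start <- c(bg_start, st[ok])
    }
    bg <- tibble(
      chrom = ch, start = bg_start, end = bg_start + bg_len - 1L,
      sw_score = as.integer(round(runif(n_bg, 200, 900))),
      repeat_name = "rep", family = sample(fam_pool, n_bg, replace = TRUE)
    )
    reps <- bind_rows(tiles, bg) |>
      mutate(length = .data$end - .data$start + 1L,
             repeat_class = repeat_class_of(.data$family),
             planted_rt = c(rep(TRUE, n_tile), rep(FALSE, n_bg)),
             passes_filter = .data$length >= 140L & .data$sw_score >= 450L) |>
      arrange(.data$start)
    repeats[[ci]] <- reps

    # sequence with telomeric arrays and guard bases so the planted tandem
    # copy numbers are exactly the maximal runs in the terminal windows
    seq <- random_dna(L)
    t5 <- strrep(rc, telo[ci, 1])
    t3 <- strrep(motif, telo[ci, 2])
    substr(seq, 1L, nchar(t5)) <- t5
    substr(seq, nchar(t5) + 1L, nchar(t5) + mlen) <- strrep("G", mlen)
    substr(seq, L - nchar(t3) + 1L, L) <- t3
    substr(seq, L - nchar(t3) - mlen + 1L, L - nchar(t3)) <- strrep("A", mlen)
    chroms[[ci]] <- tibble(chrom = ch, length = L, sequence = seq)
    truth_tel[[ci]] <- tibble(chrom = ch, copies_5p = telo[ci, 1],
                              copies_3p = telo[ci, 2])

    # expression depth: Poisson depth everywhere, zero over the centromere
    n_win <- as.integer(ceiling(L / spec$expr_window))
    depth <- rpois(n_win, spec$expr_depth)
    win_start <- (seq_len(n_win) - 1L) * spec$expr_window + 1L
    win_end <- seq_len(n_win) * spec$expr_window
    depth[win_end >= cen_start & win_start <= cen_end] <- 0L
    expr[[ci]] <- coverage_track(ch, depth)
  }

  genes_all <- gene_ranks(bind_rows(genes))
  truth_clusters <- bind_rows(truth_clu)
  structure(
    list(
      chromosomes = bind_rows(chroms),
      genes = genes_all,
      repeats = bind_rows(repeats),
      signatures = bind_rows(sigs),
      expr_track = bind_rows(expr),
      expr_window = spec$expr_window,
      truth = list(
        telomeres = bind_rows(truth_tel),
        centromeres = bind_rows(truth_cen),
        clusters = truth_clusters
      ),
      spec = spec
    ),
    class = "sim_genome"
  )
}

#' Write a simulated genome to standard-format files
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `genome.fa`, `genes.gff3`,
#'   `repeats.out`, `signatures.tsv`, `expr_track.tsv` and
#'   `truth_*.tsv` tables.
#' @export
write_sim_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$chromosomes, file.path(dir, "genome.fa"))
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  write_repeatmasker_out(sim$repeats, file.path(dir, "repeats.out"))
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(sim$signatures, "signatures.tsv")
  wt(sim$expr_track, "expr_track.tsv")
  wt(sim$truth$telomeres, "truth_telomeres.tsv")
  wt(sim$truth$centromeres, "truth_centromeres.tsv")
  clu <- sim$truth$clusters
  clu$members <- vapply(clu$members, paste, character(1), collapse = ",")
  wt(clu, "truth_clusters.tsv")
  invisible(dir)
}

#' Simulate one random chromosome instance for the cluster caller
#'
#' Draws a single-chromosome gene table with random roles, the instance class
#' used to exercise the cluster caller against its brute-force reference.
#'
#' @param n_genes Number of genes (default 12).
#' @param seed Integer seed.
#' @param role_probs Sampling probabilities for roles `cazyme`,
#'   `transporter`, `transcription_factor`, `other`.
#' @return A list with `genes` and `signatures` tibbles.
#' @export
simulate_cazgc_instance <- function(n_genes = 12L, seed = 1L,
                                    role_probs = c(0.25, 0.08, 0.07, 0.60)) {
  with_seed_(seed, {
    g_len <- sample(500:2500, n_genes, replace = TRUE)
    gaps <- sample(100:1500, n_genes, replace = TRUE)
    start <- cumsum(gaps) + cumsum(c(0L, g_len[-n_genes]))
    genes <- tibble(
      gene_id = sprintf("g%02d", seq_len(n_genes)), chrom = "chr1",
      start = start, end = start + g_len - 1L,
      strand = "+", kind = "protein_coding", length_nt = g_len
    )
    role <- sample(role_levels, n_genes, replace = TRUE, prob = role_probs)
    sigs <- tibble(gene_id = genes$gene_id, role = role)[role != "other", ]
    list(genes = genes, signatures = sigs)
  })
}

#' Simulate a near-identical mitogenome pair
#'
#' Generates a random mitogenome sequence and a derived copy carrying a known
#' number of substitutions and well-separated indel blocks, for exercising
#' the banded comparison. Edit sites are kept at least 50 bp apart so the
#' planted operation counts are the unambiguous minimal decomposition.
#'
#' @param length Sequence length in bp (default 115207, a typical polypore
#'   mitogenome).
#' @param n_substitutions Number of substitutions (default 1).
#' @param n_deletions Number of deleted blocks (default 0).
#' @param deletion_length Length of each deleted block (default 3).
#' @param n_insertions Number of inserted blocks (default 0).
#' @param insertion_length Length of each inserted block (default 3).
#' @param seed Integer seed.
#' @return A list: `seq_a`, `seq_b`, `truth` (substitution count and indel
#'   base counts).
#' @export
simulate_mito_pair <- function(length = 115207L, n_substitutions = 1L,
                               n_deletions = 0L, deletion_length = 3L,
                               n_insertions = 0L, insertion_length = 3L,
                               seed = 1L) {
  with_seed_(seed, {
    a <- random_dna(length)
    n_sites <- n_substitutions + n_deletions + n_insertions
    sites <- sort(sample(seq(100L, length - 100L, by = 50L), n_sites))
    kind <- sample(rep(c("sub", "del", "ins"),
                       c(n_substitutions, n_deletions, n_insertions)))
    b_parts <- character(0)
    prev <- 1L
    for (i in seq_len(n_sites)) {
      p <- sites[i]
      if (kind[i] == "sub") {
        base <- substr(a, p, p)
        b_parts <- c(b_parts, substr(a, prev, p - 1L),
                     sample(setdiff(c("A", "C", "G", "T"), base), 1L))
        prev <- p + 1L
      } else if (kind[i] == "del") {
        b_parts <- c(b_parts, substr(a, prev, p - 1L))
        prev <- p + deletion_length
      } else {
        b_parts <- c(b_parts, substr(a, prev, p - 1L), random_dna(insertion_length))
        prev <- p
      }
    }
    b <- paste0(paste(b_parts, collapse = ""), substr(a, prev, length))
    list(seq_a = a, seq_b = b,
         truth = list(substitutions = n_substitutions,
                      insertion_bases = n_insertions * insertion_length,
                      deletion_bases = n_deletions * deletion_length))
  })
}

#' Simulate a read-depth track with an amplified locus
#'
#' Builds a Poisson depth track over one chromosome with a planted
#' amplification (e.g. a tandem rDNA array at known copy fold) and a set of
#' single-copy control intervals, for exercising the relative copy-number
#' estimator.
#'
#' @param chrom_length Chromosome length in bp (default 5e5).
#' @param window Window size in bp (default 1000).
#' @param base_depth Mean single-copy depth (default 50).
#' @param fold Amplification fold of the target locus (default 38).
#' @param target Target interval as `c(start, end)` (default a 50 kb block).
#' @param seed Integer seed.
#' @return A list: `track`, `window`, `target_intervals`,
#'   `single_copy_intervals`, `truth` (the planted fold).
#' @export
simulate_depth_track <- function(chrom_length = 5e5, window = 1000L,
                                 base_depth = 50, fold = 38,
                                 target = c(400001L, 450000L), seed = 1L) {
  with_seed_(seed, {
    n_win <- as.integer(ceiling(chrom_length / window))
    win_start <- (seq_len(n_win) - 1L) * window + 1L
    win_end <- pmin(seq_len(n_win) * window, chrom_length)
    mu <- rep(base_depth, n_win)
    in_target <- win_start >= target[1] & win_end <= target[2]
    mu[in_target] <- base_depth * fold
    # exclude boundary windows from the target interval so the planted fold
    # is exact in expectation
    track <- coverage_track("ChVII", rpois(n_win, mu))
    tgt <- tibble(chrom = "ChVII",
                  start = min(win_start[in_target]),
                  end = max(win_end[in_target]))
    sc <- tibble(chrom = "ChVII",
                 start = c(1L, 100001L, 200001L),
                 end = c(100000L, 200000L, 300000L))
    list(track = track, window = window, target_intervals = tgt,
         single_copy_intervals = sc, truth = list(fold = fold))
  })
}
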