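#' Specification for a simulated RNA-seq count experiment
#'
#' Emulates the three-group developmental design used for mushroom
#' transcriptomics — monokaryotic vegetative mycelium, dikaryotic vegetative
#' mycelium and fruiting body — with negative-binomial counts and a planted
#' set of genes up-regulated in fruiting bodies.
#'
#' Defaults mirror a typical such study: 4 monokaryon, 2 dikaryon and 3
#' fruiting-body samples; NB dispersion 0.1 (standard for RNA-seq biological
#' replicates); planted fold factor 6, comfortably above the fold-change
#' calling threshold of 3 so that recovery measures the method rather than
#' boundary noise.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 2000).
#' @param samples_per_group Named integer vector over groups
#'   `mono_mycelium`, `di_mycelium`, `FB`.
#' @param base_meanlog,base_sdlog Log-normal parameters of per-gene baseline
#'   mean counts (default `log(200)`, 1).
#' @param dispersion NB dispersion (default 0.1; 0 gives Poisson counts).
#' @param n_up Number of planted FB-up-regulated genes (default 100).
#' @param fold Planted fold factor in the FB group (default 6).
#' @param size_factor_sdlog Log-normal spread of per-sample library size
#'   factors (default 0.15).
#' @param length_range Transcript length range in bp (default 500-3000).
#' @return An `expr_sim_spec` list.
#' @export
expr_sim_spec <- function(seed = 1L, n_genes = 2000L,
                          samples_per_group = c(mono_mycelium = 4L,
                                                di_mycelium = 2L, FB = 3L),
                          base_meanlog = log(200), base_sdlog = 1,
                          dispersion = 0.1, n_up = 100L, fold = 6,
                          size_factor_sdlog = 0.15,
                          length_range = c(500L, 3000L)) {
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         samples_per_group = samples_per_group,
         base_meanlog = base_meanlog, base_sdlog = base_sdlog,
         dispersion = dispersion, n_up = as.integer(n_up), fold = fold,
         size_factor_sdlog = size_factor_sdlog, length_range = length_range),
    class = "expr_sim_spec"
  )
}

#' Simulate a count matrix with planted differential expression
#'
#' Negative-binomial counts per [expr_sim_spec()]: gene baseline means are
#' log-normal, planted genes have their mean multiplied by the fold factor in
#' the fruiting-body group, and each sample carries a log-normal library size
#' factor. Deterministic per seed.
#'
#' @param spec An `expr_sim_spec`.
#' @return A `sim_counts` list: `counts` (tibble `gene_id`, `length_nt`,
#'   one column per sample), `groups` (tibble `sample_id`, `group`) and
#'   `truth` (tibble `gene_id`, `planted`, `fold`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  with_seed_(spec$seed, {
    n <- spec$n_genes
    gid <- sprintf("gene%05d", seq_len(n))
    len <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
    base <- stats::rlnorm(n, spec$base_meanlog, spec$base_sdlog)
    planted <- sort(sample(n, spec$n_up))
    groups <- tibble(
      sample_id = unlist(purrr::imap(as.list(spec$samples_per_group),
                                     ~ paste0(.y, "_", seq_len(.x)))),
      group = rep(names(spec$samples_per_group), spec$samples_per_group)
    )
    counts <- tibble(gene_id = gid, length_nt = len)
    for (i in seq_len(nrow(groups))) {
      s <- groups$sample_id[i]
      sf <- stats::rlnorm(1, 0, spec$size_factor_sdlog)
      mu <- base * sf
      if (groups$group[i] == "FB") mu[planted] <- mu[planted] * spec$fold
      counts[[s]] <- if (spec$dispersion > 0) {
        rnbinom(n, mu = mu, size = 1 / spec$dispersion)
      } else {
        rpois(n, mu)
      }
    }
    truth <- tibble(gene_id = gid,
                    planted = seq_len(n) %in% planted,
                    fold = ifelse(seq_len(n) %in% planted, spec$fold, 1))
    structure(list(counts = counts, groups = groups, truth = truth, spec = spec),
              class = "sim_counts")
  })
}

#' Write a simulated count experiment to TSV files
#'
#' @param sim A `sim_counts` from [simulate_counts()].
#' @param dir Output directory.
#' @return `dir`, invisibly. Writes `counts.tsv`, `groups.tsv`,
#'   `truth_genes.tsv`.
#' @export
write_sim_counts <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(sim$counts, "counts.tsv")
  wt(sim$groups, "groups.tsv")
  wt(sim$truth, "truth_genes.tsv")
  invisible(dir)
}

#' Simulate a transcript evidence table for the lncRNA cascade
#'
#' Builds `n` transcript evidence rows of which exactly `n_accept` pass every
#' stage of [filter_lncrna()] at default thresholds; the remaining rows each
#' fail exactly one stage, cycling through the six stages, and include the
#' boundary cases (length 199 nt; FPKM exactly 1.0).
#'
#' @param n Total rows (default 1000).
#' @param n_accept Rows passing all stages (default 87).
#' @param seed Integer seed.
#' @return A list: `evidence` tibble and `truth` tibble (`transcript_id`,
#'   `accepted`, `fail_stage`).
#' @export
simulate_transcript_evidence <- function(n = 1000L, n_accept = 87L, seed = 1L) {
  stopifnot(n_accept <= n)
  with_seed_(seed, {
    id <- sprintf("tx%05d", seq_len(n))
    pass_row <- function(k) tibble(
      at_gene_locus = FALSE,
      length_nt = sample(200:3000, k, replace = TRUE),
      fpkm = runif(k, 1.01, 50),
      cpc_coding = FALSE, txcds_coding = FALSE, cnci_coding = FALSE,
      pfam_domain = FALSE,
      predictor_support = sample(3:5, k, replace = TRUE)
    )
    ev <- pass_row(n)
    fail_stage <- rep(NA_character_, n)
    stages <- c("gene_locus", "short", "low_fpkm", "coding_potential",
                "pfam_domain", "low_support")
    fail_idx <- seq(n_accept + 1L, length.out = n - n_accept)
    for (j in seq_along(fail_idx)) {
      i <- fail_idx[j]
      st <- stages[(j - 1L) %% length(stages) + 1L]
      fail_stage[i] <- st
      if (st == "gene_locus") ev$at_gene_locus[i] <- TRUE
      if (st == "short") ev$length_nt[i] <- if (j <= 6) 199L else sample(50:199, 1)
      if (st == "low_fpkm") ev$fpkm[i] <- if (j <= 6) 1.0 else runif(1, 0, 1)
      if (st == "coding_potential") {
        w <- sample(3, sample(1:3, 1))
        ev$cpc_coding[i] <- 1 %in% w
        ev$txcds_coding[i] <- 2 %in% w
        ev$cnci_coding[i] <- 3 %in% w
      }
      if (st == "pfam_domain") ev$pfam_domain[i] <- TRUE
      if (st == "low_support") ev$predictor_support[i] <- sample(0:2, 1)
    }
    ord <- sample(n)
    evidence <- dplyr::bind_cols(tibble(transcript_id = id), ev)[ord, ]
    truth <- tibble(transcript_id = id, accepted = is.na(fail_stage),
                    fail_stage = fail_stage)[ord, ]
    list(evidence = evidence, truth = truth)
  })
}

#' Simulate a protein evidence table for the effector filter
#'
#' Builds `n` protein rows of which exactly `n_accept` satisfy the effector
#' definition at default thresholds; the rest each fail exactly one rule,
#' including the 300-aa boundary case.
#'
#' @param n Total rows (default 500).
#' @param n_accept Accepted rows (default 42).
#' @param seed Integer seed.
#' @return A list: `proteins` tibble and `truth` tibble.
#' @export
simulate_protein_evidence <- function(n = 500L, n_accept = 42L, seed = 1L) {
  stopifnot(n_accept <= n)
  with_seed_(seed, {
    id <- sprintf("prot%04d", seq_len(n))
    pr <- tibble(
      length_aa = sample(50:299, n, replace = TRUE),
      signal_peptide = TRUE, tm_domains = 0L, gpi_anchor = FALSE
    )
    fail_stage <- rep(NA_character_, n)
    stages <- c("no_signal_peptide", "transmembrane", "gpi_anchor", "too_long")
    fail_idx <- seq(n_accept + 1L, length.out = n - n_accept)
    for (j in seq_along(fail_idx)) {
      i <- fail_idx[j]
      st <- stages[(j - 1L) %% length(stages) + 1L]
      fail_stage[i] <- st
      if (st == "no_signal_peptide") pr$signal_peptide[i] <- FALSE
      if (st == "transmembrane") pr$tm_domains[i] <- sample(1:5, 1)
      if (st == "gpi_anchor") pr$gpi_anchor[i] <- TRUE
      if (st == "too_long") pr$length_aa[i] <- if (j <= 4) 300L else sample(300:900, 1)
    }
    ord <- sample(n)
    proteins <- dplyr::bind_cols(tibble(protein_id = id), pr)[ord, ]
    truth <- tibble(protein_id = id, accepted = is.na(fail_stage),
                    fail_stage = fail_stage)[ord, ]
    list(proteins = proteins, truth = truth)
  })
}

#' Simulate an ortholog-hit fixture with planted class labels
#'
#' Assigns each of `n_genes` query genes one of the four ortholog-overlap
#' classes, then constructs reference id sets and a hit table (including
#' above-cutoff distractor hits) that reproduce exactly that partition under
#' [venn_classes()].
#'
#' @param n_genes Number of query genes (default 1000).
#' @param class_probs Probabilities for `fbig_ortholog`, `fbdg_ortholog`,
#'   `other_ortholog`, `species_specific`.
#' @param e_cut E-value cutoff the fixture is built against (default 1e-5).
#' @param seed Integer seed.
#' @return A list: `frg_ids`, `hits`, `fbig_ids`, `fbdg_ids`, `truth`
#'   (tibble `gene_id`, `class`).
#' @export
simulate_ortholog_fixture <- function(n_genes = 1000L,
                                      class_probs = c(0.06, 0.44, 0.22, 0.28),
                                      e_cut = 1e-5, seed = 1L) {
  with_seed_(seed, {
    gid <- sprintf("frg%05d", seq_len(n_genes))
    cls <- sample(c("fbig_ortholog", "fbdg_ortholog", "other_ortholog",
                    "species_specific"),
                  n_genes, replace = TRUE, prob = class_probs)
    fbig_ids <- sprintf("CcFBIG%04d", 1:666)
    fbdg_ids <- sprintf("CcFBDG%04d", 1:2000)
    other_ids <- sprintf("CcGENE%04d", 1:3000)
    good_e <- function(k) 10^runif(k, -40, log10(e_cut))
    bad_e <- function(k) 10^runif(k, log10(e_cut) + 0.5, -1)
    hits <- list()
    for (i in seq_len(n_genes)) {
      h <- switch(
        cls[i],
        fbig_ortholog = tibble(query = gid[i],
                               subject = c(sample(fbig_ids, 1),
                                           sample(fbdg_ids, 1)),
                               e_value = c(good_e(1), good_e(1))),
        fbdg_ortholog = tibble(query = gid[i],
                               subject = c(sample(fbdg_ids, 1),
                                           sample(fbig_ids, 1)),
                               e_value = c(good_e(1), bad_e(1))),
        other_ortholog = tibble(query = gid[i],
                                subject = sample(other_ids, 1),
                                e_value = good_e(1)),
        species_specific = if (runif(1) < 0.5) {
          tibble(query = gid[i], subject = sample(other_ids, 1),
                 e_value = bad_e(1))   # only above-cutoff distractors
        } else NULL
      )
      hits[[i]] <- h
    }
    list(frg_ids = gid, hits = bind_rows(hits),
         fbig_ids = fbig_ids, fbdg_ids = fbdg_ids,
         truth = tibble(gene_id = gid,
                        class = factor(cls, levels = c("fbig_ortholog",
                                                       "fbdg_ortholog",
                                                       "other_ortholog",
                                                       "species_specific"))))
  })
}
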