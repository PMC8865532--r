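#' lncRNA candidate filter cascade
#'
#' Applies, in order, the stages used to distil high-confidence long
#' non-coding RNA candidates from assembled transcripts:
#'
#' 1. `gene_locus` — drop transcripts overlapping a known gene model;
#' 2. `short` — drop transcripts shorter than `min_len` nt (a lncRNA is
#'    >= 200 nt by definition);
#' 3. `low_fpkm` — drop transcripts with FPKM <= `fpkm_cut` (the boundary
#'    value itself is excluded);
#' 4. `coding_potential` — drop transcripts judged coding by the three
#'    coding-potential evaluations (`coding_rule = "any"`, the conservative
#'    default, drops a transcript any tool calls coding; `"majority"`
#'    requires at least two);
#' 5. `pfam_domain` — drop transcripts containing a known protein domain;
#' 6. `low_support` — keep only transcripts called by at least `min_support`
#'    lncRNA prediction tools.
#'
#' Stages 2 and 3 act as independent exclusions by default; `conjunctive =
#' TRUE` restores a literal combined reading (drop only when short **and**
#' low-FPKM), which would retain short high-FPKM transcripts.
#'
#' @param evidence Tibble with columns `transcript_id`, `at_gene_locus`
#'   (logical), `length_nt`, `fpkm`, `cpc_coding`, `txcds_coding`,
#'   `cnci_coding` (logical: tool judged it coding), `pfam_domain` (logical)
#'   and `predictor_support` (integer).
#' @param min_len Minimum transcript length in nt (default 200).
#' @param fpkm_cut Expression exclusion boundary: FPKM `<=` this value is
#'   excluded (default 1.0).
#' @param min_support Minimum number of supporting lncRNA predictors
#'   (default 3).
#' @param coding_rule `"any"` (default) or `"majority"`.
#' @param conjunctive Combine the length and FPKM exclusions into one
#'   conjunctive stage (default `FALSE`).
#' @return A `filter_cascade` object: `accepted` (character vector of ids),
#'   `stages` (tibble of per-stage exclusion tallies; the excluded counts
#'   plus the accepted count always sum to the input size), `n_input`,
#'   `n_accepted`. [tidy()] returns the stage table.
#' @export
filter_lncrna <- function(evidence, min_len = 200L, fpkm_cut = 1.0,
                          min_support = 3L, coding_rule = c("any", "majority"),
                          conjunctive = FALSE) {
  coding_rule <- match.arg(coding_rule)
  need <- c("transcript_id", "at_gene_locus", "length_nt", "fpkm",
            "cpc_coding", "txcds_coding", "cnci_coding", "pfam_domain",
            "predictor_support")
  stopifnot(all(need %in% names(evidence)))
  n_coding <- evidence$cpc_coding + evidence$txcds_coding + evidence$cnci_coding
  coding <- if (coding_rule == "any") n_coding >= 1L else n_coding >= 2L
  stages <- if (conjunctive) {
    list(
      gene_locus = evidence$at_gene_locus,
      short_and_low_fpkm = evidence$length_nt < min_len & evidence$fpkm <= fpkm_cut,
      coding_potential = coding,
      pfam_domain = evidence$pfam_domain,
      low_support = evidence$predictor_support < min_support
    )
  } else {
    list(
      gene_locus = evidence$at_gene_locus,
      short = evidence$length_nt < min_len,
      low_fpkm = evidence$fpkm <= fpkm_cut,
      coding_potential = coding,
      pfam_domain = evidence$pfam_domain,
      low_support = evidence$predictor_support < min_support
    )
  }
  run_cascade(evidence$transcript_id, stages,
              params = list(min_len = min_len, fpkm_cut = fpkm_cut,
                            min_support = min_support,
                            coding_rule = coding_rule,
                            conjunctive = conjunctive))
}

#' Effector candidate filter
#'
#' Retains proteins matching the canonical effector-candidate definition:
#' predicted secreted proteins (signal peptide present, no transmembrane
#' domain, no glycosylphosphatidylinositol anchor) shorter than `max_len`
#' amino acids (strict: a 300-aa protein fails the default cutoff).
#'
#' @param proteins Tibble with columns `protein_id`, `length_aa`,
#'   `signal_peptide` (logical), `tm_domains` (integer count) and
#'   `gpi_anchor` (logical).
#' @param max_len Length cutoff in amino acids, exclusive (default 300).
#' @return A `filter_cascade` object (see [filter_lncrna()]).
#' @export
filter_effectors <- function(proteins, max_len = 300L) {
  need <- c("protein_id", "length_aa", "signal_peptide", "tm_domains", "gpi_anchor")
  stopifnot(all(need %in% names(proteins)))
  run_cascade(
    proteins$protein_id,
    list(
      no_signal_peptide = !proteins$signal_peptide,
      transmembrane = proteins$tm_domains > 0L,
      gpi_anchor = proteins$gpi_anchor,
      too_long = proteins$length_aa >= max_len
    ),
    params = list(max_len = max_len)
  )
}

# sequentially apply exclusion stages; each row is excluded at the first
# stage whose predicate it fails
run_cascade <- function(ids, stages, params) {
  alive <- rep(TRUE, length(ids))
  tally <- tibble(stage = names(stages),
                  excluded = NA_integer_, remaining = NA_integer_)
  for (i in seq_along(stages)) {
    drop <- alive & stages[[i]]
    alive <- alive & !drop
    tally$excluded[i] <- sum(drop)
    tally$remaining[i] <- sum(alive)
  }
  structure(
    list(accepted = ids[alive], stages = tally,
         n_input = length(ids), n_accepted = sum(alive), params = params),
    class = "filter_cascade"
  )
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat("<filter_cascade> ", x$n_accepted, " of ", x$n_input, " accepted\n", sep = "")
  print(x$stages)
  invisible(x)
}
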