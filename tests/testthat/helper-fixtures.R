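# single-row evidence constructors with all-pass defaults; override a field
# to probe one rule at a time
mk_tx <- function(n = 1, ...) {
  base <- tibble::tibble(
    transcript_id = paste0("t", seq_len(n)),
    at_gene_locus = FALSE, length_nt = 500L, fpkm = 5,
    cpc_coding = FALSE, txcds_coding = FALSE, cnci_coding = FALSE,
    pfam_domain = FALSE, predictor_support = 3L
  )
  dplyr::mutate(base, ...)
}

mk_prot <- function(n = 1, ...) {
  base <- tibble::tibble(
    protein_id = paste0("p", seq_len(n)),
    length_aa = 150L, signal_peptide = TRUE, tm_domains = 0L,
    gpi_anchor = FALSE
  )
  dplyr::mutate(base, ...)
}
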