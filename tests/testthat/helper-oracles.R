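# independent reference computations used across tests

# two-sided Fisher exact p by explicit hypergeometric enumeration from
# binomial coefficients (lchoose), independent of dhyper
fisher_enum_oracle <- function(a, ra, b, rb) {
  m <- a + b; n <- ra + rb; k <- a + ra
  if (m == 0 || m + n == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  p <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  min(1, sum(p[p <= p[a - lo + 1] * (1 + 1e-7)]))
}

# BH step-up by the direct min-over-tail formula
bh_direct_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m]))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# total length of the union of 1-based inclusive intervals, by sweep line
union_length_oracle <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0L; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1L) cur_e <- max(cur_e, end[i])
    else { total <- total + (cur_e - cur_s + 1L); cur_s <- start[i]; cur_e <- end[i] }
  }
  total + (cur_e - cur_s + 1L)
}

# minimal gene-table constructor: genes laid end to end on one chromosome
mk_genes <- function(n, chrom = "c1", gene_len = 500L, gap = 100L,
                     kind = "protein_coding") {
  start <- seq(1L, by = gene_len + gap, length.out = n)
  tibble::tibble(
    gene_id = sprintf("%s_g%02d", chrom, seq_len(n)),
    chrom = chrom, start = start, end = start + gene_len - 1L,
    strand = "+", kind = kind, length_nt = gene_len
  )
}

mk_signatures <- function(genes, roles) {
  stopifnot(length(roles) == nrow(genes))
  tibble::tibble(gene_id = genes$gene_id, role = roles)[roles != "other", ]
}

members_set <- function(clusters) {
  unname(lapply(clusters$members, sort))
}
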