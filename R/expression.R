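#' Reads per kilobase
#'
#' `rpk = count / (length / 1000)`: the read count length-normalised to a
#' 1 kb transcript.
#'
#' @param count Read counts (numeric vector).
#' @param transcript_length Transcript lengths in bp (recycled).
#' @return Numeric vector of RPK values.
#' @export
rpk <- function(count, transcript_length) {
  if (any(transcript_length <= 0)) {
    abort("transcript_length must be positive", class = "mycomine_validation_error")
  }
  count / (transcript_length / 1000)
}

#' Transcripts per million
#'
#' `TPM = RPK / sum(RPK) * 1e6`, computed per sample, so every sample column
#' with any non-zero count sums to exactly one million (all-zero columns stay
#' all zero).
#'
#' @param counts Count table: tibble with columns `gene_id`, `length_nt` and
#'   one integer column per sample.
#' @return A tibble with `gene_id` plus one TPM column per sample.
#' @export
tpm <- function(counts) {
  stopifnot(all(c("gene_id", "length_nt") %in% names(counts)))
  samples <- setdiff(names(counts), c("gene_id", "length_nt"))
  out <- tibble(gene_id = counts$gene_id)
  for (s in samples) {
    r <- rpk(counts[[s]], counts$length_nt)
    tot <- sum(r)
    out[[s]] <- if (tot > 0) r / tot * 1e6 else r * 0
  }
  out
}

#' Fragments per kilobase per million mapped reads
#'
#' `fpkm = count * 1e9 / (length * library_size)`.
#'
#' @param count Read counts.
#' @param transcript_length Transcript lengths in bp.
#' @param library_size Total mapped reads in the library.
#' @return Numeric vector of FPKM values.
#' @export
fpkm <- function(count, transcript_length, library_size) {
  if (any(transcript_length <= 0) || any(library_size <= 0)) {
    abort("transcript_length and library_size must be positive",
          class = "mycomine_validation_error")
  }
  count * 1e9 / (transcript_length * library_size)
}

#' Two-sided Fisher exact test for a gene-vs-library 2x2 table
#'
#' Exact two-sided p-value for the table
#' \preformatted{           gene   rest-of-library
#'   group A   a      rest_a
#'   group B   b      rest_b}
#' computed by summing, over the hypergeometric support given the margins,
#' every table probability not exceeding the observed one (with the
#' conventional 1 + 1e-7 relative tolerance for floating-point ties).
#' Vectorised over all four arguments.
#'
#' @param gene_a,rest_a Gene count and remaining library count in group A.
#' @param gene_b,rest_b Same for group B.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_de <- function(gene_a, rest_a, gene_b, rest_b) {
  args <- vctrs_recycle(gene_a, rest_a, gene_b, rest_b)
  gene_a <- args[[1]]; rest_a <- args[[2]]; gene_b <- args[[3]]; rest_b <- args[[4]]
  if (any(c(gene_a, rest_a, gene_b, rest_b) < 0) ||
      any(c(gene_a, rest_a, gene_b, rest_b) != round(c(gene_a, rest_a, gene_b, rest_b)))) {
    abort("counts must be non-negative integers", class = "mycomine_validation_error")
  }
  vapply(seq_along(gene_a), function(i) {
    fisher_two_sided(gene_a[i], rest_a[i], gene_b[i], rest_b[i])
  }, numeric(1))
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, function(x) rep_len(x, n))
}

fisher_two_sided <- function(a, ra, b, rb) {
  m <- a + b          # gene margin
  n <- ra + rb        # rest margin
  k <- a + ra         # group A library size
  if (m == 0 || n + m == 0) return(1)
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  d <- dhyper(x, m, n, k)
  min(1, sum(d[d <= d[a - lo + 1] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper around [stats::p.adjust()]); adjusted
#' values are monotone in rank and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "mycomine_validation_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between two sample groups
#'
#' Per gene, counts are pooled within each group and tested against the rest
#' of the pooled library with the two-sided Fisher exact test
#' ([fisher_exact_de()]); p-values are FDR-adjusted by Benjamini-Hochberg.
#' Fold change is the ratio of group-mean TPM values. A gene is called:
#'
#' * `up` when `fold_change >= fc`, the (adjusted) p-value is below `alpha`,
#'   and the larger group-mean TPM exceeds `tpm_floor`;
#' * `down` symmetrically when `fold_change <= 1/fc`;
#' * `ns` otherwise.
#'
#' A nonzero-over-zero ratio is infinite fold change (passes the threshold;
#' the TPM floor guards against spurious calls); zero-over-zero is `NaN` and
#' always `ns`. An optional TPM pseudocount replaces this convention.
#'
#' @param counts Count table (`gene_id`, `length_nt`, sample columns).
#' @param groups Tibble mapping `sample_id` to `group`.
#' @param group_a,group_b Group labels to contrast (fold change and calls are
#'   oriented A over B).
#' @param fc Fold-change threshold (default 3).
#' @param alpha Significance level on the FDR (default 0.05).
#' @param tpm_floor Expression floor: the larger group-mean TPM must exceed
#'   this (default 0.5).
#' @param use_fdr Gate significance on the BH-adjusted value (default `TRUE`);
#'   `FALSE` uses the raw p-value.
#' @param pseudocount TPM pseudocount added to both group means before the
#'   ratio (default 0, i.e. off).
#' @return A `deg_contrast` object; [tidy()] returns the per-gene table
#'   (`gene_id`, `mean_tpm_a`, `mean_tpm_b`, `fold_change`, `p_value`, `fdr`,
#'   `call`), [glance()] a one-row summary.
#' @export
call_deg <- function(counts, groups, group_a, group_b, fc = 3, alpha = 0.05,
                     tpm_floor = 0.5, use_fdr = TRUE, pseudocount = 0) {
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  sa <- groups$sample_id[groups$group == group_a]
  sb <- groups$sample_id[groups$group == group_b]
  if (length(sa) == 0L || length(sb) == 0L) {
    abort("both groups need at least one sample", class = "mycomine_validation_error")
  }
  missing_cols <- setdiff(c(sa, sb), names(counts))
  if (length(missing_cols)) {
    abort(paste0("sample column(s) absent from counts: ",
                 paste(missing_cols, collapse = ", ")),
          class = "mycomine_validation_error")
  }
  tp <- tpm(counts)
  mean_a <- rowMeans(as.matrix(tp[sa])) + pseudocount
  mean_b <- rowMeans(as.matrix(tp[sb])) + pseudocount
  pooled_a <- as.integer(round(rowSums(as.matrix(counts[sa]))))
  pooled_b <- as.integer(round(rowSums(as.matrix(counts[sb]))))
  p <- fisher_exact_de(pooled_a, sum(pooled_a) - pooled_a,
                       pooled_b, sum(pooled_b) - pooled_b)
  fdr <- bh_fdr(p)
  fold <- mean_a / mean_b
  sig <- (if (use_fdr) fdr else p) < alpha
  expressed <- pmax(mean_a, mean_b) > tpm_floor
  call <- dplyr::case_when(
    expressed & sig & !is.nan(fold) & fold >= fc ~ "up",
    expressed & sig & !is.nan(fold) & fold <= 1 / fc ~ "down",
    TRUE ~ "ns"
  )
  res <- tibble(
    gene_id = counts$gene_id,
    mean_tpm_a = mean_a - pseudocount, mean_tpm_b = mean_b - pseudocount,
    fold_change = fold, p_value = p, fdr = fdr, call = call
  )
  structure(
    list(results = res, group_a = group_a, group_b = group_b,
         params = list(fc = fc, alpha = alpha, tpm_floor = tpm_floor,
                       use_fdr = use_fdr, pseudocount = pseudocount)),
    class = "deg_contrast"
  )
}

#' @export
print.deg_contrast <- function(x, ...) {
  cat("<deg_contrast> ", x$group_a, " vs ", x$group_b,
      "  (FC >= ", x$params$fc, ", ",
      if (x$params$use_fdr) "FDR" else "p", " < ", x$params$alpha,
      ", TPM floor ", x$params$tpm_floor, ")\n", sep = "")
  tab <- table(factor(x$results$call, levels = c("up", "down", "ns")))
  cat("  up: ", tab[["up"]], "  down: ", tab[["down"]], "  ns: ", tab[["ns"]],
      "  (", nrow(x$results), " genes)\n", sep = "")
  invisible(x)
}
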