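#' Tidy a differential-expression contrast
#'
#' @param x A `deg_contrast` from [call_deg()].
#' @param ... Unused.
#' @return The per-gene result tibble (`gene_id`, `mean_tpm_a`, `mean_tpm_b`,
#'   `fold_change`, `p_value`, `fdr`, `call`).
#' @method tidy deg_contrast
#' @export
tidy.deg_contrast <- function(x, ...) {
  x$results
}

#' Summarise a differential-expression contrast
#'
#' @param x A `deg_contrast`.
#' @param ... Unused.
#' @return A one-row tibble: groups, thresholds and up/down/ns tallies.
#' @method glance deg_contrast
#' @export
glance.deg_contrast <- function(x, ...) {
  tab <- table(factor(x$results$call, levels = c("up", "down", "ns")))
  tibble(
    group_a = x$group_a, group_b = x$group_b,
    n_genes = nrow(x$results),
    n_up = as.integer(tab[["up"]]), n_down = as.integer(tab[["down"]]),
    n_ns = as.integer(tab[["ns"]]),
    fc = x$params$fc, alpha = x$params$alpha, tpm_floor = x$params$tpm_floor
  )
}

#' Tidy a filter cascade
#'
#' @param x A `filter_cascade` from [filter_lncrna()] or
#'   [filter_effectors()].
#' @param ... Unused.
#' @return The per-stage tally tibble (`stage`, `excluded`, `remaining`).
#' @method tidy filter_cascade
#' @export
tidy.filter_cascade <- function(x, ...) {
  x$stages
}

#' Summarise a filter cascade
#'
#' @param x A `filter_cascade`.
#' @param ... Unused.
#' @return A one-row tibble: `n_input`, `n_accepted`, `n_excluded`.
#' @method glance filter_cascade
#' @export
glance.filter_cascade <- function(x, ...) {
  tibble(n_input = x$n_input, n_accepted = x$n_accepted,
         n_excluded = x$n_input - x$n_accepted)
}
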