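#' Classify fruiting-related genes from two contrasts
#'
#' A fruiting-related gene (FRG) is a gene up-regulated in fruiting bodies
#' relative to vegetative mycelium. Given the two contrasts — fruiting body
#' vs monokaryotic mycelium and fruiting body vs dikaryotic mycelium — the
#' default calls a gene an FRG when it is called `up` in **both** contrasts;
#' `require_both = FALSE` switches to either-contrast semantics. Swapping
#' `direction = "down"` yields vegetative-associated sets; the same machinery
#' applied to lncRNA contrasts yields fruiting-related / vegetative
#' hyphae-related lncRNA sets.
#'
#' @param contrast_mono,contrast_di `deg_contrast` objects computed on the
#'   same gene universe (fruiting body as group A in both).
#' @param require_both Require the call in both contrasts (default `TRUE`).
#' @param direction `"up"` (default) or `"down"`.
#' @return Character vector of gene identifiers.
#' @export
classify_frg <- function(contrast_mono, contrast_di, require_both = TRUE,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(contrast_mono, "deg_contrast"),
            inherits(contrast_di, "deg_contrast"))
  rm_ <- contrast_mono$results
  rd_ <- contrast_di$results
  if (!identical(sort(rm_$gene_id), sort(rd_$gene_id))) {
    abort("contrasts were not computed on the same gene universe",
          class = "mycomine_validation_error")
  }
  set_m <- rm_$gene_id[rm_$call == direction]
  set_d <- rd_$gene_id[rd_$call == direction]
  out <- if (require_both) intersect(set_m, set_d) else union(set_m, set_d)
  rm_$gene_id[rm_$gene_id %in% out]   # stable gene-universe order
}

#' Four-way ortholog-overlap classification of FRGs
#'
#' Partitions a fruiting-related gene set by its ortholog evidence against
#' reference developmental gene sets (fruiting-body initiation genes, FBIGs,
#' and fruiting-body development genes, FBDGs, of a model agaric). Hits are
#' first filtered to `e_value <= e_cut`; each gene is then assigned the
#' first matching class:
#'
#' 1. `fbig_ortholog` — some hit subject is an FBIG (FBIG takes precedence
#'    over FBDG so the partition is disjoint);
#' 2. `fbdg_ortholog` — some hit subject is an FBDG;
#' 3. `other_ortholog` — it has a filtered hit, but to neither set;
#' 4. `species_specific` — no filtered hit at all.
#'
#' @param frg_ids Character vector of FRG identifiers.
#' @param ortholog_hits Tibble of hits (`query`, `subject`, `e_value`).
#' @param fbig_ids,fbdg_ids Character vectors of reference gene identifiers.
#' @param e_cut E-value cutoff (default 1e-5).
#' @return A tibble `gene_id`, `class` (factor with the four levels above);
#'   the partition is exhaustive and disjoint.
#' @export
venn_classes <- function(frg_ids, ortholog_hits, fbig_ids, fbdg_ids,
                         e_cut = 1e-5) {
  stopifnot(all(c("query", "subject", "e_value") %in% names(ortholog_hits)))
  hits <- ortholog_hits[ortholog_hits$e_value <= e_cut, ]
  has_fbig <- frg_ids %in% hits$query[hits$subject %in% fbig_ids]
  has_fbdg <- frg_ids %in% hits$query[hits$subject %in% fbdg_ids]
  has_any <- frg_ids %in% hits$query
  cls <- dplyr::case_when(
    has_fbig ~ "fbig_ortholog",
    has_fbdg ~ "fbdg_ortholog",
    has_any ~ "other_ortholog",
    TRUE ~ "species_specific"
  )
  tibble(
    gene_id = frg_ids,
    class = factor(cls, levels = c("fbig_ortholog", "fbdg_ortholog",
                                   "other_ortholog", "species_specific"))
  )
}

#' Coverage of a reference gene set by ortholog hits
#'
#' Counts how many reference genes (e.g. the 666 fruiting-body initiation
#' genes of a model agaric) are hit by at least one query at
#' `e_value <= e_cut`, and expresses it as a percentage rounded to one
#' decimal (254 of 666 prints as 38.1).
#'
#' @param ortholog_hits Tibble of hits (`query`, `subject`, `e_value`).
#' @param fbig_ids Non-empty character vector of reference identifiers.
#' @param e_cut E-value cutoff (default 1e-5).
#' @return A one-row tibble: `count`, `percent`.
#' @export
fbig_coverage <- function(ortholog_hits, fbig_ids, e_cut = 1e-5) {
  if (length(fbig_ids) == 0L) {
    abort("fbig_ids must be non-empty", class = "mycomine_validation_error")
  }
  hits <- ortholog_hits[ortholog_hits$e_value <= e_cut, ]
  count <- length(intersect(fbig_ids, hits$subject))
  tibble(count = count, percent = round(count / length(fbig_ids) * 100, 1))
}
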