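# Sign-pattern census over the seven treatment contrasts, overlap and
# same-direction concordance between the single treatments, dominance
# classification in combined treatments, and the top-ranked gene tables for
# the two dominant Wnt patterns.

#' Enumerate the 128 possible sign patterns
#'
#' Every gene's direction of regulation across the seven treatment
#' combinations is a 7-vector over {+, -}, giving `2^7 = 128` possible
#' differential expression patterns. Patterns are encoded as strings like
#' `"++-+--+"` in [treatment_combos()] column order.
#'
#' @return Character vector of the 128 pattern strings.
#' @export
all_sign_patterns <- function() {
  grid <- expand.grid(rep(list(c("+", "-")), 7), stringsAsFactors = FALSE)
  sort(apply(grid[, 7:1], 1, paste, collapse = ""))
}

#' Census of differential expression sign patterns
#'
#' Assigns each gene the sign pattern of its log2 fold changes across the
#' seven contrasts and counts genes per pattern. By default only genes
#' significant in at least one contrast at the given FDR cutoff enter the
#' census (`significance_filter = NULL` counts every gene). Genes with a
#' zero fold change in any contrast have no defined sign and are excluded;
#' their number is recorded in the `n_excluded` attribute.
#'
#' @param results A `contrast_results` tibble.
#' @param significance_filter FDR cutoff for the at-least-one-contrast
#'   eligibility filter, or `NULL` for no filter.
#' @return A tibble with all 128 patterns: `pattern`, `count`, `rank`
#'   (by decreasing count), with attributes `n_total` and `n_excluded`.
#' @export
count_patterns <- function(results, significance_filter = 0.10) {
  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(results), "gene_id", "contrast", "log2fc"),
    names_from = "contrast", values_from = "log2fc"
  )
  lfc <- as.matrix(wide[treatment_combos()])
  keep <- rep(TRUE, nrow(wide))
  if (!is.null(significance_filter)) {
    sig <- tidyr::pivot_wider(
      dplyr::select(as_tibble(results), "gene_id", "contrast", "fdr"),
      names_from = "contrast", values_from = "fdr"
    )
    keep <- rowSums(as.matrix(sig[treatment_combos()]) <= significance_filter) >= 1
  }
  zero <- rowSums(lfc == 0) > 0
  n_excluded <- sum(keep & zero)
  keep <- keep & !zero
  pat <- apply(lfc[keep, , drop = FALSE], 1,
               function(x) paste(ifelse(x > 0, "+", "-"), collapse = ""))
  tab <- table(factor(pat, levels = all_sign_patterns()))
  out <- tibble(pattern = names(tab), count = as.integer(tab))
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$pattern)
  out$rank <- rank(-out$count, ties.method = "min")
  attr(out, "n_total") <- sum(out$count)
  attr(out, "n_excluded") <- n_excluded
  out
}

# Wide per-gene significance/sign tables for the three single treatments.
single_effects_wide <- function(effects) {
  singles <- treatments()
  e <- dplyr::filter(as_tibble(effects), .data$contrast %in% singles)
  sig <- tidyr::pivot_wider(dplyr::select(e, "gene_id", "contrast", "significant"),
                            names_from = "contrast", values_from = "significant")
  sgn <- tidyr::pivot_wider(dplyr::select(e, "gene_id", "contrast", "sign"),
                            names_from = "contrast", values_from = "sign")
  list(sig = sig, sgn = sgn)
}

#' Overlap and same-direction concordance of the single treatments
#'
#' For every non-empty subset of the three single treatments, counts genes
#' significant (at the prior 10%-FDR binarization) in exactly and in at least
#' that subset (the Venn decomposition). For each treatment pair, and for the
#' triple, counts shared significant genes and the fraction regulated in the
#' same direction.
#'
#' @param effects A binarized-effects tibble from [binarize_effects()].
#' @return An object of class `overlap_summary`: tibbles `venn` (subset,
#'   n_exact, n_at_least) and `pairwise` (a, b, shared, same_direction,
#'   fraction), and a list `triple` (shared, same_direction, fraction).
#'   Fractions over empty intersections are reported as `NA`.
#' @export
overlap_and_concordance <- function(effects) {
  w <- single_effects_wide(effects)
  singles <- treatments()
  sig <- as.matrix(w$sig[singles])
  sgn <- as.matrix(w$sgn[singles])
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(singles, k, paste, collapse = "+")), use.names = FALSE)
  venn <- purrr::map_dfr(subsets, function(ss) {
    mem <- singles %in% combo_members(ss)
    at_least <- rowSums(sig[, mem, drop = FALSE]) == sum(mem)
    exact <- at_least & rowSums(sig[, !mem, drop = FALSE]) == 0
    tibble(subset = ss, n_exact = sum(exact), n_at_least = sum(at_least))
  })
  pairs <- utils::combn(singles, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    shared <- sig[, a] & sig[, b]
    same <- shared & sgn[, a] == sgn[, b]
    tibble(a = a, b = b, shared = sum(shared), same_direction = sum(same),
           fraction = ifelse(sum(shared) == 0, NA_real_, sum(same) / sum(shared)))
  })
  all3 <- rowSums(sig) == 3
  same3 <- all3 & sgn[, 1] == sgn[, 2] & sgn[, 2] == sgn[, 3]
  structure(
    list(venn = venn, pairwise = pairwise,
         triple = list(shared = sum(all3), same_direction = sum(same3),
                       fraction = if (sum(all3) == 0) NA_real_ else sum(same3) / sum(all3))),
    class = "overlap_summary"
  )
}

#' Dominance of one single treatment over another in the combined treatment
#'
#' Over the genes significant in both single treatments but regulated in
#' opposite directions, a treatment dominates when the combined (double)
#' treatment regulates the gene in that treatment's direction. A zero fold
#' change in the combined contrast leaves the gene unresolved.
#'
#' @param results A `contrast_results` tibble (provides the combined-contrast
#'   fold changes).
#' @param effects The matching binarized effects.
#' @param a,b Two distinct single treatments, e.g. `"TGFB"` and `"WNT"`.
#' @param require_significant_combined Additionally require the combined
#'   contrast to be significant for a dominance call (unresolved otherwise).
#' @return A one-row tibble: `a`, `b`, `shared`, `same_direction`,
#'   `opposite`, `a_dominant`, `b_dominant`, `unresolved`. Conservation:
#'   `same_direction + a_dominant + b_dominant + unresolved == shared`.
#' @export
dominance <- function(results, effects, a, b, require_significant_combined = FALSE) {
  stopifnot(a %in% treatments(), b %in% treatments(), a != b)
  combined <- canonical_combo(paste(a, b, sep = "+"))
  w <- single_effects_wide(effects)
  res <- dplyr::filter(as_tibble(results), .data$contrast == combined)
  comb_lfc <- res$log2fc[match(w$sig$gene_id, res$gene_id)]
  comb_sig <- dplyr::filter(as_tibble(effects), .data$contrast == combined)
  comb_sig <- comb_sig$significant[match(w$sig$gene_id, comb_sig$gene_id)]
  shared <- w$sig[[a]] & w$sig[[b]]
  same <- shared & w$sgn[[a]] == w$sgn[[b]]
  opp <- shared & !same
  comb_sign <- sign(comb_lfc)
  resolved <- opp & comb_sign != 0
  if (require_significant_combined) resolved <- resolved & comb_sig
  a_dom <- resolved & comb_sign == w$sgn[[a]]
  b_dom <- resolved & comb_sign == w$sgn[[b]]
  tibble(
    a = a, b = b,
    shared = sum(shared), same_direction = sum(same), opposite = sum(opp),
    a_dominant = sum(a_dom), b_dominant = sum(b_dom),
    unresolved = sum(opp) - sum(a_dom) - sum(b_dom)
  )
}

#' Top-ranked genes of the two dominant Wnt expression patterns
#'
#' Restricts to genes significant (FDR below `fdr_cutoff`) in all three
#' single treatments, keeps those matching the requested pattern class —
#' class 1: all seven contrasts share one direction; class 2: the Wnt-3a
#' single treatment is opposite in direction to the other six contrasts
#' (which must share one direction) — and ranks them by the absolute log2
#' fold change of the Wnt-3a single treatment, descending (ties broken by
#' gene id).
#'
#' @param results A `contrast_results` tibble.
#' @param pattern_class 1 or 2.
#' @param top_n Maximum number of genes returned.
#' @param fdr_cutoff Significance filter applied to the three singles.
#' @return A tibble of at most `top_n` rows: `gene_id` plus the seven
#'   log2-fold-change columns, in rank order.
#' @export
top_pattern_genes <- function(results, pattern_class = 1, top_n = 30,
                              fdr_cutoff = 0.10) {
  stopifnot(pattern_class %in% c(1, 2))
  res <- as_tibble(results)
  lfc <- tidyr::pivot_wider(dplyr::select(res, "gene_id", "contrast", "log2fc"),
                            names_from = "contrast", values_from = "log2fc")
  fdr <- tidyr::pivot_wider(dplyr::select(res, "gene_id", "contrast", "fdr"),
                            names_from = "contrast", values_from = "fdr")
  keep <- rowSums(as.matrix(fdr[treatments()]) < fdr_cutoff) == 3
  lfc <- lfc[keep, , drop = FALSE]
  m <- as.matrix(lfc[treatment_combos()])
  if (any(m == 0)) {
    lfc <- lfc[rowSums(m == 0) == 0, , drop = FALSE]
    m <- as.matrix(lfc[treatment_combos()])
  }
  if (nrow(lfc) == 0) {
    return(lfc[, c("gene_id", treatment_combos()), drop = FALSE])
  }
  sgn <- sign(m)
  others <- setdiff(treatment_combos(), "WNT")
  other_same <- apply(sgn[, others, drop = FALSE], 1,
                      function(x) length(unique(x)) == 1)
  match_class <- if (pattern_class == 1) {
    other_same & sgn[, "WNT"] == sgn[, others[1]]
  } else {
    other_same & sgn[, "WNT"] != sgn[, others[1]]
  }
  out <- lfc[match_class, c("gene_id", treatment_combos()), drop = FALSE]
  out <- out[order(-abs(out$WNT), out$gene_id), , drop = FALSE]
  head(out, top_n)
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Single-treatment overlap and concordance\n")
  print(x$pairwise)
  cat(sprintf("  triple: shared %d, same direction %d (%.1f%%)\n",
              x$triple$shared, x$triple$same_direction,
              100 * x$triple$fraction))
  invisible(x)
}
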