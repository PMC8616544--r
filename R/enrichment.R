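# Rank-based gene-set enrichment of contrast fold changes against phenotype
# signatures (e.g. the proliferative and invasive melanoma cell-state gene
# sets): a Wilcoxon rank-sum p-value on the set members' fold-change ranks,
# and the enrichment curve f(i) = |rank(i)/n - i/m| that visualises how far
# the members' ranks depart from an even spread.

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   member ids, tab-separated).
#' @return A named list of character vectors of member gene ids.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

# Resolve set members among the ranked genes; error listing missing ids when
# no member is present.
match_members <- function(gene_id, gene_set) {
  members <- which(gene_id %in% gene_set)
  if (length(members) == 0) {
    abort(paste0("no gene-set member found among ranked genes; missing ids: ",
                 paste(head(gene_set, 10), collapse = ", "),
                 if (length(gene_set) > 10) ", ..." else ""))
  }
  members
}

#' Wilcoxon rank-sum enrichment p-value
#'
#' Ranks genes by log2 fold change and tests the set members' values against
#' the non-members' with the Wilcoxon rank-sum test (ties mid-ranked).
#' `side = "up"` asks whether members sit at larger fold changes,
#' `side = "down"` at smaller; the default is two-sided.
#'
#' @param data A tibble with columns `gene_id` and `log2fc` (one contrast).
#' @param gene_set Character vector of member gene ids.
#' @param side `"two.sided"` (default), `"up"` or `"down"`.
#' @return The p-value.
#' @export
wilcoxon_enrichment <- function(data, gene_set, side = c("two.sided", "up", "down")) {
  side <- match.arg(side)
  stopifnot(all(c("gene_id", "log2fc") %in% names(data)))
  members <- match_members(data$gene_id, gene_set)
  alternative <- switch(side, two.sided = "two.sided", up = "greater", down = "less")
  if (length(members) == nrow(data)) {
    abort("gene set covers all ranked genes; no non-members to compare against")
  }
  stats::wilcox.test(data$log2fc[members], data$log2fc[-members],
                     alternative = alternative, exact = NULL)$p.value
}

#' Enrichment curve of a gene set along the fold-change ranking
#'
#' Genes are sorted by log2 fold change (descending by default, so the top
#' rank is the strongest up-regulation). For the i-th set member in rank
#' order, with global rank `rank(i)` among all `n` genes and `m` members in
#' total, the curve is `f(i) = |rank(i)/n - i/m|`; an evenly spread
#' (unenriched) set keeps f near zero, while a set concentrated at either
#' end pushes f towards one.
#'
#' @inheritParams wilcoxon_enrichment
#' @param descending Sort by decreasing fold change.
#' @param name Optional gene-set name carried into the result.
#' @return An object of class `enrichment_curve`: tibble `curve` with
#'   columns `i`, `rank`, `f`, plus `n`, `m`, and `name`.
#' @export
enrichment_curve <- function(data, gene_set, descending = TRUE, name = NULL) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(data)))
  members <- match_members(data$gene_id, gene_set)
  ord <- order(data$log2fc, decreasing = descending)
  n <- nrow(data)
  is_member <- seq_len(n) %in% members
  global_rank <- which(is_member[ord])
  m <- length(global_rank)
  f <- abs(global_rank / n - seq_len(m) / m)
  structure(
    list(curve = tibble(i = seq_len(m), rank = global_rank, f = f),
         n = n, m = m, name = name %||% "gene set"),
    class = "enrichment_curve"
  )
}

#' Enrich several gene sets against every contrast
#'
#' Convenience wrapper running [wilcoxon_enrichment()] for each gene set and
#' contrast of a results table.
#'
#' @param results A `contrast_results` tibble.
#' @param gene_sets Named list of gene-id vectors (see [read_gene_sets()]).
#' @param side Passed to [wilcoxon_enrichment()].
#' @return A tibble: `set`, `contrast`, `p_value`, `m` (members found), `n`.
#' @export
enrich_gene_sets <- function(results, gene_sets, side = "two.sided") {
  res <- as_tibble(results)
  purrr::map_dfr(names(gene_sets), function(nm) {
    purrr::map_dfr(unique(res$contrast), function(cb) {
      d <- dplyr::filter(res, .data$contrast == cb)
      found <- sum(d$gene_id %in% gene_sets[[nm]])
      p <- if (found == 0) NA_real_ else
        wilcoxon_enrichment(d, gene_sets[[nm]], side = side)
      tibble(set = nm, contrast = cb, p_value = p, m = found, n = nrow(d))
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("Enrichment curve for %s: m = %d of n = %d genes, mean f = %.3f\n",
              x$name, x$m, x$n, mean(x$curve$f)))
  invisible(x)
}
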