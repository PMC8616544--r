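# Synthetic combinatorial perturbation screens with a known signalling
# hierarchy, so every downstream stage (DE, BUM, NEM, patterns, enrichment)
# can be benchmarked against ground truth.
#
# The generator emulates the layout of the study it benchmarks: two cell
# lines, eight conditions (control + 7 single/double/triple treatment
# combinations), technical duplicates, negative-binomial counts with a
# multiplicative per-gene cell-line batch effect, and a nested effect
# structure in which each responsive gene is attached to one node of a
# three-node hierarchy (default: the chain TGFB -> LATS -> WNT).

#' The default three-node hierarchy (chain TGFB -> LATS -> WNT)
#'
#' Returned as a reflexive, transitively closed logical adjacency matrix over
#' the three perturbations, the representation used throughout the NEM code.
#'
#' @return A 3 x 3 logical matrix.
#' @export
chain_hierarchy <- function() {
  s <- treatments()
  adj <- diag(TRUE, 3)
  dimnames(adj) <- list(s, s)
  adj["TGFB", "LATS"] <- TRUE
  adj["LATS", "WNT"] <- TRUE
  transitive_closure(adj)
}

#' Generate a ground-truth object for simulation
#'
#' Assigns each gene independently to one of the three hierarchy nodes (or to
#' none) with the given probabilities, draws signed effect sizes, and flags a
#' fraction of the WNT-attached genes as responding to the Wnt-3a single
#' treatment in the direction opposite to the upstream treatments — the
#' second dominant expression pattern seen in combinatorial screens of this
#' kind. Baseline expression is log-normal across genes and each gene carries
#' a log-normal cell-line (batch) effect.
#'
#' @param n_genes Number of genes.
#' @param fractions Named or unnamed numeric of length 3: probability that a
#'   gene attaches to TGFB, LATS, WNT (remainder unattached). Must sum to <= 1.
#' @param effect_magnitude Absolute log2 fold change of attached genes.
#' @param opposite_fraction Fraction of WNT-attached genes whose Wnt-3a-single
#'   response direction is flipped relative to upstream treatments.
#' @param hierarchy Reflexive transitively closed adjacency over the three
#'   nodes; default [chain_hierarchy()].
#' @param dispersion Per-gene negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param batch_sd Standard deviation (log2 units) of the per-gene cell-line
#'   effect.
#' @param seed Integer seed; the truth is reproducible given the seed.
#' @return An object of class `synthetic_truth`: a list with a per-gene
#'   tibble `genes`, the `hierarchy`, and the generation parameters.
#' @export
generate_truth <- function(n_genes = 1000,
                           fractions = c(TGFB = 0.1, LATS = 0.1, WNT = 0.1),
                           effect_magnitude = 2,
                           opposite_fraction = 0.5,
                           hierarchy = chain_hierarchy(),
                           dispersion = 0.1,
                           batch_sd = 0.5,
                           seed = 1L) {
  if (n_genes < 1) abort("n_genes must be >= 1")
  if (length(fractions) != 3 || any(fractions < 0) || sum(fractions) > 1) {
    abort("fractions must be 3 nonnegative proportions summing to at most 1")
  }
  if (opposite_fraction < 0 || opposite_fraction > 1) {
    abort("opposite_fraction must lie in [0, 1]")
  }
  stopifnot(all(diag(hierarchy)), identical(hierarchy, transitive_closure(hierarchy)))
  set.seed(seed)
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  attachment <- sample(c(treatments(), "none"), n_genes, replace = TRUE,
                       prob = c(fractions, 1 - sum(fractions)))
  sign_draw <- sample(c(-1, 1), n_genes, replace = TRUE)
  effect <- ifelse(attachment == "none", 0, sign_draw * effect_magnitude)
  wnt_opposite <- attachment == "WNT" & runif(n_genes) < opposite_fraction
  genes <- tibble(
    gene_id = gene_id,
    attachment = attachment,
    effect_log2fc = effect,
    wnt_opposite = wnt_opposite,
    dispersion = rep(dispersion, n_genes),
    baseline_mean = rlnorm(n_genes, meanlog = log(500), sdlog = 1),
    batch_log2fc = rnorm(n_genes, 0, batch_sd)
  )
  structure(
    list(genes = genes, hierarchy = hierarchy, seed = seed,
         params = list(fractions = fractions, effect_magnitude = effect_magnitude,
                       opposite_fraction = opposite_fraction,
                       dispersion = dispersion, batch_sd = batch_sd)),
    class = "synthetic_truth"
  )
}

#' Expected log2 fold change of every gene under one treatment combination
#'
#' A gene is affected by a combination iff its attachment node is reachable
#' in the hierarchy from at least one perturbed node. Affected genes carry
#' their attached effect size; for WNT-attached genes flagged as
#' Wnt-opposite, the sign is flipped only when the combination perturbs no
#' node strictly upstream of the gene's attachment — upstream perturbations
#' dominate the flipped Wnt direction in combined treatments.
#'
#' @param truth A `synthetic_truth`.
#' @param combo A non-empty treatment combination label, e.g. `"TGFB+WNT"`.
#' @return Numeric vector of per-gene expected log2 fold changes (0 for
#'   unaffected genes), named by gene id.
#' @export
expected_log2fc <- function(truth, combo) {
  combo <- canonical_combo(combo)
  if (combo == "") abort("combo must be non-empty (control has no fold change)")
  perturbed <- combo_members(combo)
  adj <- truth$hierarchy
  g <- truth$genes
  out <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    s <- g$attachment[i]
    if (s == "none") next
    affected <- any(adj[perturbed, s])
    if (!affected) next
    eff <- g$effect_log2fc[i]
    if (g$wnt_opposite[i] && "WNT" %in% perturbed) {
      upstream <- setdiff(rownames(adj)[adj[, s]], s)
      if (!any(perturbed %in% upstream)) eff <- -eff
    }
    out[i] <- eff
  }
  setNames(out, g$gene_id)
}

#' Simulate a count matrix and sample sheet from a ground truth
#'
#' Enumerates 2 cell lines x 8 conditions x `n_replicates` technical
#' replicates and draws negative-binomial counts with mean
#' `baseline_mean * 2^(batch_log2fc * L) * 2^(expected log2 fold change) * sf`,
#' where `sf` scales the expected control library of cell line 1 to
#' `library_size`, and variance `mu + dispersion * mu^2`.
#'
#' @param truth A `synthetic_truth`.
#' @param n_replicates Technical replicates per condition per cell line.
#' @param library_size Expected total counts of a control library of the
#'   first cell line.
#' @param seed Integer seed for the count draws; defaults to `truth$seed + 1`
#'   so truth generation and sampling can be re-run independently.
#' @return A list with elements `counts` (tibble, `gene_id` + one column per
#'   sample) and `samples` (sample sheet tibble).
#' @export
simulate_counts <- function(truth, n_replicates = 2, library_size = 1e6,
                            seed = truth$seed + 1L) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  g <- truth$genes
  set.seed(seed)
  samples <- tidyr::expand_grid(
    cell_line = c("line1", "line2"),
    combo = conditions(),
    replicate = seq_len(n_replicates)
  )
  cond_label <- ifelse(samples$combo == "", "ctrl", gsub("+", ".", samples$combo, fixed = TRUE))
  samples <- dplyr::mutate(
    samples,
    sample_id = paste(.data$cell_line, cond_label, paste0("r", .data$replicate), sep = "_"),
    .before = 1
  )
  sf <- library_size / sum(g$baseline_mean)
  elfc <- vapply(treatment_combos(), function(cb) expected_log2fc(truth, cb),
                 numeric(nrow(g)))
  if (!is.matrix(elfc)) {
    elfc <- matrix(elfc, nrow = 1, dimnames = list(NULL, treatment_combos()))
  }
  counts <- matrix(0L, nrow(g), nrow(samples),
                   dimnames = list(g$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    L <- as.numeric(samples$cell_line[j] == "line2")
    fc <- if (samples$combo[j] == "") 0 else elfc[, samples$combo[j]]
    mu <- g$baseline_mean * 2^(g$batch_log2fc * L) * 2^fc * sf
    counts[, j] <- rnbinom(nrow(g), mu = mu, size = 1 / g$dispersion)
  }
  list(
    counts = dplyr::bind_cols(tibble(gene_id = g$gene_id), as_tibble(counts)),
    samples = samples
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  tally <- table(factor(x$genes$attachment, levels = c(treatments(), "none")))
  cat("Synthetic perturbation-screen truth\n")
  cat("  genes:", nrow(x$genes), " seed:", x$seed, "\n")
  cat("  attachments:", paste(names(tally), tally, sep = "=", collapse = " "), "\n")
  cat("  hierarchy edges:",
      paste(apply(which(x$hierarchy & !diag(3), arr.ind = TRUE), 1, function(e)
        paste0(rownames(x$hierarchy)[e[1]], "->", colnames(x$hierarchy)[e[2]])),
        collapse = " "), "\n")
  invisible(x)
}
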