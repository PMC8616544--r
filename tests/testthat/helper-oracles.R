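# Independent oracles used across tests. These reimplement the checked
# quantities by the most literal route available (brute force, enumeration,
# closed form) and deliberately share no code with the package internals.

# Benjamini-Hochberg by the literal step-up recipe: sort, scale by n/i,
# cumulative minimum from the largest p, unsort.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Negative-binomial log-link GLM by hand-coded iteratively reweighted least
# squares at fixed dispersion phi (variance mu + phi mu^2).
irls_nb <- function(y, X, offset, phi, maxit = 100, tol = 1e-10) {
  beta <- qr.solve(X, log(pmax(y, 0.5)) - offset)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- eta - offset + (y - mu) / mu
    beta_new <- qr.solve(sqrt(w) * X, sqrt(w) * z)
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# All C(n, m) placements of m member ranks among n: exact one-sided p-value
# for the rank-sum of the members (smaller rank-sum = members at the top).
exact_ranksum_p <- function(member_ranks, n, side = c("low", "high", "two.sided")) {
  side <- match.arg(side)
  m <- length(member_ranks)
  obs <- sum(member_ranks)
  placements <- utils::combn(n, m)
  sums <- colSums(placements)
  p_low <- mean(sums <= obs)
  p_high <- mean(sums >= obs)
  switch(side,
         low = p_low,
         high = p_high,
         two.sided = min(1, 2 * min(p_low, p_high)))
}

# A tiny deterministic sample sheet covering both cell lines, all 8
# conditions and `reps` replicates.
tiny_samples <- function(reps = 1) {
  grid <- expand.grid(cell_line = c("line1", "line2"),
                      combo = conditions(),
                      replicate = seq_len(reps),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = paste0("s", seq_len(nrow(grid))),
    cell_line = grid$cell_line,
    combo = grid$combo,
    replicate = grid$replicate
  )
}

# Long contrast-results tibble from a genes x 7 log2fc matrix (and optional
# matching fdr / p matrices), for pattern/dominance fixtures.
results_from_matrix <- function(lfc, fdr = NULL, p_raw = NULL) {
  combos <- treatment_combos()
  stopifnot(ncol(lfc) == 7)
  colnames(lfc) <- combos
  gene_id <- rownames(lfc)
  if (is.null(gene_id)) gene_id <- sprintf("g%03d", seq_len(nrow(lfc)))
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(gene_id = gene_id),
                     tibble::as_tibble(lfc)),
    -gene_id, names_to = "contrast", values_to = "log2fc")
  out$fdr <- if (is.null(fdr)) 0 else {
    colnames(fdr) <- combos
    f <- tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(gene_id = gene_id), tibble::as_tibble(fdr)),
      -gene_id, names_to = "contrast", values_to = "fdr")
    f$fdr
  }
  out$p_raw <- if (is.null(p_raw)) out$fdr else {
    colnames(p_raw) <- combos
    q <- tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(gene_id = gene_id), tibble::as_tibble(p_raw)),
      -gene_id, names_to = "contrast", values_to = "p")
    q$p
  }
  out
}

# End-to-end evidence matrix from a synthetic truth: simulate, fit, BUM.
synthetic_evidence <- function(seed, n_genes = 1000, ...) {
  truth <- generate_truth(n_genes = n_genes, seed = seed, ...)
  sim <- simulate_counts(truth, seed = seed + 1000L)
  res <- fit_contrasts(sim$counts, build_design(sim$samples))
  bum <- fit_bum(res$p_raw)
  list(truth = truth, results = res, bum = bum, R = log_density(res, bum))
}
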