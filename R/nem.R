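# Exhaustive nested effects model over the three perturbed signalling nodes
# (S-genes). A candidate hierarchy is a reflexive, transitively closed
# digraph Phi over the S-genes; perturbing a node propagates to every node
# reachable from it, so a gene attached at node s is predicted to respond in
# exactly the experiments that perturb some node upstream of (or equal to) s.
# Each candidate is scored against the beta-uniform-mixture log densities R:
# per gene e and attachment s the evidence is A(e,s) = sum_j R(e,j) * E(s,j)
# with E the predicted 0/1 effect profile, the gene's marginal integrates the
# attachment out under a uniform prior over {TGFB, LATS, WNT, none}, and the
# graph's log score sums the gene marginals. With only three S-genes the 29
# candidate quasi-orders are enumerated and scored exhaustively.

#' Transitive closure / reduction of an adjacency matrix
#'
#' `transitive_closure()` saturates reachability (and keeps the diagonal
#' reflexive); `transitive_reduction()` drops an edge i -> j when some third
#' node k with i -> k and k -> j carries the same reachability, unless k is
#' mutually reachable with i or j (so 2-cycles between equivalent nodes are
#' kept intact).
#'
#' @param adj Square logical adjacency matrix.
#' @return A logical matrix of the same shape.
#' @export
transitive_closure <- function(adj) {
  adj <- adj | diag(TRUE, nrow(adj))
  repeat {
    nxt <- adj | ((adj %*% adj) > 0)
    if (identical(nxt, adj)) return(adj)
    adj <- nxt
  }
}

#' @rdname transitive_closure
#' @export
transitive_reduction <- function(adj) {
  n <- nrow(adj)
  red <- adj & !diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !adj[i, j]) next
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      if (adj[i, k] && adj[k, j] && !adj[k, i] && !adj[j, k]) {
        red[i, j] <- FALSE
        break
      }
    }
  }
  red
}

#' Enumerate all transitively closed hierarchies over k S-genes
#'
#' Scans all `2^(k(k-1))` off-diagonal adjacency patterns and keeps those
#' equal to their own transitive closure. For k = 3 there are 29 such
#' quasi-orders.
#'
#' @param k Number of S-genes (at most 5; enumeration is exhaustive).
#' @param sgenes Node labels; default [treatments()] for k = 3.
#' @return A list of reflexive, transitively closed logical adjacency
#'   matrices.
#' @export
enumerate_sgraphs <- function(k = 3, sgenes = if (k == 3) treatments() else paste0("S", seq_len(k))) {
  if (k < 1) abort("k must be >= 1")
  if (k > 5) abort("exhaustive enumeration is limited to k <= 5")
  off <- which(!diag(TRUE, k))
  graphs <- list()
  for (code in seq_len(2^length(off)) - 1L) {
    adj <- diag(TRUE, k)
    adj[off] <- as.logical(bitwAnd(bitwShiftR(code, seq_along(off) - 1L), 1L))
    if (identical(transitive_closure(adj), adj)) {
      dimnames(adj) <- list(sgenes, sgenes)
      graphs[[length(graphs) + 1]] <- adj
    }
  }
  graphs
}

#' The perturbation map of the seven treatment combinations
#'
#' @return A 7 x 3 logical matrix: experiment (rows, in [treatment_combos()]
#'   order) x S-gene, TRUE where the experiment perturbs the S-gene.
#' @export
perturbation_map <- function() {
  combos <- treatment_combos()
  m <- t(vapply(combos, function(cb) treatments() %in% combo_members(cb),
                logical(3)))
  dimnames(m) <- list(combos, treatments())
  m
}

#' Predicted effect profiles of a hierarchy
#'
#' Entry (s, j) is TRUE iff attachment node s is reachable in the graph from
#' at least one S-gene perturbed in experiment j; the `"none"` attachment row
#' is all FALSE.
#'
#' @param graph A reflexive, transitively closed adjacency matrix.
#' @param perturbations The experiments x S-genes map; default
#'   [perturbation_map()].
#' @return A 4 x 7 logical matrix, rows `TGFB`, `LATS`, `WNT`, `none`.
#' @export
predicted_effects <- function(graph, perturbations = perturbation_map()) {
  sgenes <- colnames(graph)
  eff <- matrix(FALSE, nrow = length(sgenes) + 1, ncol = nrow(perturbations),
                dimnames = list(c(sgenes, "none"), rownames(perturbations)))
  for (s in sgenes) for (j in seq_len(nrow(perturbations))) {
    perturbed <- sgenes[perturbations[j, ]]
    eff[s, j] <- any(graph[perturbed, s])
  }
  eff
}

# Coerce a log-density input (wide tibble from log_density() or a plain
# matrix) to a genes x experiments numeric matrix with gene ids as row names.
as_logdensity_matrix <- function(R) {
  if (is.matrix(R)) {
    if (is.null(rownames(R))) rownames(R) <- paste0("gene", seq_len(nrow(R)))
    return(R[, treatment_combos(), drop = FALSE])
  }
  stopifnot(is.data.frame(R), "gene_id" %in% names(R))
  m <- as.matrix(R[treatment_combos()])
  rownames(m) <- R$gene_id
  m
}

#' Score one candidate hierarchy against the log-density evidence
#'
#' Per gene, the attachment evidence is `A(e, s) = sum_j R(e, j) * E(s, j)`;
#' the gene marginal is `log sum_s prior(s) exp A(e, s)` (computed stably)
#' and the attachment posterior is the corresponding softmax. The graph's
#' log score is the sum of gene marginals.
#'
#' @param R Log-density evidence: the wide tibble from [log_density()] or a
#'   genes x 7 matrix with [treatment_combos()] columns.
#' @param graph A candidate hierarchy (reflexive, transitively closed).
#' @param prior Attachment prior over `{TGFB, LATS, WNT, none}`; uniform by
#'   default.
#' @return A list: `log_score` and `attachment_posterior` (tibble, one row
#'   per gene with a probability column per attachment).
#' @export
score_graph <- function(R, graph, prior = rep(1 / 4, 4)) {
  Rm <- as_logdensity_matrix(R)
  stopifnot(all(is.finite(Rm)), length(prior) == 4, all(prior > 0))
  eff <- predicted_effects(graph)
  A <- Rm %*% t(eff)  # genes x 4 attachment evidence
  A <- sweep(A, 2, log(prior), `+`)
  marg <- row_logsumexp(A)
  post <- exp(A - marg)
  list(
    log_score = sum(marg),
    attachment_posterior = dplyr::bind_cols(tibble(gene_id = rownames(Rm)),
                                            as_tibble(post))
  )
}

# Deterministic candidate ordering used for tie-breaking: fewer edges first,
# then lexicographic on the row-major adjacency pattern.
graph_priority <- function(graphs) {
  n_edges <- vapply(graphs, function(g) sum(g) - nrow(g), integer(1))
  lexkey <- vapply(graphs, function(g) paste(as.integer(t(g)), collapse = ""),
                   character(1))
  order(n_edges, lexkey)
}

# Per-gene marginal log-likelihood matrix (genes x graphs); column sums are
# the graph log scores, and resampling genes only permutes/repeats rows, so
# the bootstrap reuses this matrix.
marginal_matrix <- function(Rm, graphs, prior) {
  lp <- log(prior)
  vapply(graphs, function(g) {
    A <- sweep(Rm %*% t(predicted_effects(g)), 2, lp, `+`)
    row_logsumexp(A)
  }, numeric(nrow(Rm)))
}

# Index of the best-scoring graph with the deterministic tie-break.
best_graph_index <- function(scores, priority_rank, tol = 0) {
  cand <- which(scores >= max(scores) - tol)
  cand[which.min(priority_rank[cand])]
}

#' Infer the best hierarchy by exhaustive scoring
#'
#' Scores every transitively closed 3-node hierarchy against the evidence and
#' returns the maximum-score graph. Ties are broken deterministically in
#' favour of fewer edges, then lexicographically on the adjacency pattern, so
#' uninformative evidence yields the empty hierarchy.
#'
#' @inheritParams score_graph
#' @return An object of class `nem_fit`: the winning `graph`, its
#'   `log_score`, the full `score_table` (one row per candidate), the
#'   per-gene `attachment_posterior`, and the per-gene maximum-posterior
#'   `regulator` assignment.
#' @export
infer_best <- function(R, prior = rep(1 / 4, 4)) {
  Rm <- as_logdensity_matrix(R)
  if (nrow(Rm) < 1) abort("need at least one gene")
  stopifnot(all(is.finite(Rm)))
  graphs <- enumerate_sgraphs(3)
  M <- marginal_matrix(Rm, graphs, prior)
  scores <- colSums(M)
  prio <- graph_priority(graphs)
  prank <- integer(length(graphs)); prank[prio] <- seq_along(graphs)
  # Ties are exact (identical floating-point scores, e.g. uninformative R).
  best_i <- best_graph_index(scores, prank)
  best <- graphs[[best_i]]
  sc <- score_graph(Rm, best, prior)
  post <- sc$attachment_posterior
  labs <- c(treatments(), "none")
  reg <- labs[max.col(as.matrix(post[labs]), ties.method = "first")]
  score_table <- tibble(
    graph_id = seq_along(graphs),
    edges = vapply(graphs, format_edges, character(1)),
    n_edges = vapply(graphs, function(g) sum(g) - nrow(g), integer(1)),
    log_score = scores
  )
  structure(
    list(graph = best, log_score = scores[best_i],
         score_table = score_table,
         attachment_posterior = post,
         regulator = setNames(reg, post$gene_id),
         prior = prior, n_genes = nrow(Rm)),
    class = "nem_fit"
  )
}

format_edges <- function(g) {
  e <- which(g & !diag(nrow(g)), arr.ind = TRUE)
  if (nrow(e) == 0) return("(empty)")
  paste(paste0(rownames(g)[e[, 1]], "->", colnames(g)[e[, 2]]), collapse = ",")
}

#' Assign each gene to a regulator at a posterior threshold
#'
#' A gene is assigned to its maximum-posterior attachment iff that posterior
#' exceeds the threshold; otherwise it is reported `"unassigned"`. Genes
#' whose winning attachment is `"none"` are non-responders.
#'
#' @param fit A `nem_fit`.
#' @param threshold Posterior probability threshold (default 0.9).
#' @return A tibble: `gene_id`, `regulator` (maximum-posterior attachment),
#'   `posterior` (its probability), `assignment` (the regulator label or
#'   `"unassigned"`).
#' @export
assign_regulators <- function(fit, threshold = 0.9) {
  stopifnot(inherits(fit, "nem_fit"))
  post <- fit$attachment_posterior
  labs <- c(treatments(), "none")
  pm <- as.matrix(post[labs])
  idx <- max.col(pm, ties.method = "first")
  pmax_ <- pm[cbind(seq_len(nrow(pm)), idx)]
  tibble(
    gene_id = post$gene_id,
    regulator = labs[idx],
    posterior = pmax_,
    assignment = ifelse(pmax_ > threshold, labs[idx], "unassigned")
  )
}

#' Bootstrap support for the inferred edges
#'
#' Each run resamples genes (rows of the evidence matrix) with replacement to
#' the original size, re-infers the best hierarchy, and records the edges of
#' that hierarchy's transitive reduction (the display form of the graph);
#' support for the closure (reachability) edges is tallied alongside.
#'
#' @inheritParams score_graph
#' @param B Number of bootstrap runs.
#' @param seed Integer seed; results are fully reproducible.
#' @param resample Optional function `n -> integer indices` replacing the
#'   default `sample(n, n, replace = TRUE)` (used for degenerate-bootstrap
#'   checks).
#' @return An object of class `bootstrap_support`: a tibble `edges` with one
#'   row per ordered S-gene pair (`from`, `to`, `support_reduction`,
#'   `support_closure`), plus `B` and `seed`.
#' @export
bootstrap_edges <- function(R, B = 10000, seed = 1L, prior = rep(1 / 4, 4),
                            resample = NULL) {
  if (B < 1) abort("B must be >= 1")
  Rm <- as_logdensity_matrix(R)
  graphs <- enumerate_sgraphs(3)
  M <- marginal_matrix(Rm, graphs, prior)
  prio <- graph_priority(graphs)
  prank <- integer(length(graphs)); prank[prio] <- seq_along(graphs)
  red <- lapply(graphs, transitive_reduction)
  clo <- lapply(graphs, function(g) g & !diag(nrow(g)))
  s <- treatments()
  pairs <- expand.grid(to = s, from = s, stringsAsFactors = FALSE)[, c("from", "to")]
  pairs <- pairs[pairs$from != pairs$to, ]
  n_red <- matrix(0L, 3, 3, dimnames = list(s, s))
  n_clo <- n_red
  n <- nrow(Rm)
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- if (is.null(resample)) sample.int(n, n, replace = TRUE) else resample(n)
    scores <- colSums(M[idx, , drop = FALSE])
    i <- best_graph_index(scores, prank)
    n_red <- n_red + red[[i]]
    n_clo <- n_clo + clo[[i]]
  }
  edges <- tibble(
    from = pairs$from, to = pairs$to,
    support_reduction = n_red[cbind(pairs$from, pairs$to)],
    support_closure = n_clo[cbind(pairs$from, pairs$to)]
  )
  structure(list(edges = edges, B = B, seed = seed), class = "bootstrap_support")
}

#' @export
print.nem_fit <- function(x, ...) {
  cat("Nested effects model fit (exhaustive, 3 S-genes)\n")
  cat("  best hierarchy:", format_edges(x$graph), "\n")
  cat(sprintf("  log score: %.3f over %d genes, %d candidate graphs\n",
              x$log_score, x$n_genes, nrow(x$score_table)))
  invisible(x)
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat(sprintf("Bootstrap edge support (%d runs, seed %d)\n", x$B, x$seed))
  print(x$edges)
  invisible(x)
}
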