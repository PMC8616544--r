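# Independent transitivity check used by the enumeration oracle: a literal
# triple loop, no closure computation.
is_transitive <- function(adj) {
  n <- nrow(adj)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (adj[i, j] && adj[j, k] && !adj[i, k]) return(FALSE)
  }
  TRUE
}

test_that("hierarchy enumeration matches a brute-force transitivity scan", {
  expect_length(enumerate_sgraphs(1), 1)
  expect_length(enumerate_sgraphs(2), 4)
  graphs <- enumerate_sgraphs(3)
  expect_length(graphs, 29)
  # oracle: scan all 64 off-diagonal patterns with a literal triple loop
  off <- which(!diag(TRUE, 3))
  n_valid <- 0
  for (code in 0:63) {
    adj <- diag(TRUE, 3)
    adj[off] <- as.logical(bitwAnd(bitwShiftR(code, 0:5), 1L))
    if (is_transitive(adj)) n_valid <- n_valid + 1
  }
  expect_equal(length(graphs), n_valid)
  # every member is reflexive, transitively closed (idempotent), and unique
  keys <- vapply(graphs, function(g) paste(as.integer(g), collapse = ""),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (g in graphs) {
    expect_true(all(diag(g)))
    expect_identical(transitive_closure(g), g)
  }
  # the chain (with its closure edge) is a member
  expect_true(any(vapply(graphs, identical, logical(1), chain_hierarchy())))
  expect_error(enumerate_sgraphs(6), "k <= 5")
})

test_that("predicted effect profiles follow reachability from perturbed nodes", {
  chain <- chain_hierarchy()
  eff <- predicted_effects(chain)
  expect_equal(dim(eff), c(4L, 7L))
  expect_true(all(eff["WNT", ]))                       # bottom node: all 7
  expect_false(any(eff["none", ]))                     # null attachment row
  expect_equal(unname(eff["TGFB", ]), grepl("TGFB", treatment_combos()))
  expect_equal(unname(eff["LATS", ]), treatment_combos() != "WNT")

  empty <- diag(TRUE, 3); dimnames(empty) <- list(treatments(), treatments())
  eff0 <- predicted_effects(empty)
  for (s in treatments()) {
    expect_equal(unname(eff0[s, ]), grepl(s, treatment_combos()))
  }

  full <- matrix(TRUE, 3, 3); dimnames(full) <- list(treatments(), treatments())
  expect_true(all(predicted_effects(full)[treatments(), ]))
})

test_that("uninformative evidence scores every graph at zero with flat posteriors", {
  R <- matrix(0, 5, 7, dimnames = list(paste0("g", 1:5), treatment_combos()))
  for (g in enumerate_sgraphs(3)) {
    sc <- score_graph(R, g)
    expect_equal(sc$log_score, 0)
    expect_equal(as.matrix(sc$attachment_posterior[-1]),
                 matrix(0.25, 5, 4), ignore_attr = TRUE)
  }
  fit <- infer_best(R)
  expect_equal(sum(fit$graph) - 3, 0)  # tie broken to the empty hierarchy
  expect_equal(fit$log_score, max(fit$score_table$log_score))
})

test_that("gene marginals match literal enumeration of the four attachments", {
  set.seed(61)
  graphs <- enumerate_sgraphs(3)
  for (rep in 1:10) {
    R <- matrix(rnorm(6 * 7, sd = 2), 6, 7,
                dimnames = list(paste0("g", 1:6), treatment_combos()))
    g <- graphs[[sample(29, 1)]]
    sc <- score_graph(R, g)
    eff <- predicted_effects(g)
    oracle <- sum(vapply(1:6, function(e) {
      per_att <- vapply(rownames(eff), function(s)
        0.25 * exp(sum(R[e, ] * eff[s, ])), numeric(1))
      log(sum(per_att))
    }, numeric(1)))
    expect_equal(sc$log_score, oracle, tolerance = 1e-9)
  }
})

test_that("scoring is invariant under joint relabeling of S-genes and evidence columns", {
  set.seed(62)
  R <- matrix(rnorm(8 * 7), 8, 7, dimnames = list(paste0("g", 1:8), treatment_combos()))
  g <- chain_hierarchy()
  base <- score_graph(R, g)$log_score
  # swap TGFB and WNT everywhere: relabel graph nodes and remap experiments
  perm <- c(TGFB = "WNT", LATS = "LATS", WNT = "TGFB")
  g2 <- g
  rownames(g2) <- colnames(g2) <- unname(perm[rownames(g)])
  g2 <- g2[treatments(), treatments()]
  remap <- vapply(treatment_combos(), function(cb) {
    canonical_combo(paste(unname(perm[combo_members(cb)]), collapse = "+"))
  }, character(1))
  R2 <- R[, order(match(remap, treatment_combos()))]
  colnames(R2) <- treatment_combos()
  expect_equal(score_graph(R2, g2)$log_score, base, tolerance = 1e-9)
})

test_that("posteriors normalise and respond monotonically to evidence", {
  set.seed(63)
  R <- matrix(rnorm(20 * 7), 20, 7,
              dimnames = list(paste0("g", 1:20), treatment_combos()))
  sc <- score_graph(R, chain_hierarchy())
  expect_equal(rowSums(as.matrix(sc$attachment_posterior[-1])),
               rep(1, 20), tolerance = 1e-9, ignore_attr = TRUE)
  # raising evidence in the WNT-single experiment (predicted only for the
  # WNT attachment under the empty graph) raises the WNT posterior
  empty <- diag(TRUE, 3); dimnames(empty) <- list(treatments(), treatments())
  R2 <- R
  R2[1, "WNT"] <- R[1, "WNT"] + 3
  p1 <- score_graph(R, empty)$attachment_posterior$WNT[1]
  p2 <- score_graph(R2, empty)$attachment_posterior$WNT[1]
  expect_gt(p2, p1)
})

test_that("strong chain evidence makes the chain beat all 28 alternatives", {
  ev <- synthetic_evidence(seed = 71, n_genes = 300)
  fit <- infer_best(ev$R)
  expect_identical(fit$graph, chain_hierarchy())
  chain_score <- fit$score_table$log_score[
    fit$score_table$edges == perturbnem:::format_edges(chain_hierarchy())]
  expect_true(all(fit$score_table$log_score[
    fit$score_table$edges != perturbnem:::format_edges(chain_hierarchy())] <
      chain_score))
  # regulator recovery: >= 95% of attached genes called correctly
  reg <- assign_regulators(fit, threshold = 0.9)
  truth_att <- ev$truth$genes$attachment[
    match(reg$gene_id, ev$truth$genes$gene_id)]
  attached <- truth_att %in% treatments()
  expect_gte(mean(reg$regulator[attached] == truth_att[attached]), 0.95)
})

test_that("regulator assignment applies the posterior threshold", {
  R <- matrix(0, 2, 7, dimnames = list(c("flat", "wnt"), treatment_combos()))
  R["wnt", "WNT"] <- 5  # only the WNT attachment predicts this experiment (empty graph)
  empty <- diag(TRUE, 3); dimnames(empty) <- list(treatments(), treatments())
  sc <- score_graph(R, empty)
  # direct softmax: attachment evidence (0, 0, 5, 0) under a uniform prior
  expect_equal(sc$attachment_posterior$WNT[2], exp(5) / (exp(5) + 3),
               tolerance = 1e-12)
  fit <- list(attachment_posterior = sc$attachment_posterior)
  class(fit) <- "nem_fit"
  asg <- assign_regulators(fit, threshold = 0.9)
  expect_equal(asg$assignment, c("unassigned", "WNT"))
})

test_that("bootstrap support is reproducible and exact in the degenerate case", {
  ev <- synthetic_evidence(seed = 73, n_genes = 200)
  # identity resample: support is the indicator of the full-data reduction
  fit <- infer_best(ev$R)
  red <- transitive_reduction(fit$graph)
  boot1 <- bootstrap_edges(ev$R, B = 1, seed = 1, resample = function(n) seq_len(n))
  for (i in seq_len(nrow(boot1$edges))) {
    expect_equal(boot1$edges$support_reduction[i],
                 as.integer(red[boot1$edges$from[i], boot1$edges$to[i]]))
  }
  expect_true(all(boot1$edges$support_reduction %in% 0:1))
  b1 <- bootstrap_edges(ev$R, B = 30, seed = 5)
  b2 <- bootstrap_edges(ev$R, B = 30, seed = 5)
  expect_identical(b1$edges, b2$edges)
  expect_true(all(b1$edges$support_reduction >= 0 & b1$edges$support_reduction <= 30))
})

test_that("transitive reduction strips closure edges but keeps 2-cycles", {
  chain <- chain_hierarchy()
  red <- transitive_reduction(chain)
  expect_true(red["TGFB", "LATS"] && red["LATS", "WNT"])
  expect_false(red["TGFB", "WNT"])
  cyc <- diag(TRUE, 3); dimnames(cyc) <- list(treatments(), treatments())
  cyc["TGFB", "LATS"] <- cyc["LATS", "TGFB"] <- TRUE
  redc <- transitive_reduction(cyc)
  expect_true(redc["TGFB", "LATS"] && redc["LATS", "TGFB"])
})
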