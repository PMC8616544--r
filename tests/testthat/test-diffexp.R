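test_that("TMM factors are symmetric, normalized, and track library scaling", {
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", 1:50)),
    tibble::as_tibble(matrix(rep(rpois(50, 100), 4), ncol = 4,
                             dimnames = list(NULL, paste0("s", 1:4)))))
  nf <- normalization_factors(counts)
  expect_equal(unname(nf$norm_factor), rep(1, 4))

  set.seed(1)
  base <- rpois(200, 50) + 1
  doubled <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", 1:200)),
    tibble::as_tibble(cbind(s1 = base, s2 = base, s3 = 2L * base)))
  nf2 <- normalization_factors(doubled)
  expect_equal(unname(nf2$offset[3] - nf2$offset[1]), log(2), tolerance = 1e-6)

  set.seed(2)
  rand <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", 1:300)),
    tibble::as_tibble(matrix(rnbinom(300 * 6, mu = 80, size = 5), ncol = 6,
                             dimnames = list(NULL, paste0("s", 1:6)))))
  nf3 <- normalization_factors(rand)
  expect_equal(exp(mean(log(nf3$norm_factor))), 1, tolerance = 1e-10)

  zero <- rand
  zero$s1 <- 0L
  expect_error(normalization_factors(zero), "all-zero")
})

test_that("identical samples give null fold changes and p-values of one", {
  samples <- tiny_samples(reps = 2)
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", 1:30)),
    tibble::as_tibble(matrix(rep(rpois(30, 200) + 10L, nrow(samples)),
                             ncol = nrow(samples),
                             dimnames = list(NULL, samples$sample_id))))
  res <- fit_contrasts(counts, build_design(samples))
  expect_equal(res$log2fc, rep(0, nrow(res)), tolerance = 1e-8)
  expect_equal(res$p_raw, rep(1, nrow(res)), tolerance = 1e-6)
})

test_that("GLM estimates match a hand-coded IRLS oracle at fixed dispersion", {
  truth <- generate_truth(n_genes = 10, seed = 31, fractions = c(0.3, 0.3, 0.3))
  sim <- simulate_counts(truth, n_replicates = 2)
  design <- build_design(sim$samples)
  norm <- normalization_factors(sim$counts)
  res <- fit_contrasts(sim$counts, design, norm, filter = FALSE, dispersion = 0.1)
  m <- as.matrix(sim$counts[-1])
  offs <- norm$offset[match(colnames(m), norm$sample_id)]
  for (i in seq_len(nrow(m))) {
    beta <- irls_nb(m[i, ], design, offs, phi = 0.1)
    est <- res$log2fc[res$gene_id == sim$counts$gene_id[i]]
    expect_equal(est, unname(beta[treatment_combos()]) / log(2), tolerance = 1e-3)
  }
})

test_that("a strong synthetic effect is estimated near its true size", {
  truth <- generate_truth(n_genes = 500, seed = 41)
  sim <- simulate_counts(truth)
  res <- fit_contrasts(sim$counts, build_design(sim$samples))
  tg <- dplyr::filter(res, .data$contrast == "TGFB",
                      .data$gene_id %in%
                        truth$genes$gene_id[truth$genes$attachment == "TGFB"])
  signs <- truth$genes$effect_log2fc[match(tg$gene_id, truth$genes$gene_id)]
  err <- tg$log2fc * sign(signs) - 2
  expect_equal(mean(err), 0, tolerance = 0.1)
  # per-gene sampling error at 4 vs 4 libraries and dispersion 0.1 has
  # log2-scale SE ~ 0.3; most genes land well inside two SEs
  expect_lt(unname(quantile(abs(err), 0.9)), 0.6)
})

test_that("log2fc bias shrinks as replication grows", {
  bias <- vapply(c(1, 4, 16), function(reps) {
    truth <- generate_truth(n_genes = 200, seed = 43, batch_sd = 0)
    sim <- simulate_counts(truth, n_replicates = reps)
    res <- fit_contrasts(sim$counts, build_design(sim$samples))
    tg <- dplyr::filter(res, .data$contrast == "TGFB",
                        .data$gene_id %in%
                          truth$genes$gene_id[truth$genes$attachment == "TGFB"])
    s <- truth$genes$effect_log2fc[match(tg$gene_id, truth$genes$gene_id)]
    mean(abs(tg$log2fc - s))
  }, numeric(1))
  expect_true(bias[3] < bias[1])
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(rep(1, 10)), rep(1, 10))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(5:50, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
  # invariance to input order
  p <- runif(100)
  perm <- sample(100)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.1, NaN)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("binarization applies the FDR cutoff to adjusted p-values", {
  lfc <- matrix(c(1, -1), nrow = 2, ncol = 7)
  fdr <- matrix(c(0.09, 0.11), nrow = 2, ncol = 7)
  res <- results_from_matrix(lfc, fdr)
  eff <- binarize_effects(res, cutoff = 0.10)
  expect_true(all(eff$significant[eff$gene_id == "g001"]))
  expect_false(any(eff$significant[eff$gene_id == "g002"]))
  expect_equal(unique(eff$sign[eff$gene_id == "g002"]), -1)
  # cutoff 0 switches everything off for positive fdr
  expect_false(any(binarize_effects(res, cutoff = 0)$significant))
  # per-contrast significant counts equal a direct threshold recount
  set.seed(8)
  res2 <- results_from_matrix(matrix(rnorm(50 * 7), 50),
                              matrix(runif(50 * 7), 50))
  eff2 <- binarize_effects(res2, 0.1)
  counts2 <- dplyr::count(dplyr::filter(eff2, .data$significant), .data$contrast)
  recount <- table(res2$contrast[res2$fdr <= 0.1])
  expect_equal(counts2$n, as.integer(recount[counts2$contrast]),
               ignore_attr = TRUE)
})

test_that("PCA input is log1p counts with the cell-line shift removable", {
  samples <- tiny_samples()
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", 1:20)),
    tibble::as_tibble(matrix(rpois(20 * nrow(samples), 50),
                             ncol = nrow(samples),
                             dimnames = list(NULL, samples$sample_id))))
  x <- pca_input(counts, samples)
  expect_equal(dim(x), c(nrow(samples), 20))
  expect_equal(unname(x[1, ]), log(as.numeric(counts[[samples$sample_id[1]]]) + 1))
  zero <- counts
  zero[[samples$sample_id[1]]][1] <- 0L
  expect_equal(pca_input(zero, samples)[samples$sample_id[1], 1], 0,
               ignore_attr = TRUE)

  # a single cell line leaves the matrix untouched
  one_line <- samples[samples$cell_line == "line1", ]
  expect_equal(pca_input(counts, one_line, remove_cell_line = TRUE),
               pca_input(counts, one_line), tolerance = 1e-9)

  # an injected additive shift on line 2 log counts is removed
  delta <- 0.7
  line2 <- samples$sample_id[samples$cell_line == "line2"]
  counts_shift <- counts
  for (s in line2) counts_shift[[s]] <- as.integer(round(exp(log(counts[[s]] + 1) + delta) - 1))
  cleaned <- pca_input(counts_shift, samples, remove_cell_line = TRUE)
  raw <- pca_input(counts_shift, samples, remove_cell_line = FALSE)
  gap_raw <- mean(raw[line2, ]) - mean(raw[setdiff(samples$sample_id, line2), ])
  gap_clean <- mean(cleaned[line2, ]) -
    mean(cleaned[setdiff(samples$sample_id, line2), ])
  expect_equal(gap_raw, delta, tolerance = 0.05)
  expect_equal(gap_clean, 0, tolerance = 1e-6)
})
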