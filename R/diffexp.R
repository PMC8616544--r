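# Differential expression over the 9-coefficient treatment design: TMM
# normalization offsets, per-gene negative-binomial GLM with a
# likelihood-ratio test per treatment-combination coefficient, BH correction,
# and 10%-FDR binarization. Model fitting is delegated to edgeR; the design
# and contrast bookkeeping, filtering and binarization live here.

#' Library-size and TMM scaling factors
#'
#' Computes per-sample library sizes and trimmed-mean-of-M-values scaling
#' factors (trim fractions: 30% on log-ratios, 5% on absolute intensities —
#' edgeR's defaults), with the combined log offset used by the gene model.
#' Factors are scaled so their geometric mean is 1.
#'
#' @param counts A count tibble (see [read_counts()]).
#' @return A tibble: `sample_id`, `lib_size`, `norm_factor`, `offset`
#'   (`log(lib_size * norm_factor)`).
#' @export
normalization_factors <- function(counts) {
  validate_counts(counts)
  m <- as.matrix(counts[-1])
  if (ncol(m) < 2) abort("need at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM")
  tibble(sample_id = colnames(m), lib_size = lib, norm_factor = f,
         offset = log(lib * f))
}

# Keep genes with >= min_cpm counts-per-million in >= min_samples samples;
# avoids degenerate GLM fits on all-zero or near-zero genes.
filter_expressed <- function(counts, min_cpm = 1, min_samples = 2) {
  m <- as.matrix(counts[-1])
  cpm <- t(t(m) / colSums(m)) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Fit the per-gene count model and test the seven treatment contrasts
#'
#' Fits, for every gene passing the expression filter (>= 1 count-per-million
#' in >= 2 samples), a negative-binomial log-linear model with the nine
#' design coefficients and TMM/library-size offsets, then tests each of the
#' seven treatment-combination coefficients against zero with a
#' likelihood-ratio test. Dispersions are estimated per gene by adjusted
#' profile likelihood and shrunk towards the common (pooled) dispersion with
#' `prior_df` prior degrees of freedom. P-values are BH-corrected within each
#' contrast.
#'
#' @param counts A count tibble.
#' @param design The 9-column design matrix from [build_design()].
#' @param norm Normalization tibble from [normalization_factors()]; computed
#'   if `NULL`.
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @param filter Apply the expression filter before fitting.
#' @param dispersion Optional fixed dispersion (scalar or per-gene vector)
#'   bypassing estimation; mainly for validation against reference fits.
#' @return A tibble of class `contrast_results`: one row per gene x contrast
#'   with `gene_id`, `contrast`, `log2fc`, `p_raw`, `fdr`, `dispersion`.
#' @export
fit_contrasts <- function(counts, design, norm = NULL, prior_df = 20,
                          filter = TRUE, dispersion = NULL) {
  validate_counts(counts)
  if (is.null(norm)) norm <- normalization_factors(counts)
  if (filter) counts <- filter_expressed(counts)
  m <- as.matrix(counts[-1])
  rownames(m) <- counts$gene_id
  if (!all(colnames(m) == rownames(design))) {
    design <- design[colnames(m), , drop = FALSE]
  }
  if (qr(design)$rank < ncol(design)) abort("design matrix is not of full column rank")
  offs <- norm$offset[match(colnames(m), norm$sample_id)]
  y <- edgeR::DGEList(counts = m)
  y <- edgeR::scaleOffset(y, offs)
  if (is.null(dispersion)) {
    y <- edgeR::estimateGLMCommonDisp(y, design)
    y <- edgeR::estimateGLMTagwiseDisp(y, design, prior.df = prior_df, trend = FALSE)
  } else {
    y$tagwise.dispersion <- rep_len(dispersion, nrow(m))
  }
  fit <- edgeR::glmFit(y, design, dispersion = y$tagwise.dispersion)
  combos <- treatment_combos()
  res <- purrr::map_dfr(combos, function(cb) {
    lrt <- edgeR::glmLRT(fit, coef = cb)
    tt <- lrt$table
    tibble(gene_id = rownames(tt), contrast = cb,
           log2fc = tt$logFC, p_raw = tt$PValue)
  })
  res <- dplyr::mutate(dplyr::group_by(res, .data$contrast),
                       fdr = bh_adjust(.data$p_raw))
  res <- dplyr::ungroup(res)
  res$dispersion <- y$tagwise.dispersion[match(res$gene_id, rownames(m))]
  res$contrast <- factor(res$contrast, levels = combos)
  res <- dplyr::arrange(res, .data$gene_id, .data$contrast)
  res$contrast <- as.character(res$contrast)
  class(res) <- c("contrast_results", class(res))
  res
}

#' Benjamini-Hochberg step-up correction
#'
#' @param p_raw Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values in `[0, 1]`.
#' @export
bh_adjust <- function(p_raw) {
  if (anyNA(p_raw)) abort("p-values contain NA/NaN")
  if (any(p_raw < 0 | p_raw > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p_raw, method = "BH")
}

#' Binarize contrast results at an FDR cutoff
#'
#' @param results A `contrast_results` tibble.
#' @param cutoff FDR threshold; the default 0.10 is the 10% cutoff used for
#'   all overlap, dominance and pattern analyses.
#' @return A tibble: `gene_id`, `contrast`, `significant` (fdr <= cutoff),
#'   `sign` (sign of `log2fc`).
#' @export
binarize_effects <- function(results, cutoff = 0.10) {
  dplyr::transmute(as_tibble(results),
                   gene_id = .data$gene_id,
                   contrast = .data$contrast,
                   significant = .data$fdr <= cutoff,
                   sign = sign(.data$log2fc))
}

#' Log-transformed matrix for principal component analysis
#'
#' Returns the samples x genes `log(x + 1)` matrix of raw counts. With
#' `remove_cell_line = TRUE` the additive cell-line effect is removed from
#' the log counts (per-gene least-squares fit of the cell-line indicator,
#' via limma's batch-removal), so that treatment structure is visible past
#' the dominant between-line variation.
#'
#' @param counts A count tibble.
#' @param samples A sample tibble.
#' @param remove_cell_line Remove the cell-line effect?
#' @return A numeric matrix, samples in rows, genes in columns.
#' @export
pca_input <- function(counts, samples, remove_cell_line = FALSE) {
  validate_counts(counts)
  m <- log(as.matrix(counts[-1]) + 1)  # genes x samples
  rownames(m) <- counts$gene_id
  m <- m[, samples$sample_id, drop = FALSE]
  if (remove_cell_line && length(unique(samples$cell_line)) > 1) {
    m <- limma::removeBatchEffect(m, batch = factor(samples$cell_line))
  }
  t(m)
}
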