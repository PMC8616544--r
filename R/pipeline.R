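# Orchestration: run the full analysis (or a synthetic benchmark) from a
# YAML config, writing every stage's output plus a JSON manifest. The single
# global seed is expanded deterministically into per-stage child seeds
# (truth = seed, counts = seed + 1, bootstrap = seed + 2) so any stage can be
# rerun in isolation.

#' Default pipeline configuration
#'
#' @param output_dir Output directory.
#' @param seed Global seed.
#' @return A nested list mirroring the YAML config layout: `paths` (counts,
#'   samples, gene_sets, output_dir), `fdr_cutoff`, `posterior_threshold`,
#'   `bootstrap_B`, `seed`, and a `synthetic` block (enabled + generator
#'   settings).
#' @export
default_config <- function(output_dir = "perturbnem_out", seed = 1L) {
  list(
    paths = list(counts = NULL, samples = NULL, gene_sets = NULL,
                 output_dir = output_dir),
    fdr_cutoff = 0.10,
    posterior_threshold = 0.9,
    bootstrap_B = 10000L,
    seed = as.integer(seed),
    synthetic = list(
      enabled = TRUE, n_genes = 1000L,
      fractions = c(TGFB = 0.1, LATS = 0.1, WNT = 0.1),
      effect_magnitude = 2, opposite_fraction = 0.5,
      dispersion = 0.1, batch_sd = 0.5,
      n_replicates = 2L, library_size = 1e6
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unset fields fall back to [default_config()] values.
#'
#' @param path Path to a YAML file.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(utils::modifyList(default_config(), cfg))
}

validate_config <- function(config) {
  if (config$fdr_cutoff <= 0 || config$fdr_cutoff >= 1) {
    abort("fdr_cutoff must lie in (0, 1)")
  }
  if (config$posterior_threshold <= 0 || config$posterior_threshold >= 1) {
    abort("posterior_threshold must lie in (0, 1)")
  }
  if (config$bootstrap_B < 1) abort("bootstrap_B must be >= 1")
  config
}

stage_log <- function(stage, ..., t0) {
  message(sprintf("[%s] %s (%.1fs)", stage, paste0(...),
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes input/simulation -> differential expression -> beta-uniform
#' mixture -> nested effects model (+ bootstrap) -> sign patterns,
#' overlap/dominance -> enrichment (if gene sets are configured), writes all
#' stage outputs under `output_dir`, and returns a manifest. The same config
#' and seed give byte-identical numeric outputs.
#'
#' @param config A config list (see [default_config()]) or path to a YAML
#'   file.
#' @return The manifest list, invisibly: parameters, per-stage dimensions,
#'   the inferred hierarchy, and output paths.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  out <- config$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  manifest <- list(package_version = as.character(utils::packageVersion("perturbnem")),
                   seed = config$seed, parameters = config[c("fdr_cutoff",
                     "posterior_threshold", "bootstrap_B")], stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(error = conditionMessage(e))
      write_manifest()
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  # -- inputs ----------------------------------------------------------------
  truth <- NULL
  if (isTRUE(config$synthetic$enabled)) {
    sim <- run_stage("input", {
      syn <- config$synthetic
      truth <- generate_truth(
        n_genes = syn$n_genes, fractions = unlist(syn$fractions),
        effect_magnitude = syn$effect_magnitude,
        opposite_fraction = syn$opposite_fraction,
        dispersion = syn$dispersion, batch_sd = syn$batch_sd,
        seed = config$seed
      )
      simulate_counts(truth, n_replicates = syn$n_replicates,
                      library_size = syn$library_size,
                      seed = config$seed + 1L)
    })
    counts <- sim$counts
    samples <- sim$samples
    write_counts(counts, file.path(out, "counts.tsv"))
    write_sample_table(samples, file.path(out, "samples.tsv"))
    jsonlite::write_json(
      list(hierarchy_edges = format_edges(transitive_reduction(truth$hierarchy)),
           attachments = as.list(table(truth$genes$attachment))),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    counts <- run_stage("input", read_counts(config$paths$counts))
    samples <- run_stage("input", read_sample_table(config$paths$samples, counts))
  }
  manifest$stages$input <- list(n_genes = nrow(counts), n_samples = nrow(samples))
  stage_log("input", nrow(counts), " genes x ", nrow(samples), " samples", t0 = t0)

  # -- differential expression ----------------------------------------------
  results <- run_stage("diffexp", {
    design <- build_design(samples)
    norm <- normalization_factors(counts)
    fit_contrasts(counts, design, norm)
  })
  effects <- binarize_effects(results, cutoff = config$fdr_cutoff)
  readr::write_tsv(as_tibble(results), file.path(out, "contrasts.tsv"), progress = FALSE)
  readr::write_tsv(effects, file.path(out, "binary_effects.tsv"), progress = FALSE)
  manifest$stages$diffexp <- list(
    n_genes_tested = dplyr::n_distinct(results$gene_id),
    n_significant = sum(effects$significant))
  stage_log("diffexp", dplyr::n_distinct(results$gene_id), " genes tested", t0 = t0)

  # -- beta-uniform mixture --------------------------------------------------
  bum <- run_stage("bum", fit_bum(results$p_raw))
  R <- log_density(results, bum)
  jsonlite::write_json(unclass(bum), file.path(out, "bum.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(R, file.path(out, "log_densities.tsv"), progress = FALSE)
  manifest$stages$bum <- list(lambda = bum$lambda, a = bum$a)
  stage_log("bum", sprintf("lambda %.3f a %.3f", bum$lambda, bum$a), t0 = t0)

  # -- nested effects model --------------------------------------------------
  fit <- run_stage("nem", infer_best(R))
  regulators <- assign_regulators(fit, threshold = config$posterior_threshold)
  boot <- run_stage("nem", bootstrap_edges(R, B = config$bootstrap_B,
                                           seed = config$seed + 2L))
  jsonlite::write_json(
    list(best_edges = format_edges(fit$graph),
         best_reduction = format_edges(transitive_reduction(fit$graph)),
         log_score = fit$log_score,
         score_table = fit$score_table),
    file.path(out, "nem.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(dplyr::left_join(regulators, fit$attachment_posterior, by = "gene_id"),
                   file.path(out, "regulators.tsv"), progress = FALSE)
  jsonlite::write_json(list(B = boot$B, seed = boot$seed, edges = boot$edges),
                       file.path(out, "bootstrap.json"), auto_unbox = TRUE, digits = NA)
  manifest$stages$nem <- list(
    best_hierarchy = format_edges(transitive_reduction(fit$graph)),
    log_score = fit$log_score,
    n_assigned = sum(regulators$assignment != "unassigned"))
  stage_log("nem", format_edges(transitive_reduction(fit$graph)), t0 = t0)

  # -- patterns, overlap, dominance -----------------------------------------
  pat <- run_stage("patterns", count_patterns(results, config$fdr_cutoff))
  ov <- run_stage("patterns", overlap_and_concordance(effects))
  doms <- run_stage("patterns", dplyr::bind_rows(
    dominance(results, effects, "TGFB", "WNT"),
    dominance(results, effects, "LATS", "WNT"),
    dominance(results, effects, "TGFB", "LATS")))
  readr::write_tsv(pat, file.path(out, "pattern_counts.tsv"), progress = FALSE)
  jsonlite::write_json(list(venn = ov$venn, pairwise = ov$pairwise,
                            triple = ov$triple),
                       file.path(out, "overlap.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(doms, file.path(out, "dominance.tsv"), progress = FALSE)
  for (cls in 1:2) {
    readr::write_tsv(top_pattern_genes(results, cls, fdr_cutoff = config$fdr_cutoff),
                     file.path(out, sprintf("top_pattern%d.tsv", cls)), progress = FALSE)
  }
  manifest$stages$patterns <- list(n_patterns_observed = sum(pat$count > 0),
                                   n_genes = attr(pat, "n_total"))
  stage_log("patterns", sum(pat$count > 0), " patterns observed", t0 = t0)

  # -- enrichment ------------------------------------------------------------
  if (!is.null(config$paths$gene_sets)) {
    enr <- run_stage("enrichment", {
      sets <- read_gene_sets(config$paths$gene_sets)
      enrich_gene_sets(results, sets)
    })
    readr::write_tsv(enr, file.path(out, "enrichment.tsv"), progress = FALSE)
    manifest$stages$enrichment <- list(n_sets = dplyr::n_distinct(enr$set))
    stage_log("enrichment", dplyr::n_distinct(enr$set), " gene sets", t0 = t0)
  }

  manifest$outputs <- list.files(out)
  write_manifest()
  invisible(manifest)
}
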