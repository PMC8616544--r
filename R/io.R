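# Reading, validating and writing the two tabular inputs: the gene-by-sample
# count table and the sample sheet describing each library.

#' Read a count table
#'
#' Reads a TSV with a header row of sample identifiers and gene identifiers in
#' the first column. Counts must be non-negative integers. The returned tibble
#' has a `gene_id` column followed by one column per sample.
#'
#' @param path Path to a tab-separated count file.
#' @return A tibble: `gene_id` plus one integer column per sample.
#' @export
read_counts <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("count file needs a gene id column and at least one sample column")
  names(raw)[1] <- "gene_id"
  validate_counts_chr(raw, path)
  counts <- raw
  for (j in seq(2, ncol(counts))) counts[[j]] <- as.integer(counts[[j]])
  validate_counts(counts)
  counts
}

# Character-level validation so errors can name the offending line (header is
# line 1, so data row i sits on line i + 1).
validate_counts_chr <- function(raw, path) {
  if (anyDuplicated(names(raw)[-1])) {
    abort(paste0("duplicate sample ids in header of ", path))
  }
  dup <- which(duplicated(raw$gene_id))
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id '", raw$gene_id[dup[1]], "' at line ", dup[1] + 1))
  }
  for (j in seq(2, ncol(raw))) {
    v <- raw[[j]]
    bad <- which(is.na(v) | !grepl("^[0-9]+$", v))
    if (length(bad) > 0) {
      abort(paste0("non-integer or negative count '", v[bad[1]], "' at line ",
                   bad[1] + 1, ", column '", names(raw)[j], "'"))
    }
  }
  invisible(raw)
}

#' Validate a count tibble
#'
#' Checks the invariants of the count container: a `gene_id` first column with
#' unique ids, unique sample columns, and non-negative integer counts.
#'
#' @param counts A tibble as returned by [read_counts()].
#' @return The input, invisibly, or an error.
#' @export
validate_counts <- function(counts) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "gene_id")
  if (anyDuplicated(counts$gene_id)) abort("gene ids must be unique")
  if (anyDuplicated(names(counts)[-1])) abort("sample ids must be unique")
  vals <- as.matrix(counts[-1])
  if (anyNA(vals)) abort("counts contain missing values")
  if (any(vals < 0)) abort("counts contain negative entries")
  if (any(vals != round(vals))) abort("counts must be integers")
  invisible(counts)
}

#' @rdname read_counts
#' @param counts A count tibble.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `cell_line`, `combo`
#' and `replicate`. `combo` holds plus-separated treatment tokens (for
#' example `"TGFB+LATS"`); the empty string denotes the control condition.
#'
#' @param path Path to a tab-separated sample sheet.
#' @param counts Optional count tibble; if supplied, every `sample_id` must
#'   appear among its columns.
#' @return A tibble with the four columns, combos canonicalised.
#' @export
read_sample_table <- function(path, counts = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cell_line = readr::col_character(),
    combo = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  tbl$combo[is.na(tbl$combo)] <- ""
  validate_sample_table(tbl, counts)
}

#' @rdname read_sample_table
#' @param samples A sample tibble.
#' @export
validate_sample_table <- function(samples, counts = NULL) {
  need <- c("sample_id", "cell_line", "combo", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) abort(paste0("sample table lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(samples$sample_id)) abort("sample ids must be unique")
  if (any(samples$replicate < 1)) abort("replicate must be a positive integer")
  samples$combo <- canonical_combo(samples$combo)
  if (!is.null(counts)) {
    missing_samples <- setdiff(samples$sample_id, names(counts)[-1])
    if (length(missing_samples) > 0) {
      abort(paste0("sample id(s) absent from count table: ",
                   paste(missing_samples, collapse = ", ")))
    }
  }
  as_tibble(samples)
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Build the treatment design matrix
#'
#' One row per sample and nine coefficient columns: an intercept, a cell-line
#' indicator (1 for the second cell line, reference level = lexicographically
#' first label), and one indicator per non-empty treatment combination, in the
#' fixed order of [treatment_combos()]. A control sample of the reference cell
#' line is the row (1, 0, ..., 0). The per-combination coefficients therefore
#' estimate each treatment combination's differential expression against
#' control, accounting for the cell-line effect.
#'
#' @param samples A sample tibble (see [read_sample_table()]).
#' @return A numeric matrix, samples x 9, with row names `sample_id`.
#' @export
build_design <- function(samples) {
  samples <- validate_sample_table(samples)
  lines <- sort(unique(samples$cell_line))
  if (length(lines) > 2) abort("at most two cell lines are supported")
  combos <- treatment_combos()
  x <- matrix(0, nrow = nrow(samples), ncol = 2 + length(combos),
              dimnames = list(samples$sample_id,
                              c("intercept", "cell_line", combos)))
  x[, "intercept"] <- 1
  x[, "cell_line"] <- as.numeric(samples$cell_line == lines[length(lines)] &
                                   length(lines) == 2)
  for (i in seq_len(nrow(samples))) {
    cb <- samples$combo[i]
    if (cb != "") x[i, cb] <- 1
  }
  x
}
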