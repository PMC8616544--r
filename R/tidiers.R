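# broom-style tidiers for the package's fitted objects.

#' Tidy a beta-uniform mixture fit
#'
#' @param x A `bum_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.bum_fit <- function(x, ...) {
  tibble(term = c("lambda", "a"), estimate = c(x$lambda, x$a))
}

#' @rdname tidy.bum_fit
#' @return For `glance()`: a one-row tibble (`lambda`, `a`, `loglik`, `n`).
#' @export
glance.bum_fit <- function(x, ...) {
  tibble(lambda = x$lambda, a = x$a, loglik = x$loglik, n = x$n)
}

#' Tidy a nested effects model fit
#'
#' One row per directed edge of the winning hierarchy, flagged by whether
#' the edge survives the transitive reduction (the display form) or is
#' implied by closure.
#'
#' @param x A `nem_fit`.
#' @param ... Unused.
#' @return A tibble: `from`, `to`, `in_reduction`.
#' @export
tidy.nem_fit <- function(x, ...) {
  g <- x$graph
  red <- transitive_reduction(g)
  e <- which(g & !diag(nrow(g)), arr.ind = TRUE)
  tibble(from = rownames(g)[e[, 1]], to = colnames(g)[e[, 2]],
         in_reduction = red[e])
}

#' @rdname tidy.nem_fit
#' @return For `glance()`: a one-row tibble (`log_score`, `n_genes`,
#'   `n_graphs`, `edges`).
#' @export
glance.nem_fit <- function(x, ...) {
  tibble(log_score = x$log_score, n_genes = x$n_genes,
         n_graphs = nrow(x$score_table),
         edges = format_edges(transitive_reduction(x$graph)))
}

#' Tidy bootstrap edge support
#'
#' @param x A `bootstrap_support`.
#' @param ... Unused.
#' @return The per-edge support tibble with `B` appended as a column.
#' @export
tidy.bootstrap_support <- function(x, ...) {
  dplyr::mutate(x$edges, B = x$B)
}
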