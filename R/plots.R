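# ggplot2 visualisations of the main result types.

#' Plot an enrichment curve
#'
#' Draws f(i) against the member index i; flat curves near zero indicate an
#' evenly spread (unenriched) gene set.
#'
#' @param object An `enrichment_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$i, y = .data$f)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "gene-set member (rank order)", y = "f(i)",
                  title = object$name,
                  subtitle = sprintf("m = %d of n = %d genes", object$m, object$n)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the inferred hierarchy
#'
#' Shows the transitive reduction of the winning graph as arrows between the
#' three perturbations, optionally annotated with bootstrap support.
#'
#' @param object A `nem_fit`.
#' @param bootstrap Optional `bootstrap_support` for edge labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nem_fit <- function(object, bootstrap = NULL, ...) {
  s <- rownames(object$graph)
  layout <- tibble(node = s, x = c(1, 2, 3)[seq_along(s)], y = 0)
  red <- transitive_reduction(object$graph)
  e <- which(red, arr.ind = TRUE)
  edges <- tibble(
    from = s[e[, 1]], to = s[e[, 2]],
    x = layout$x[e[, 1]], xend = layout$x[e[, 2]]
  )
  if (!is.null(bootstrap)) {
    lab <- tidy.bootstrap_support(bootstrap)
    edges <- dplyr::left_join(edges, lab, by = c("from", "to"))
    edges$label <- sprintf("%d/%d", edges$support_reduction, edges$B)
  } else {
    edges$label <- ""
  }
  ggplot2::ggplot() +
    ggplot2::geom_curve(
      data = edges,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0),
      curvature = -0.25,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in"), type = "closed")
    ) +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(x = .data$x, y = 0, label = .data$node)) +
    ggplot2::geom_text(data = edges,
                       ggplot2::aes(x = (.data$x + .data$xend) / 2, y = 0.12,
                                    label = .data$label)) +
    ggplot2::ylim(-0.3, 0.4) +
    ggplot2::theme_void()
}

#' Bar plot of the most frequent sign patterns
#'
#' @param pattern_counts The tibble from [count_patterns()].
#' @param top_n How many patterns to show.
#' @return A ggplot object.
#' @export
plot_pattern_counts <- function(pattern_counts, top_n = 10) {
  d <- head(dplyr::arrange(pattern_counts, .data$rank), top_n)
  d$pattern <- factor(d$pattern, levels = rev(d$pattern))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "genes", y = "sign pattern (7 contrasts)") +
    ggplot2::theme_minimal()
}
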