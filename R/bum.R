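# Beta-uniform mixture model of a p-value distribution. Null p-values are
# uniform on (0,1]; signal p-values concentrate near zero and are modelled by
# a Beta(a, 1) component with shape a in (0, 1], whose density a*p^(a-1) is
# nonincreasing. The mixture density is
#
#   f(p) = lambda + (1 - lambda) * a * p^(a - 1),
#
# and the log density of the beta component, evaluated at each raw p-value,
# is the per-gene, per-contrast evidence score fed to the nested effects
# model: since the uniform density is 1, log(a * p^(a-1)) is the log
# likelihood ratio of "effect" against "no effect".

#' Mixture density of the beta-uniform model
#'
#' @param p P-values in `[0, 1]`.
#' @param lambda Weight of the uniform component, in `[0, 1]`.
#' @param a Beta shape parameter, in `(0, 1]`.
#' @param component `"mixture"`, `"beta"` or `"uniform"`.
#' @return Density values.
#' @export
dbum <- function(p, lambda, a, component = c("mixture", "beta", "uniform")) {
  component <- match.arg(component)
  switch(component,
         mixture = lambda + (1 - lambda) * a * p^(a - 1),
         beta = a * p^(a - 1),
         uniform = rep(1, length(p)))
}

#' Draw p-values from a beta-uniform mixture
#'
#' With probability `lambda` a draw is Uniform(0, 1), otherwise Beta(`a`, 1)
#' (inverse-CDF: `u^(1/a)`).
#'
#' @inheritParams dbum
#' @param n Number of draws.
#' @return Numeric vector of simulated p-values.
#' @export
rbum <- function(n, lambda, a) {
  null <- runif(n) < lambda
  p <- runif(n)
  p[!null] <- p[!null]^(1 / a)
  p
}

#' Fit the beta-uniform mixture by maximum likelihood
#'
#' Bounded optimization (L-BFGS-B from a small deterministic grid of starts)
#' of the mixture log-likelihood in (lambda, a). P-values are clamped to
#' `[eps, 1]` before evaluation because `p^(a-1)` diverges at zero.
#'
#' @param p_raw Raw p-values (>= 100 recommended for a stable fit).
#' @param eps Lower clamp for p-values.
#' @return An object of class `bum_fit`: `lambda`, `a`, `loglik`, `n`, `eps`.
#' @export
fit_bum <- function(p_raw, eps = 1e-10) {
  if (anyNA(p_raw)) abort("p-values contain NA")
  p <- pmin(pmax(p_raw, eps), 1)
  nll <- function(par) -sum(log(dbum(p, par[1], par[2])))
  lower <- c(1e-6, 1e-6)
  upper <- c(1 - 1e-6, 1)
  starts <- expand.grid(lambda = c(0.25, 0.5, 0.75), a = c(0.1, 0.5, 0.9))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("beta-uniform mixture optimization failed from every start")
  structure(
    list(lambda = best$par[1], a = best$par[2], loglik = -best$value,
         n = length(p), eps = eps),
    class = "bum_fit"
  )
}

#' Log-density evidence matrix for the nested effects model
#'
#' Evaluates, at every gene x contrast raw p-value, the log density of the
#' fitted beta component (default) or of the full mixture. Positive values
#' mark p-values small enough to be evidence for an effect; at p = 1 the
#' beta log density is `log(a) < 0` for `a < 1`, evidence against.
#'
#' @param results A `contrast_results` tibble.
#' @param fit A `bum_fit`.
#' @param component `"beta"` (default, the evidence score used for NEM
#'   inference) or `"mixture"`.
#' @return A wide tibble: `gene_id` plus one log-density column per contrast.
#' @export
log_density <- function(results, fit, component = c("beta", "mixture")) {
  component <- match.arg(component)
  stopifnot(inherits(fit, "bum_fit"))
  p <- pmin(pmax(results$p_raw, fit$eps), 1)
  r <- if (component == "beta") {
    log(fit$a) + (fit$a - 1) * log(p)
  } else {
    log(dbum(p, fit$lambda, fit$a))
  }
  out <- tibble(gene_id = results$gene_id, contrast = results$contrast, R = r)
  out <- tidyr::pivot_wider(out, names_from = "contrast", values_from = "R")
  out[, c("gene_id", intersect(treatment_combos(), names(out)))]
}

#' @export
print.bum_fit <- function(x, ...) {
  cat("Beta-uniform mixture fit\n")
  cat(sprintf("  lambda = %.4f  a = %.4f  loglik = %.2f  (n = %d)\n",
              x$lambda, x$a, x$loglik, x$n))
  invisible(x)
}
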