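# Treatment-combination vocabulary shared across the package.
#
# The three perturbations are TGFB (TGF-beta treatment), LATS (siLATS1/2
# knockdown, i.e. YAP/TAZ activation) and WNT (Wnt-3a treatment). A condition
# is a subset of the three; the empty subset is the control. Combinations are
# encoded as plus-separated tokens in a fixed canonical order so that design
# columns, contrasts and pattern strings index identically everywhere.

#' Treatment and condition vocabulary
#'
#' `treatments()` returns the three perturbation labels in canonical order.
#' `treatment_combos()` returns the seven non-empty treatment combinations in
#' the fixed column order used by the design matrix, the contrast results and
#' the sign-pattern census: the three singles, the three doubles, then the
#' triple. `conditions()` prepends the control (encoded as the empty string).
#'
#' @return A character vector of labels.
#' @export
#' @examples
#' treatments()
#' treatment_combos()
treatments <- function() c("TGFB", "LATS", "WNT")

#' @rdname treatments
#' @export
treatment_combos <- function() {
  c("TGFB", "LATS", "WNT",
    "TGFB+LATS", "TGFB+WNT", "LATS+WNT",
    "TGFB+LATS+WNT")
}

#' @rdname treatments
#' @export
conditions <- function() c("", treatment_combos())

#' Canonicalise a treatment-combination label
#'
#' Splits plus-separated tokens, validates them against [treatments()], and
#' re-joins them in canonical order. The empty string (control) is passed
#' through unchanged.
#'
#' @param combo Character vector of combination labels.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' canonical_combo("WNT+TGFB")  # "TGFB+WNT"
canonical_combo <- function(combo) {
  vapply(combo, function(x) {
    if (is.na(x) || x == "") return("")
    toks <- strsplit(x, "+", fixed = TRUE)[[1]]
    toks <- toks[toks != ""]
    bad <- setdiff(toks, treatments())
    if (length(bad) > 0) {
      abort(paste0("unknown treatment token(s): ", paste(bad, collapse = ", "),
                   " in combo '", x, "'"))
    }
    if (anyDuplicated(toks)) {
      abort(paste0("duplicated treatment token in combo '", x, "'"))
    }
    paste(treatments()[treatments() %in% toks], collapse = "+")
  }, character(1), USE.NAMES = FALSE)
}

# Split a canonical combo into its member treatments ("" -> character(0)).
combo_members <- function(combo) {
  if (combo == "") return(character(0))
  strsplit(combo, "+", fixed = TRUE)[[1]]
}

# Numerically stable log(sum(exp(x))) over rows of a matrix.
row_logsumexp <- function(x) {
  m <- apply(x, 1, max)
  m + log(rowSums(exp(x - m)))
}
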