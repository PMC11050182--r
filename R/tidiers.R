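#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment result
#'
#' Returns the per-term table as a plain tibble (one row per tested
#' term).
#'
#' @param x A `g4_enrichment` object from [hypergeom_enrichment()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.g4_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "g4_enrichment")
  as_tibble(out)
}

#' One-row summary of an enrichment result
#'
#' @param x A `g4_enrichment` object.
#' @param alpha Adjusted-p significance cutoff used for `n_significant`.
#' @param ... Unused.
#' @return A one-row tibble: `n_terms`, `n_significant`, `min_p_adj`,
#'   `n_selected`, `n_universe`.
#' @export
glance.g4_enrichment <- function(x, alpha = 0.05, ...) {
  tibble(
    n_terms = nrow(x),
    n_significant = sum(x$p_adj <= alpha),
    min_p_adj = if (nrow(x)) min(x$p_adj) else NA_real_,
    n_selected = if (nrow(x)) x$n[1] else NA_integer_,
    n_universe = if (nrow(x)) x$N[1] else NA_integer_
  )
}
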