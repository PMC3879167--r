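#' Hypergeometric term enrichment of a hit list
#'
#' Tests each annotation term for over-representation among hits with the
#' hypergeometric upper tail: with `N` genes in the universe, `K` annotated
#' with the term, `n` hits and `k` annotated hits,
#' `p = P(X >= k), X ~ Hypergeometric(N, K, n)`. P-values are adjusted across
#' tested terms by Benjamini-Hochberg. Terms annotating fewer than `k_min`
#' universe genes are skipped. The term vocabulary (GO, KEGG, or any gene-set
#' table) is supplied by the user as a two-column gene-to-term map.
#'
#' @param hits Character vector of hit gene identifiers (must be a subset of
#'   `universe`).
#' @param universe Character vector defining the sampling frame; for a screen,
#'   all mutants quantified.
#' @param annotation Data frame with columns `gene`, `term` (one row per
#'   gene-term link); genes outside the universe are ignored.
#' @param k_min Minimum universe genes per term for the term to be tested
#'   (default 3).
#' @return Tibble `term, N, K, n, k, p, q`, ordered by `p`.
#' @export
enrich_terms <- function(hits, universe, annotation, k_min = 3L) {
  universe <- unique(universe)
  hits <- unique(hits)
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    abort(sprintf("hits not in universe: %s",
                  paste(utils::head(outside, 10), collapse = ", ")))
  }
  ann <- annotation |>
    dplyr::rename(gene = 1, term = 2) |>
    dplyr::filter(.data$gene %in% universe) |>
    dplyr::distinct(.data$gene, .data$term)
  N <- length(universe); n <- length(hits)
  res <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(K = dplyr::n(), k = sum(.data$gene %in% hits)) |>
    dplyr::filter(.data$K >= k_min) |>
    dplyr::mutate(N = N, n = n,
                  p = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                                    lower.tail = FALSE))
  res |>
    dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::select("term", "N", "K", "n", "k", "p", "q") |>
    dplyr::arrange(.data$p, .data$term)
}
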