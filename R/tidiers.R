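#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-condition comparison into its membership classes
#'
#' @param x A `screen_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return Tibble `conditions, n_conditions, size` over all `2^k - 1`
#'   membership classes.
#' @export
tidy.screen_comparison <- function(x, ...) x$classes

#' One-row summary of a cross-condition comparison
#'
#' @param x A `screen_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return One-row tibble: `n_conditions`, `min_hits`, `max_hits`,
#'   `union_size`, `condition_specific_fraction`.
#' @export
glance.screen_comparison <- function(x, ...) {
  tibble(n_conditions = nrow(x$per_condition),
         min_hits = min(x$per_condition$n_hits),
         max_hits = max(x$per_condition$n_hits),
         union_size = x$union_size,
         condition_specific_fraction = x$condition_specific_fraction)
}
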