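#' Simulate double-mutant colony sizes for growth-score analysis
#'
#' Generative model for a genetic-interaction screen:
#' `size(gene, rep) = base_size * gene_fitness * interaction *
#' exp(plate_effect[rep]) * exp(noise)`, with the plate effect shared by all
#' genes on a replicate plate and i.i.d. log-normal colony noise. The returned
#' truth stores each gene's planted interaction multiplier, so growth-score
#' recovery can be checked exactly.
#'
#' @param spec A [gi_sim_spec()].
#' @param gene_list Non-empty character vector of gene names.
#' @return A list with `sizes` (tibble `gene, replicate, plate, size`) and
#'   `truth` (tibble `gene, gene_fitness, interaction`).
#' @export
simulate_colony_sizes <- function(spec, gene_list) {
  if (!length(gene_list)) abort("`gene_list` must be non-empty")
  if (spec$base_size <= 0) abort("`base_size` must be positive")
  fit <- rep(1, length(gene_list)); names(fit) <- gene_list
  fit[names(spec$gene_fitness)[names(spec$gene_fitness) %in% gene_list]] <-
    spec$gene_fitness[names(spec$gene_fitness) %in% gene_list]
  int <- rep(1, length(gene_list)); names(int) <- gene_list
  int[names(spec$interaction)[names(spec$interaction) %in% gene_list]] <-
    spec$interaction[names(spec$interaction) %in% gene_list]

  n <- length(gene_list); reps <- spec$replicates
  withr::with_seed(derive_seed(spec$seed, "gi-sizes"), {
    plate_eff <- stats::rnorm(reps, 0, spec$plate_effect_sd)
    noise <- matrix(stats::rnorm(n * reps, 0, spec$noise_sd), n, reps)
  })
  sizes <- tidyr::expand_grid(gene = gene_list, replicate = seq_len(reps)) |>
    dplyr::mutate(
      plate = sprintf("gp%02d", .data$replicate),
      size = spec$base_size * fit[.data$gene] * int[.data$gene] *
        exp(plate_eff[.data$replicate]) *
        exp(noise[cbind(match(.data$gene, gene_list), .data$replicate)])
    )
  list(sizes = sizes,
       truth = tibble(gene = gene_list, gene_fitness = unname(fit),
                      interaction = unname(int)))
}
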