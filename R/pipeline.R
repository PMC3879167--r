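#' Run the full screen pipeline on a simulated library
#'
#' End-to-end driver: arrays a mutant library onto plates, plants CPRG
#' classes, renders every plate at every timepoint, quantifies each image,
#' auto-selects the quantification timepoint, flags neighbour contamination,
#' averages clones, calls hits, and compares conditions. When `out_dir` is
#' given, all documented TSV outputs are written (per-condition scores, hit
#' lists, membership classes) alongside the images.
#'
#' @param n_mutants Library size (default 384).
#' @param conditions Condition labels (default [cprg_conditions()]).
#' @param timepoints Imaging times in hours (default `c(12, 23)`).
#' @param spec A [plate_spec()]; its seed drives all randomness.
#' @param cprg_fraction,effect_size_range Planting parameters for
#'   [make_screen_truth()].
#' @param threshold Hit threshold; `NULL` (default) calibrates it from the
#'   score distribution with [calibrate_threshold()].
#' @param out_dir Optional output directory.
#' @return A list: `layout`, `truth`, `timepoint` (selected), `threshold`,
#'   `measurements` (at the selected timepoint, contamination-flagged),
#'   `measurements_all` (all timepoints), `scores`, `hits`, `comparison`.
#' @export
run_screen_pipeline <- function(n_mutants = 384L,
                                conditions = cprg_conditions(),
                                timepoints = c(12, 23),
                                spec = plate_spec(),
                                cprg_fraction = 0.02,
                                effect_size_range = c(0.04, 0.12),
                                threshold = NULL,
                                out_dir = NULL) {
  mutants <- sprintf("mut%04d", seq_len(n_mutants))
  layout <- make_screen_layout(mutants, rows = spec$rows, cols = spec$cols)
  truth <- make_screen_truth(mutants, conditions, cprg_fraction = cprg_fraction,
                             effect_size_range = effect_size_range,
                             seed = spec$seed)
  sim <- simulate_screen(layout, truth, timepoints, spec, out_dir = out_dir)

  measurements_all <- purrr::pmap_dfr(sim, function(condition, plate, timepoint,
                                                    render, truth, path) {
    img <- plate_image(render$image, plate_id = plate, condition = condition,
                       timepoint = timepoint)
    quantify_plate(img, layout = layout[layout$plate == plate, ])
  })
  tp <- select_timepoint(measurements_all)
  m_early <- measurements_all[measurements_all$timepoint == tp, ]

  if (is.null(threshold)) threshold <- calibrate_threshold(m_early$cprg_score)
  m_early <- m_early |>
    dplyr::group_by(.data$plate, .data$condition) |>
    dplyr::group_modify(~ flag_neighbor_contamination(.x, threshold)) |>
    dplyr::ungroup()

  scores <- average_replicates(m_early)
  hits <- call_hits(scores, threshold)
  comparison <- compare_conditions(hits)

  if (!is.null(out_dir)) {
    for (cond in conditions) {
      utils::write.table(
        as.data.frame(scores[scores$condition == cond, ]),
        file.path(out_dir, sprintf("scores_%s.tsv", gsub("[^A-Za-z0-9]+", "_", cond))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(as.data.frame(hits[hits$is_hit, ]),
                       file.path(out_dir, "hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(comparison$classes),
                       file.path(out_dir, "membership_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(layout = layout, truth = truth, timepoint = tp, threshold = threshold,
       measurements = m_early, measurements_all = measurements_all,
       scores = scores, hits = hits, comparison = comparison)
}
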