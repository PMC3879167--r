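#' @import ggplot2
NULL

#' Display a rendered or photographed plate
#'
#' @param object A `plate_render` or [plate_image()].
#' @param ... Unused.
#' @return A ggplot raster of the plate photograph.
#' @export
autoplot.plate_render <- function(object, ...) {
  px <- object$image %||% object$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  ras <- grDevices::as.raster(px)
  ggplot() +
    annotation_raster(ras, xmin = 0.5, xmax = w + 0.5, ymin = -(h + 0.5), ymax = -0.5) +
    coord_fixed(xlim = c(0.5, w + 0.5), ylim = c(-(h + 0.5), -0.5), expand = FALSE) +
    theme_void()
}

#' @rdname autoplot.plate_render
#' @export
autoplot.plate_image <- autoplot.plate_render

#' CPRG score distribution on a log axis, with the hit cut-off
#'
#' The standard screen diagnostic: a histogram of `log10(1 + score)` per
#' condition with the hit threshold drawn as a dashed line. In a specific
#' assay only a small proportion of mutants fall right of the line.
#'
#' @param scores Score matrix from [average_replicates()] (or any tibble with
#'   `score` and optionally `condition`).
#' @param threshold Optional threshold to draw.
#' @param bins Histogram bins (default 60).
#' @return A ggplot.
#' @export
plot_score_distribution <- function(scores, threshold = NULL, bins = 60) {
  p <- ggplot(scores, aes(x = log10(1 + .data$score))) +
    geom_histogram(bins = bins, fill = "grey35") +
    labs(x = expression(log[10](1 + "CPRG score")), y = "mutants")
  if ("condition" %in% names(scores) && dplyr::n_distinct(scores$condition) > 1) {
    p <- p + facet_wrap(~condition)
  }
  if (!is.null(threshold)) {
    p <- p + geom_vline(xintercept = log10(1 + threshold),
                        linetype = "dashed", colour = "red3")
  }
  p
}

#' Growth-score ranking plot for a genetic-interaction screen
#'
#' @param gi Result of [score_gi_screen()].
#' @param epsilon Neutral band drawn around 1 (default 0.2).
#' @return A ggplot of ranked growth scores coloured by interaction class.
#' @export
plot_gi_scores <- function(gi, epsilon = 0.2) {
  gi <- dplyr::mutate(gi, rank = dplyr::row_number(dplyr::desc(.data$growth_score)))
  ggplot(gi, aes(x = .data$rank, y = .data$growth_score, colour = .data$class)) +
    geom_hline(yintercept = 1, colour = "grey50") +
    geom_hline(yintercept = c(1 - epsilon, 1 + epsilon),
               linetype = "dotted", colour = "grey50") +
    geom_point(size = 0.8) +
    labs(x = "gene rank", y = "growth score", colour = "interaction")
}
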