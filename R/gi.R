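#' Growth score of a double mutant
#'
#' The growth score is the mean colony size of the double-mutant clone's
#' replicates divided by the average colony size of library clones on the
#' same plate set. Dead replicates (size 0) are excluded from the numerator;
#' a gene whose replicates are all dead scores 0 (a lethal candidate).
#'
#' @param sizes Replicate colony sizes for the gene (numeric, >= 0).
#' @param library_sizes Colony sizes of the reference library clones; must
#'   contain grown (> 0) colonies.
#' @return The growth score `g >= 0`.
#' @export
growth_score <- function(sizes, library_sizes) {
  lib <- library_sizes[library_sizes > 0]
  if (!length(lib) || mean(lib) <= 0) abort("library size set has no grown colonies")
  grown <- sizes[sizes > 0]
  if (!length(grown)) return(0)
  mean(grown) / mean(lib)
}

#' Classify a genetic interaction from its growth score
#'
#' Scores greater than one indicate suppressive interactions and scores less
#' than one negative interactions. A neutral band of half-width `epsilon`
#' around 1 absorbs measurement noise: suppressive when `g > 1 + epsilon`,
#' negative when `g < 1 - epsilon`, neutral otherwise. `epsilon = 0`
#' reproduces the strict greater-than/less-than rule (with `g = 1` exactly
#' classed neutral).
#'
#' @param g Growth score(s), >= 0.
#' @param epsilon Neutral band half-width (default 0.2).
#' @return Character vector in `{"suppressive", "neutral", "negative"}`.
#' @export
classify_interaction <- function(g, epsilon = 0.2) {
  if (any(g < 0)) abort("`g` must be >= 0")
  if (epsilon < 0) abort("`epsilon` must be >= 0")
  dplyr::case_when(g > 1 + epsilon ~ "suppressive",
                   g < 1 - epsilon ~ "negative",
                   TRUE ~ "neutral")
}

#' Score a genetic-interaction screen from a colony-size table
#'
#' Computes growth scores and interaction classes for every gene in a
#' double-mutant colony-size table. The default reference is the library
#' mean: the average size of all grown library clones (optionally excluding
#' border rows/columns, which overgrow in pinned arrays). With
#' `reference = "matched-single"` each gene is instead referenced to the mean
#' size of its matched single mutant supplied in `singles`. Per-plate
#' normalisation divides every size by its plate's library mean before
#' pooling, removing shared plate effects.
#'
#' @param sizes Tibble with columns `gene, replicate, plate, size` (e.g. from
#'   [simulate_colony_sizes()], a TSV, or [quantify_plate()]'s `size_score`).
#' @param layout Optional `plate_layout`; when given, every gene must appear
#'   in it and border positions can be excluded from the reference.
#' @param per_plate_norm Normalise sizes by the per-plate library mean before
#'   pooling (default FALSE).
#' @param epsilon Neutral band for [classify_interaction()] (default 0.2).
#' @param reference `"library-mean"` (default) or `"matched-single"`.
#' @param singles For `reference = "matched-single"`: tibble `gene, size` of
#'   single-mutant reference sizes.
#' @param exclude_border With a layout, drop border rows/columns from the
#'   library reference (default FALSE).
#' @return Tibble `gene, n_replicates, mean_size, library_mean, growth_score,
#'   class, flag`, sorted by descending score. Flags: `dead_replicates`
#'   (some replicates dead), `lethal-candidate` (all dead).
#' @export
score_gi_screen <- function(sizes, layout = NULL, per_plate_norm = FALSE,
                            epsilon = 0.2,
                            reference = c("library-mean", "matched-single"),
                            singles = NULL, exclude_border = FALSE) {
  reference <- match.arg(reference)
  if (any(sizes$size < 0)) abort("colony sizes must be >= 0")
  if (!is.null(layout)) {
    absent <- setdiff(unique(sizes$gene), layout$mutant_id)
    if (length(absent)) {
      abort(sprintf("genes absent from layout: %s",
                    paste(utils::head(absent, 10), collapse = ", ")))
    }
  }
  df <- as_tibble(sizes)
  in_reference <- rep(TRUE, nrow(df))
  if (exclude_border && !is.null(layout)) {
    rows <- attr(layout, "rows"); cols <- attr(layout, "cols")
    border_genes <- layout$mutant_id[layout$row %in% c(0L, rows - 1L) |
                                       layout$col %in% c(0L, cols - 1L)]
    in_reference <- !(df$gene %in% border_genes)
  }
  df$.in_ref <- in_reference
  if (per_plate_norm) {
    df <- df |>
      dplyr::group_by(.data$plate) |>
      dplyr::mutate(size = .data$size / mean(.data$size[.data$size > 0 & .data$.in_ref])) |>
      dplyr::ungroup()
  }
  lib_mean <- switch(reference,
    "library-mean" = mean(df$size[df$size > 0 & df$.in_ref]),
    "matched-single" = NULL
  )
  if (reference == "matched-single") {
    if (is.null(singles)) abort("`singles` is required with reference = \"matched-single\"")
    ref_tbl <- singles |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(ref_size = mean(.data$size[.data$size > 0]))
  }
  out <- df |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_grown = sum(.data$size > 0),
      mean_size = if (sum(.data$size > 0)) mean(.data$size[.data$size > 0]) else 0,
      .groups = "drop"
    )
  if (reference == "matched-single") {
    out <- dplyr::left_join(out, ref_tbl, by = "gene")
    if (any(is.na(out$ref_size))) {
      abort(sprintf("no single-mutant reference for: %s",
                    paste(utils::head(out$gene[is.na(out$ref_size)], 10), collapse = ", ")))
    }
    out$library_mean <- out$ref_size
  } else {
    out$library_mean <- lib_mean
  }
  out |>
    dplyr::mutate(
      growth_score = ifelse(.data$n_grown == 0, 0, .data$mean_size / .data$library_mean),
      class = ifelse(.data$n_grown == 0, "negative",
                     classify_interaction(.data$growth_score, epsilon)),
      flag = dplyr::case_when(
        n_grown == 0 ~ "lethal-candidate",
        n_grown < n_replicates ~ "dead_replicates",
        TRUE ~ ""
      )
    ) |>
    dplyr::select("gene", "n_replicates", "mean_size", "library_mean",
                  "growth_score", "class", "flag") |>
    dplyr::arrange(dplyr::desc(.data$growth_score))
}
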