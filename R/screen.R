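#' Select the quantification timepoint for a plate series
#'
#' Chooses the earliest imaging timepoint at which at least a fraction `phi`
#' of the expected colonies are segmented with area at least `min_area` --
#' i.e. the earliest time the array has grown in. Because the red hydrolysis
#' product keeps diffusing, later images have wider halos that can reach
#' neighbouring positions, so quantifying the earliest adequately grown image
#' avoids neighbours of red colonies being scored as hits; later timepoints
#' are retained for QC only.
#'
#' @param measurements Measurement tibble covering one or more timepoints
#'   (column `timepoint`), e.g. row-bound [quantify_plate()] outputs.
#' @param phi Required grown fraction (default 0.9).
#' @param min_area Minimum colony area in pixels (default 10).
#' @return The chosen timepoint (scalar). Falls back to the last timepoint
#'   with a warning when none satisfies the growth criterion.
#' @export
select_timepoint <- function(measurements, phi = 0.9, min_area = 10) {
  tps <- sort(unique(measurements$timepoint))
  if (!length(tps)) abort("no timepoints in `measurements`")
  grown <- vapply(tps, function(tt) {
    m <- measurements[measurements$timepoint == tt, ]
    mean(m$mask_area >= min_area)
  }, numeric(1))
  ok <- which(grown >= phi)
  if (!length(ok)) {
    warn(sprintf("no timepoint reaches grown fraction %.2f (best %.2f); using the last",
                 phi, max(grown)))
    return(tps[length(tps)])
  }
  tps[min(ok)]
}

#' Average clone scores into a mutant-by-condition score matrix
#'
#' The score of a mutant in a condition is the arithmetic mean of the CPRG
#' scores of its replicate clones (2 in a standard ordered library). Mutants
#' with a single available clone are averaged over that clone and flagged;
#' mutants with no clone get a missing score. Measurement flags (including
#' `neighbor_contaminated`) are propagated as the union over clones.
#'
#' @param measurements Measurement tibble at the selected timepoint, with
#'   `mutant_id`, `condition`, `cprg_score`, `flags` (e.g. row-bound
#'   [quantify_plate()] outputs across plates/conditions).
#' @param replicate_index Optional index from [map_replicates()]; when given,
#'   mutants missing from a condition appear with `n_clones = 0`.
#' @return A long score matrix: tibble `mutant_id, condition, score,
#'   n_clones, flags`.
#' @export
average_replicates <- function(measurements, replicate_index = NULL) {
  m <- measurements |>
    dplyr::filter(!grepl("empty", .data$flags)) |>
    dplyr::group_by(.data$mutant_id, .data$condition) |>
    dplyr::summarise(
      score = mean(.data$cprg_score),
      n_clones = dplyr::n(),
      flags = paste(unique(unlist(strsplit(.data$flags[.data$flags != ""], ","))),
                    collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(flags = ifelse(.data$n_clones == 1L,
                                 sub("^,", "", paste(.data$flags, "single_clone_pos", sep = ",")),
                                 .data$flags))
  if (!is.null(replicate_index)) {
    frame <- dplyr::distinct(replicate_index, .data$mutant_id, .data$condition)
    m <- dplyr::left_join(frame, m, by = c("mutant_id", "condition")) |>
      dplyr::mutate(n_clones = dplyr::coalesce(.data$n_clones, 0L),
                    flags = dplyr::coalesce(.data$flags, "missing"))
  }
  dplyr::arrange(m, .data$condition, .data$mutant_id)
}

#' Calibrate a hit threshold from a score distribution
#'
#' Robust data-driven cut-off for screens in arbitrary score units: over the
#' central 90% quantile mass of `log(1 + S)`, the threshold is
#' `expm1(mean + z * sd)`. With the default `z = 6` only the far right tail
#' of the bulk distribution exceeds the cut-off, matching the expectation
#' that only a small proportion of mutants score positively. A published
#' instrument-specific cut-off (e.g. `10^3.7` units) can be supplied directly
#' to [call_hits()] instead.
#'
#' @param scores Numeric scores (e.g. the `score` column of
#'   [average_replicates()]).
#' @param z Tail multiplier (default 6).
#' @return Threshold on the raw score scale.
#' @export
calibrate_threshold <- function(scores, z = 6) {
  s <- scores[is.finite(scores)]
  ls <- log1p(s)
  qs <- stats::quantile(ls, c(0.05, 0.95), names = FALSE)
  core <- ls[ls >= qs[1] & ls <= qs[2]]
  expm1(mean(core) + z * stats::sd(core))
}

#' Call CPRG+ hits by score threshold
#'
#' A mutant is a hit in a condition when its replicate-averaged score is
#' strictly above the threshold (scores exactly at the cut-off are not hits).
#' Rows flagged `neighbor_contaminated` or with no score are excluded before
#' calling.
#'
#' @param scores Long score matrix from [average_replicates()] (or any tibble
#'   with `mutant_id, condition, score`).
#' @param threshold Positive score threshold; the published cut-off of the
#'   reference screen is `10^3.7` units.
#' @return Tibble `mutant_id, condition, score, threshold, is_hit`.
#' @export
call_hits <- function(scores, threshold) {
  if (!is.numeric(threshold) || threshold <= 0) abort("`threshold` must be > 0")
  flags <- if ("flags" %in% names(scores)) scores$flags else ""
  keep <- !grepl("neighbor_contaminated", flags) & !is.na(scores$score)
  scores[keep, intersect(c("mutant_id", "condition", "score"), names(scores))] |>
    dplyr::mutate(threshold = threshold, is_hit = .data$score > threshold)
}

#' Compare hit lists across screen conditions
#'
#' Enumerates all `2^k - 1` condition-membership classes of the union of hits
#' (the set-size breakdown a Venn diagram displays) and the
#' condition-specific fraction: the share of union hits positive in exactly
#' one condition.
#'
#' @param hits Hit calls from [call_hits()] over >= 2 conditions.
#' @return An object of class `screen_comparison`: list with
#'   `per_condition` (hit counts), `classes` (tibble `conditions, n_conditions,
#'   size` over all membership classes), `union_size` and
#'   `condition_specific_fraction`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
compare_conditions <- function(hits) {
  conditions <- sort(unique(hits$condition))
  if (length(conditions) < 2L) abort("need >= 2 conditions to compare")
  hit_tbl <- hits[hits$is_hit, c("mutant_id", "condition")]
  membership <- hit_tbl |>
    dplyr::group_by(.data$mutant_id) |>
    dplyr::summarise(conditions = paste(sort(unique(.data$condition)), collapse = " & "),
                     n_conditions = dplyr::n_distinct(.data$condition))
  k <- length(conditions)
  all_classes <- purrr::map_dfr(seq_len(k), function(m) {
    combos <- utils::combn(conditions, m, simplify = FALSE)
    tibble(conditions = purrr::map_chr(combos, paste, collapse = " & "),
           n_conditions = m)
  })
  classes <- all_classes |>
    dplyr::left_join(dplyr::count(membership, .data$conditions, name = "size"),
                     by = "conditions") |>
    dplyr::mutate(size = dplyr::coalesce(.data$size, 0L))
  union_size <- nrow(membership)
  structure(list(
    per_condition = dplyr::count(hit_tbl, .data$condition, name = "n_hits"),
    classes = classes,
    union_size = union_size,
    condition_specific_fraction =
      if (union_size) sum(membership$n_conditions == 1) / union_size else NA_real_
  ), class = "screen_comparison")
}

#' @export
print.screen_comparison <- function(x, ...) {
  cat(sprintf("<screen_comparison> %d conditions, union %d hits, %.1f%% condition-specific\n",
              nrow(x$per_condition), x$union_size,
              100 * x$condition_specific_fraction))
  print(x$per_condition)
  invisible(x)
}
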