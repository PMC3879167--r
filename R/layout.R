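#' Default screen conditions
#'
#' The four growth conditions of the envelope-integrity screen: two incubation
#' temperatures (30 C and room temperature) crossed with LB agar at 0 and 1%
#' NaCl. Condition labels are free strings throughout the package; this set is
#' only a documented default.
#'
#' @return Character vector of four condition labels.
#' @export
cprg_conditions <- function() c("30 LB0", "30 LB1", "RT LB0", "RT LB1")

layout_columns <- c("plate", "row", "col", "strain_id", "mutant_id",
                    "clone_index", "is_control", "is_empty")

new_plate_layout <- function(df, rows, cols) {
  structure(df, rows = as.integer(rows), cols = as.integer(cols),
            class = c("plate_layout", class(tibble())))
}

validate_layout <- function(df, rows, cols) {
  dup <- df |> dplyr::count(.data$plate, .data$row, .data$col) |> dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicate layout positions: %s",
                  paste(sprintf("%s(%d,%d)", dup$plate, dup$row, dup$col), collapse = ", ")))
  }
  oob <- df$row < 0 | df$row >= rows | df$col < 0 | df$col >= cols
  if (any(oob)) {
    abort(sprintf("layout positions outside the %d x %d grid (0-based): %s",
                  rows, cols,
                  paste(sprintf("%s(%d,%d)", df$plate[oob], df$row[oob], df$col[oob]), collapse = ", ")))
  }
  no_id <- !df$is_empty & (is.na(df$mutant_id) | df$mutant_id == "")
  if (any(no_id)) abort("non-empty layout entries must name a mutant_id")
  invisible(df)
}

#' Arrange an ordered mutant library onto pinned plates
#'
#' Builds a plate layout for a replicated ordered library: each mutant is
#' represented by `clones` replicate clones. With
#' `arrangement = "same_plate"` (the default) the clones of a mutant sit at
#' separate positions on the same plate (clone 1 in the top half, clone 2 in
#' the bottom half, row-major); with `"sister_plates"` clone `k` of every
#' mutant sits at the same grid position on sister plate `<plate>s<k>`.
#'
#' @param mutant_ids Character vector of mutant identifiers.
#' @param rows,cols Plate grid format (default 16 x 24 = 384-pin).
#' @param clones Replicate clones per mutant (default 2, as in ordered
#'   deletion libraries).
#' @param arrangement `"same_plate"` or `"sister_plates"`.
#' @return A `plate_layout` tibble with columns
#'   `plate, row, col, strain_id, mutant_id, clone_index, is_control,
#'   is_empty`; grid positions are 0-based, row-major, origin top-left.
#' @export
make_screen_layout <- function(mutant_ids, rows = 16L, cols = 24L, clones = 2L,
                               arrangement = c("same_plate", "sister_plates")) {
  arrangement <- match.arg(arrangement)
  rows <- as.integer(rows); cols <- as.integer(cols); clones <- as.integer(clones)
  cap <- rows * cols
  n <- length(mutant_ids)
  if (!n) abort("`mutant_ids` must be non-empty")
  if (anyDuplicated(mutant_ids)) abort("`mutant_ids` must be unique")

  if (arrangement == "same_plate") {
    per_plate <- cap %/% clones
    entries <- purrr::map_dfr(seq_len(ceiling(n / per_plate)), function(p) {
      idx <- ((p - 1) * per_plate + 1):min(p * per_plate, n)
      m <- mutant_ids[idx]
      k <- length(m)
      purrr::map_dfr(seq_len(clones), function(cl) {
        pos <- (cl - 1) * per_plate + seq_len(k) - 1L  # row-major offset
        tibble(plate = sprintf("p%02d", p),
               row = pos %/% cols, col = pos %% cols,
               strain_id = sprintf("%s.c%d", m, cl),
               mutant_id = m, clone_index = cl,
               is_control = FALSE, is_empty = FALSE)
      })
    })
  } else {
    entries <- purrr::map_dfr(seq_len(ceiling(n / cap)), function(p) {
      idx <- ((p - 1) * cap + 1):min(p * cap, n)
      m <- mutant_ids[idx]
      pos <- seq_along(m) - 1L
      purrr::map_dfr(seq_len(clones), function(cl) {
        tibble(plate = sprintf("p%02ds%d", p, cl),
               row = pos %/% cols, col = pos %% cols,
               strain_id = sprintf("%s.c%d", m, cl),
               mutant_id = m, clone_index = cl,
               is_control = FALSE, is_empty = FALSE)
      })
    })
  }
  # pad unused positions of each plate as explicit empties
  full <- entries |>
    dplyr::group_by(.data$plate) |>
    dplyr::group_modify(function(df, key) {
      grid <- tidyr::expand_grid(row = 0:(rows - 1L), col = 0:(cols - 1L))
      dplyr::left_join(grid, df, by = c("row", "col")) |>
        dplyr::mutate(
          is_empty = is.na(.data$mutant_id),
          is_control = dplyr::coalesce(.data$is_control, FALSE),
          clone_index = dplyr::coalesce(.data$clone_index, NA_integer_)
        )
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(layout_columns))
  validate_layout(full, rows, cols)
  new_plate_layout(full, rows, cols)
}

#' Read a plate layout from TSV
#'
#' Expects the columns `plate, row, col, strain_id, mutant_id, clone_index,
#' is_control, is_empty` (tab-separated, header required). Grid positions are
#' 0-based, row-major, origin at the top-left of the image. Duplicate or
#' out-of-range positions are rejected.
#'
#' @param path Path to a TSV file.
#' @param rows,cols Expected grid format (default 16 x 24).
#' @return A `plate_layout` tibble.
#' @export
read_layout <- function(path, rows = 16L, cols = 24L) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "#")
  missing_cols <- setdiff(layout_columns, names(df))
  if (length(missing_cols)) {
    abort(sprintf("layout file lacks required columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df[layout_columns])
  df$row <- as.integer(df$row); df$col <- as.integer(df$col)
  df$clone_index <- as.integer(df$clone_index)
  df$is_control <- as.logical(df$is_control)
  df$is_empty <- as.logical(df$is_empty)
  df$mutant_id <- as.character(df$mutant_id)
  df$mutant_id[is.na(df$mutant_id)] <- ""
  validate_layout(df, rows, cols)
  new_plate_layout(df, rows, cols)
}

#' Write a plate layout to TSV
#'
#' @param layout A `plate_layout` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout)[layout_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Index replicate clone positions per mutant and condition
#'
#' Builds the replicate index used for clone averaging: for every mutant and
#' condition, the list of (plate, row, col) positions holding its clones.
#' Mutants with a clone count other than 2 are flagged (`single_clone`,
#' `multi_clone`); a mutant absent from a condition is recorded with
#' `n_clones = 0` and flag `missing`, not treated as an error.
#'
#' @param layouts Either a single `plate_layout` shared by all conditions, or
#'   a named list of layouts, one per condition.
#' @param conditions Character vector of condition labels (default the four
#'   screen conditions of [cprg_conditions()]).
#' @return A tibble with columns `mutant_id, condition, plate, row, col,
#'   clone_index, n_clones, flag`, one row per clone position (or one
#'   `NA`-position row for missing mutants).
#' @export
map_replicates <- function(layouts, conditions = cprg_conditions()) {
  if (inherits(layouts, "plate_layout") || is.data.frame(layouts)) {
    layouts <- stats::setNames(rep(list(layouts), length(conditions)), conditions)
  }
  missing_conditions <- setdiff(conditions, names(layouts))
  if (length(missing_conditions)) {
    abort(sprintf("no layout supplied for condition(s): %s",
                  paste(missing_conditions, collapse = ", ")))
  }
  all_mutants <- unique(unlist(lapply(layouts[conditions], function(l) {
    l$mutant_id[!l$is_empty & !l$is_control]
  })))
  idx <- purrr::map_dfr(conditions, function(cond) {
    l <- layouts[[cond]]
    pos <- l |>
      dplyr::filter(!.data$is_empty, !.data$is_control) |>
      dplyr::select("mutant_id", "plate", "row", "col", "clone_index") |>
      dplyr::mutate(condition = cond)
    absent <- setdiff(all_mutants, pos$mutant_id)
    if (length(absent)) {
      pos <- dplyr::bind_rows(pos, tibble(
        mutant_id = absent, plate = NA_character_, row = NA_integer_,
        col = NA_integer_, clone_index = NA_integer_, condition = cond))
    }
    pos
  })
  idx |>
    dplyr::group_by(.data$mutant_id, .data$condition) |>
    dplyr::mutate(n_clones = sum(!is.na(.data$plate))) |>
    dplyr::ungroup() |>
    dplyr::mutate(flag = dplyr::case_when(
      n_clones == 0L ~ "missing",
      n_clones == 1L ~ "single_clone",
      n_clones == 2L ~ "",
      TRUE ~ "multi_clone"
    )) |>
    dplyr::select("mutant_id", "condition", "plate", "row", "col",
                  "clone_index", "n_clones", "flag") |>
    dplyr::arrange(.data$mutant_id, .data$condition, .data$clone_index)
}
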