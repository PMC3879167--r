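# Sector labels in angular order starting at +x (east), y pointing down.
.sector_names <- c("E", "SE", "S", "SW", "W", "NW", "N", "NE")

#' Quantify every colony of a plate image
#'
#' The per-plate quantification pipeline: fits the pin grid
#' ([fit_grid()]), segments each cell ([segment_colony()]), measures HSV
#' colour and background-corrected redness over the colony mask and its halo
#' annulus ([measure_color()]), and emits one measurement row per non-empty
#' layout position (or per grid position when no layout is given). The halo
#' annulus extends `halo_width` pixels beyond the colony rim but is clipped to
#' the cell rectangle so it stops before neighbouring cells; its redness is
#' additionally summarised in 8 directional sectors, which
#' [flag_neighbor_contamination()] uses to tell locally produced pigment from
#' colour diffusing in from a red neighbour.
#'
#' @param image A [plate_image()], `plate_render`, or RGB array.
#' @param layout Optional `plate_layout`; when given, only this plate's
#'   non-empty positions are measured and mutant annotation is joined in.
#' @param rows,cols Grid format (taken from `layout` when given).
#' @param halo Include the halo annulus in the redness sum (default TRUE).
#' @param halo_width Annulus width beyond the colony rim, pixels; default half
#'   the fitted pin spacing.
#' @param h_ref,sigma_h Redness kernel: reference hue and kernel width in
#'   degrees (defaults 0 and 20).
#' @param min_area Minimum colony mask area (pixels).
#' @param normalize `"none"` (raw scores, default) or `"plate_median"`
#'   (scores divided by the plate median positive score).
#' @return A measurement tibble, one row per position: grid indices, centre,
#'   `mask_area`, `mean_hue`, `mean_saturation`, `mean_value`, `redness_sum`,
#'   `cprg_score`, `size_score`, 8 `halo_*` sector means and a comma-separated
#'   `flags` column. The fitted grid, quantification parameters and source
#'   image id are attached as attributes (`grid`, `params`, `source_image`).
#' @export
quantify_plate <- function(image, layout = NULL, rows = 16L, cols = 24L,
                           halo = TRUE, halo_width = NULL,
                           h_ref = 0, sigma_h = 20, min_area = 10,
                           normalize = c("none", "plate_median")) {
  normalize <- match.arg(normalize)
  px <- if (is.list(image)) image$pixels %||% image$image else image
  meta <- if (inherits(image, "plate_image")) {
    image
  } else if (inherits(image, "plate_render")) {
    list(plate_id = image$plate_id, condition = NA_character_,
         timepoint = image$elapsed_time)
  } else list(plate_id = "plate", condition = NA_character_, timepoint = NA_real_)
  if (!is.null(layout)) {
    rows <- attr(layout, "rows") %||% rows
    cols <- attr(layout, "cols") %||% cols
  }
  grid <- fit_grid(px, rows, cols)
  if (is.null(halo_width)) halo_width <- 0.5 * (grid$spacing_y + grid$spacing_x) / 2

  positions <- if (is.null(layout)) {
    tidyr::expand_grid(row = 0:(rows - 1L), col = 0:(cols - 1L)) |>
      dplyr::mutate(mutant_id = sprintf("m%02d_%02d", .data$row, .data$col),
                    clone_index = NA_integer_)
  } else {
    layout |>
      dplyr::filter(!.data$is_empty) |>
      dplyr::select("row", "col", "mutant_id", "clone_index") |>
      as_tibble()
  }

  one <- function(row, col, mutant_id, clone_index) {
    seg <- segment_colony(px, grid, row, col, min_area = min_area)
    ys <- seg$bbox$ys; xs <- seg$bbox$xs
    cell <- px[ys, xs, , drop = FALSE]
    flags <- seg$flag
    if (seg$area == 0) {
      return(tibble(row = row, col = col, mutant_id = mutant_id,
                    clone_index = clone_index,
                    center_y = seg$centroid[["y"]], center_x = seg$centroid[["x"]],
                    mask_area = 0, mean_hue = NA_real_, mean_saturation = NA_real_,
                    mean_value = NA_real_, redness_sum = 0, cprg_score = 0,
                    size_score = 0,
                    !!!stats::setNames(as.list(rep(0, 8)), paste0("halo_", .sector_names)),
                    flags = paste(unique(c("empty", flags[flags != ""])), collapse = ",")))
    }
    r_eff <- sqrt(seg$area / pi)
    dy <- ys - seg$centroid[["y"]]; dx <- xs - seg$centroid[["x"]]
    dist <- sqrt(outer(dy^2, dx^2, `+`))
    halo_mask <- !seg$mask & dist > r_eff & dist <= r_eff + halo_width
    bgh <- pixels_to_hsv(array(seg$background, c(1, 1, 3)))
    wbg <- redness_weight(bgh$h[1], bgh$s[1], h_ref, sigma_h)
    mc <- measure_color(cell, seg$mask,
                        halo_annulus = if (halo) halo_mask else NULL,
                        background = seg$background, h_ref = h_ref, sigma_h = sigma_h)
    # directional halo redness, always computed from the annulus
    sect <- rep(0, 8)
    if (any(halo_mask)) {
      hh <- pixels_to_hsv(cell, halo_mask)
      wpix <- pmax(redness_weight(hh$h, hh$s, h_ref, sigma_h) - wbg, 0)
      ang <- atan2(matrix(dy, length(ys), length(xs))[halo_mask],
                   matrix(dx, length(ys), length(xs), byrow = TRUE)[halo_mask])
      bin <- (round(ang / (pi / 4)) %% 8) + 1  # 1 = E, 2 = SE, ...
      sums <- tapply(wpix, factor(bin, levels = 1:8), mean, default = 0)
      sect <- as.numeric(sums)
    }
    tibble(row = row, col = col, mutant_id = mutant_id, clone_index = clone_index,
           center_y = seg$centroid[["y"]], center_x = seg$centroid[["x"]],
           mask_area = seg$area,
           mean_hue = mc$mean_hue, mean_saturation = mc$mean_saturation,
           mean_value = mc$mean_value, redness_sum = mc$redness_sum,
           cprg_score = cprg_score(mc$redness_sum), size_score = seg$area,
           !!!stats::setNames(as.list(sect), paste0("halo_", .sector_names)),
           flags = paste(flags[flags != ""], collapse = ","))
  }
  out <- purrr::pmap_dfr(positions, one)
  if (normalize == "plate_median") {
    med <- stats::median(out$cprg_score[out$cprg_score > 0])
    if (is.finite(med) && med > 0) out$cprg_score <- out$cprg_score / med
  }
  out <- dplyr::mutate(out,
                       plate = meta$plate_id, condition = meta$condition,
                       timepoint = meta$timepoint, .before = 1)
  attr(out, "grid") <- grid
  attr(out, "params") <- list(rows = rows, cols = cols, halo = halo,
                              halo_width = halo_width, h_ref = h_ref,
                              sigma_h = sigma_h, min_area = min_area,
                              normalize = normalize)
  attr(out, "source_image") <- meta$plate_id
  out
}

#' Flag colonies whose redness is colour spill from a red neighbour
#'
#' A colony is flagged `neighbor_contaminated` when (a) one of its 8 grid
#' neighbours has a CPRG score above the hit threshold and (b) the colony's
#' halo-annulus redness is directional toward that neighbour: the mean annulus
#' redness of the sector facing the neighbour exceeds `gamma` times the
#' opposite sector. Flagged colonies are excluded from hit calling at that
#' timepoint (the screen design quantifies an earlier image instead, where
#' halos have not yet reached neighbours).
#'
#' Colour can only diffuse from a redder colony to a whiter one, so a colony
#' is only flagged when the offending neighbour's score also dominates its
#' own (`delta`-fold); this protects genuinely red colonies sitting next to
#' each other from flagging one another.
#'
#' @param measurements Measurement tibble from [quantify_plate()] (one plate).
#' @param threshold Hit threshold on the CPRG score.
#' @param gamma Directionality factor (default 2).
#' @param delta Required neighbour/self score ratio (default 2).
#' @return `measurements` with `neighbor_contaminated` appended to `flags`
#'   where detected.
#' @export
flag_neighbor_contamination <- function(measurements, threshold, gamma = 2,
                                        delta = 2) {
  m <- measurements
  key <- paste(m$row, m$col)
  hit <- m$cprg_score > threshold
  # neighbour offsets paired with the sector facing them and its opposite
  offs <- list(E = c(0, 1), SE = c(1, 1), S = c(1, 0), SW = c(1, -1),
               W = c(0, -1), NW = c(-1, -1), N = c(-1, 0), NE = c(-1, 1))
  opposite <- stats::setNames(.sector_names[((seq_along(.sector_names) + 3) %% 8) + 1],
                              .sector_names)
  eps <- 1e-9
  contaminated <- rep(FALSE, nrow(m))
  for (s in names(offs)) {
    nb <- match(paste(m$row + offs[[s]][1], m$col + offs[[s]][2]), key)
    nb_hit <- !is.na(nb) & hit[nb] & m$cprg_score[nb] > delta * m$cprg_score
    toward <- m[[paste0("halo_", s)]]
    away <- m[[paste0("halo_", opposite[[s]])]]
    contaminated <- contaminated |
      (nb_hit & toward > gamma * (away + eps) & toward > 0.01)
  }
  # a genuinely red colony is protected by the gradient criterion: its own
  # halo is isotropic, so toward/opposite sector ratios stay near 1
  m$flags <- ifelse(contaminated & !grepl("neighbor_contaminated", m$flags),
                    sub("^,", "", paste(m$flags, "neighbor_contaminated", sep = ",")),
                    m$flags)
  m$flags <- sub("^,", "", m$flags)
  m
}
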