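# Rendering constants shared by the forward model and its documentation:
# colony discs are bright near-white plastic-on-agar (value channel ~0.92);
# red pigment converts saturation, not brightness; a fixed fraction of the
# rim pigment leaks into the halo.
.colony_value <- 0.92
.halo_fraction <- 0.6

#' Ground-truth colony table for a synthetic plate
#'
#' Realises per-colony geometry (jittered centres, radii) and planted redness
#' for every grid position of a plate. The result is the ground truth consumed
#' by [render_plate()] and compared against by downstream recovery tests.
#'
#' @param spec A [plate_spec()].
#' @param redness Planted redness per position, recycled row-major over the
#'   grid. 0 renders a white (CPRG-) colony; redness accumulates pigment as
#'   `1 - exp(-redness)` saturation, so values in (0, 2] span pink to
#'   fully red.
#' @param mutant_id Mutant identifiers per position (recycled); default
#'   `"m<row>_<col>"`.
#' @param empty Either a single fraction of positions to leave empty (no
#'   colony pinned) or a logical vector over the grid, row-major.
#' @param plate_id Identifier used to derive the per-plate random substream.
#' @return A tibble with columns `row`, `col` (0-based grid indices),
#'   `center_y`, `center_x`, `radius` (pixels), `redness_true`, `size_true`
#'   (pixels^2), `is_empty`, `mutant_id`.
#' @export
make_colony_truths <- function(spec, redness = 0, mutant_id = NULL,
                               empty = 0, plate_id = "p1") {
  n <- spec$rows * spec$cols
  pc <- pin_centers(spec)
  grid <- tidyr::expand_grid(row = seq(0L, spec$rows - 1L),
                             col = seq(0L, spec$cols - 1L))
  redness <- rep_len(redness, n)
  if (is.null(mutant_id)) mutant_id <- sprintf("m%02d_%02d", grid$row, grid$col)
  mutant_id <- rep_len(mutant_id, n)
  withr::with_seed(derive_seed(spec$seed, "truth", plate_id), {
    jit_y <- stats::rnorm(n, 0, spec$position_jitter_sd)
    jit_x <- stats::rnorm(n, 0, spec$position_jitter_sd)
    radius <- pmax(1, stats::rnorm(n, spec$colony_radius_mean, spec$colony_radius_sd))
    radius <- pmin(radius, spec_max_radius(spec))
    is_empty <- if (is.logical(empty)) rep_len(empty, n) else stats::runif(n) < empty
  })
  tibble(
    row = grid$row, col = grid$col,
    center_y = pc$y[grid$row + 1L] + jit_y,
    center_x = pc$x[grid$col + 1L] + jit_x,
    radius = ifelse(is_empty, 0, radius),
    redness_true = ifelse(is_empty, 0, redness),
    size_true = ifelse(is_empty, 0, pi * radius^2),
    is_empty = is_empty,
    mutant_id = mutant_id
  )
}

# Deterministic background field (gradient + vignette, no noise), HxW matrix.
background_field <- function(spec) {
  d <- plate_dims(spec)
  h <- d[["height"]]; w <- d[["width"]]
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  y <- matrix(seq_len(h), h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  dmax2 <- (h - cy)^2 + (w - cx)^2
  level <- spec$background_level + spec$background_gradient * (x - cx)
  vig <- 1 - spec$vignette_strength * (((y - cy)^2 + (x - cx)^2) / dmax2)
  pmin(pmax(level * vig, 0), 1)
}

#' Render a synthetic plate photograph
#'
#' Forward model of a CPRG indicator plate: each non-empty colony is a bright
#' disc whose colour interpolates white to red with its planted redness
#' (saturation `1 - exp(-redness_true)` at hue 0), sitting on an agar
#' background with linear gradient, radial vignette and i.i.d. sensor noise.
#' Red colonies are surrounded by a radially decaying Gaussian halo of width
#' `halo_diffusion_sigma_per_hour * elapsed_time` beyond the rim, emulating
#' diffusion of the hydrolysis product into the agar. Identical spec, truth
#' and arguments reproduce the image bit-for-bit.
#'
#' @param spec A [plate_spec()].
#' @param truths Colony truth table from [make_colony_truths()] (or any subset
#'   of grid positions with the same columns).
#' @param elapsed_time Incubation time in hours (>= 0); scales the halo width.
#'   Colony geometry does not change with time, isolating colour effects from
#'   size effects.
#' @param plate_id Identifier folded into the noise substream and carried into
#'   the result.
#' @return A list of class `plate_render` with elements `image` (height x
#'   width x 3 array, values quantised to 8-bit sRGB on a 0-1 scale), `truth`
#'   (the input tibble), `spec`, `elapsed_time`, `plate_id`.
#' @export
render_plate <- function(spec, truths, elapsed_time = 12, plate_id = "p1") {
  if (elapsed_time < 0) abort("`elapsed_time` must be >= 0")
  bad <- truths$row < 0 | truths$row >= spec$rows | truths$col < 0 | truths$col >= spec$cols
  if (any(bad)) {
    abort(sprintf("truth positions outside the %d x %d grid: %s",
                  spec$rows, spec$cols,
                  paste(sprintf("(%d,%d)", truths$row[bad], truths$col[bad]), collapse = ", ")))
  }
  d <- plate_dims(spec)
  h <- d[["height"]]; w <- d[["width"]]
  sigma <- spec$halo_diffusion_sigma_per_hour * elapsed_time

  pigment <- matrix(0, h, w)   # colony saturation (alpha)
  halo <- matrix(0, h, w)      # halo saturation over agar
  disc <- matrix(FALSE, h, w)
  overlap <- FALSE

  live <- truths[!truths$is_empty & truths$radius > 0, ]
  for (i in seq_len(nrow(live))) {
    cy <- live$center_y[i]; cx <- live$center_x[i]; r <- live$radius[i]
    a <- 1 - exp(-live$redness_true[i])
    ext <- ceiling(r + (if (a > 0) 4 * sigma else 0) + 2)
    ys <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
    xs <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
    dy <- ys - cy; dx <- xs - cx
    dist <- sqrt(outer(dy^2, dx^2, `+`))
    in_disc <- dist <= r
    if (any(disc[ys, xs] & in_disc)) overlap <- TRUE
    disc[ys, xs] <- disc[ys, xs] | in_disc
    pig <- pigment[ys, xs]
    pig[in_disc] <- pmax(pig[in_disc], a)
    pigment[ys, xs] <- pig
    if (a > 0 && sigma > 0) {
      hv <- a * .halo_fraction * exp(-pmax(dist - r, 0)^2 / (2 * sigma^2))
      hv[in_disc] <- 0
      halo[ys, xs] <- pmax(halo[ys, xs], hv)
    }
  }
  if (overlap) warn("overlapping colony discs; rendered by max-blend")

  bg <- background_field(spec)
  red <- ifelse(disc, .colony_value, bg)
  grn <- ifelse(disc, .colony_value * (1 - pigment), bg * (1 - halo))
  blu <- grn
  img <- array(c(red, grn, blu), dim = c(h, w, 3))
  if (spec$noise_sd > 0) {
    withr::with_seed(derive_seed(spec$seed, "render", plate_id, format(elapsed_time)), {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    })
  }
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  structure(list(image = img, truth = truths, spec = spec,
                 elapsed_time = elapsed_time, plate_id = plate_id),
            class = "plate_render")
}

#' @export
print.plate_render <- function(x, ...) {
  cat(sprintf("<plate_render> %s: %d x %d px, %d colonies, t = %g h\n",
              x$plate_id, dim(x$image)[1], dim(x$image)[2],
              sum(!x$truth$is_empty), x$elapsed_time))
  invisible(x)
}
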