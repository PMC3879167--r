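# Value channel (HSV V = max of R,G,B) of an image array.
value_channel <- function(px) pmax(px[, , 1], px[, , 2], px[, , 3])

# Weighted positional profile of foreground mass along one axis, optionally
# under a small rotation (profiles are accumulated over coordinates projected
# onto the rotated axis).
axis_profile <- function(w, coord, n_bins) {
  idx <- pmin(pmax(round(coord), 1L), n_bins)
  as.numeric(tapply(w, factor(idx, levels = seq_len(n_bins)), sum, default = 0))
}

# Best regular lattice (offset + spacing) for k peaks on a 1-D profile.
# Exhaustive grid search over spacing and offset, then per-centre centroid
# refinement within a third of the spacing.
fit_lattice <- function(profile, k) {
  L <- length(profile)
  sm <- stats::filter(profile, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  s_grid <- seq(L / (k + 3), (L - 2) / max(k - 1, 1), length.out = 140)
  best <- list(score = -Inf)
  for (s in s_grid) {
    span <- s * (k - 1)
    offs <- seq(1, max(L - span, 1), by = max(s / 20, 0.5))
    for (o in offs) {
      centers <- o + s * (0:(k - 1))
      sc <- sum(sm[pmin(pmax(round(centers), 1L), L)])
      if (sc > best$score) best <- list(score = sc, offset = o, spacing = s)
    }
  }
  rigid <- best$offset + best$spacing * (0:(k - 1))
  half <- best$spacing / 3
  refined <- vapply(rigid, function(cc) {
    lo <- max(1L, floor(cc - half)); hi <- min(L, ceiling(cc + half))
    wts <- profile[lo:hi]
    if (sum(wts) <= 0) cc else sum((lo:hi) * wts) / sum(wts)
  }, numeric(1))
  if (any(diff(refined) <= 0)) refined <- rigid
  contrast <- mean(sm[pmin(pmax(round(refined), 1L), L)]) / (mean(sm) + 1e-12)
  list(centers = refined, rigid = rigid, spacing = best$spacing,
       residual = sqrt(mean((refined - rigid)^2)), contrast = contrast)
}

#' Fit the pin grid of a colony-array image
#'
#' Locates the row and column centre lines of a pinned array by peak-fitting
#' smoothed axis projections of the background-subtracted value channel,
#' preceded by a small-angle rotation search that maximises projection
#' sharpness. The grid model is rigid (regular row/column lattice plus one
#' global rotation); each centre line is then refined by a local profile
#' centroid, and the RMS deviation of the refined centres from the rigid
#' lattice is reported as the fit residual.
#'
#' @param image A [plate_image()], `plate_render`, or RGB array.
#' @param rows,cols Expected grid dimensions (default 16 x 24).
#' @param rotation_angles Candidate rotations in degrees (default
#'   `seq(-2, 2, 0.5)`); fits beyond +/- 5 degrees are treated as failures.
#' @return A list of class `grid_fit`: `row_centers` (y, pixels),
#'   `col_centers` (x), `rotation` (degrees), `residual` (pixels),
#'   `spacing_y`, `spacing_x`, and the two `profiles`. Errors with class
#'   `chromopin_grid_fit_error` (carrying the offending profile) when no
#'   credible grid is found.
#' @export
fit_grid <- function(image, rows = 16L, cols = 24L,
                     rotation_angles = seq(-2, 2, by = 0.5)) {
  px <- if (is.list(image)) image$pixels %||% image$image else image
  v <- value_channel(px)
  h <- nrow(v); w <- ncol(v)
  bg <- stats::median(v)
  dev <- pmax(v - bg, 0)
  if (max(dev) <= 0) {
    abort("image has no foreground above the background level; no grid to fit",
          class = "chromopin_grid_fit_error")
  }
  fg <- which(dev > 0.1 * max(dev))
  ys <- ((fg - 1) %% h) + 1
  xs <- ((fg - 1) %/% h) + 1
  wts <- dev[fg]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2

  sharpness <- vapply(rotation_angles, function(a) {
    th <- a * pi / 180
    yr <- cy + (ys - cy) * cos(th) - (xs - cx) * sin(th)
    xr <- cx + (ys - cy) * sin(th) + (xs - cx) * cos(th)
    sum(axis_profile(wts, yr, h)^2) + sum(axis_profile(wts, xr, w)^2)
  }, numeric(1))
  ang <- rotation_angles[which.max(sharpness)]
  if (abs(ang) > 5) {
    abort(sprintf("grid rotation beyond +/- 5 degrees (best %g)", ang),
          class = "chromopin_grid_fit_error")
  }
  th <- ang * pi / 180
  yr <- cy + (ys - cy) * cos(th) - (xs - cx) * sin(th)
  xr <- cx + (ys - cy) * sin(th) + (xs - cx) * cos(th)
  prof_y <- axis_profile(wts, yr, h)
  prof_x <- axis_profile(wts, xr, w)

  fy <- fit_lattice(prof_y, rows)
  fx <- fit_lattice(prof_x, cols)
  if (fy$contrast < 1.3 || fx$contrast < 1.3) {
    abort(sprintf("no credible %d x %d grid (profile contrast %.2f / %.2f)",
                  rows, cols, fy$contrast, fx$contrast),
          class = "chromopin_grid_fit_error",
          profile_y = prof_y, profile_x = prof_x)
  }
  structure(list(
    row_centers = fy$centers, col_centers = fx$centers,
    rotation = ang, residual = sqrt((fy$residual^2 + fx$residual^2) / 2),
    spacing_y = fy$spacing, spacing_x = fx$spacing,
    rows = as.integer(rows), cols = as.integer(cols),
    image_center = c(y = cy, x = cx),
    profiles = list(y = prof_y, x = prof_x)
  ), class = "grid_fit")
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf("<grid_fit> %d x %d, spacing %.2f x %.2f px, rotation %g deg, residual %.2f px\n",
              x$rows, x$cols, x$spacing_y, x$spacing_x, x$rotation, x$residual))
  invisible(x)
}

# Pin centre of (row, col) in original image coordinates (inverting the
# fitted rotation about the image centre).
grid_center <- function(grid, row, col) {
  y <- grid$row_centers[row + 1L]
  x <- grid$col_centers[col + 1L]
  if (grid$rotation != 0) {
    th <- -grid$rotation * pi / 180
    cy <- grid$image_center[["y"]]; cx <- grid$image_center[["x"]]
    yy <- cy + (y - cy) * cos(th) - (x - cx) * sin(th)
    xx <- cx + (y - cy) * sin(th) + (x - cx) * cos(th)
    c(y = yy, x = xx)
  } else c(y = y, x = x)
}
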