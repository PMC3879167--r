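#' Segment one colony cell of a gridded plate image
#'
#' Works inside the rectangular cell around the pin position `(row, col)`:
#' the per-channel median over the cell's border annulus (agar only)
#' estimates the local background; foreground pixels are those whose
#' value-channel deviation above that background exceeds an Otsu-derived
#' split; the largest connected component touching the cell centre is kept.
#' Cells whose kept component is smaller than `min_area` are flagged empty.
#'
#' @param image RGB array (or [plate_image()]/`plate_render`).
#' @param grid A [fit_grid()] result.
#' @param row,col 0-based grid indices.
#' @param min_area Minimum mask area in pixels to count as a colony.
#' @param min_contrast Minimum value-channel deviation for any foreground
#'   (guards noise-only cells).
#' @return A list: `bbox` (`ys`, `xs` pixel ranges of the cell), `mask`
#'   (logical matrix over the cell), `background` (RGB triple), `area`
#'   (pixels), `centroid` (`y`, `x` in image coordinates; pin centre when
#'   empty), `flag` (`""`, `"empty"` or `"segmentation_low_confidence"`).
#' @export
segment_colony <- function(image, grid, row, col, min_area = 10,
                           min_contrast = 0.05) {
  px <- if (is.list(image)) image$pixels %||% image$image else image
  h <- dim(px)[1]; w <- dim(px)[2]
  ctr <- grid_center(grid, row, col)
  hy <- grid$spacing_y / 2; hx <- grid$spacing_x / 2
  ys <- max(1L, ceiling(ctr[["y"]] - hy)):min(h, floor(ctr[["y"]] + hy))
  xs <- max(1L, ceiling(ctr[["x"]] - hx)):min(w, floor(ctr[["x"]] + hx))
  cell <- px[ys, xs, , drop = FALSE]
  nv <- length(ys); nx <- length(xs)

  bw <- max(2L, round(0.15 * min(nv, nx)))
  border <- matrix(TRUE, nv, nx)
  if (nv > 2 * bw && nx > 2 * bw) border[(bw + 1):(nv - bw), (bw + 1):(nx - bw)] <- FALSE
  background <- vapply(1:3, function(ch) stats::median(cell[, , ch][border]), numeric(1))

  v <- value_channel(cell)
  dev <- pmax(v - max(background), 0)
  empty_result <- function(flag) {
    list(bbox = list(ys = ys, xs = xs), mask = matrix(FALSE, nv, nx),
         background = background, area = 0,
         centroid = c(y = ctr[["y"]], x = ctr[["x"]]), flag = flag)
  }
  if (max(dev) < min_contrast) return(empty_result("empty"))

  thr <- tryCatch(EBImage::otsu(EBImage::Image(dev / max(dev))) * max(dev),
                  error = function(e) max(dev) / 2)
  fg <- dev > pmax(thr, min_contrast / 2)
  if (!any(fg)) return(empty_result("empty"))

  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  ci <- round(ctr[["y"]] - ys[1] + 1); cj <- round(ctr[["x"]] - xs[1] + 1)
  nbr_i <- pmin(pmax(ci + (-2:2), 1L), nv); nbr_j <- pmin(pmax(cj + (-2:2), 1L), nx)
  central <- unique(as.numeric(lab[nbr_i, nbr_j]))
  central <- central[central > 0]
  if (!length(central)) return(empty_result("empty"))
  keep <- central[which.max(tabulate(match(lab, central), length(central)))]
  mask <- lab == keep
  area <- sum(mask)
  if (area < min_area) return(empty_result("empty"))

  touches_edge <- any(mask[1, ]) || any(mask[nv, ]) || any(mask[, 1]) || any(mask[, nx])
  centroid_y <- sum(row(mask)[mask]) / area + ys[1] - 1
  centroid_x <- sum(col(mask)[mask]) / area + xs[1] - 1
  list(bbox = list(ys = ys, xs = xs), mask = mask, background = background,
       area = area, centroid = c(y = centroid_y, x = centroid_x),
       flag = if (touches_edge) "segmentation_low_confidence" else "")
}
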