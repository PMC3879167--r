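# Circular hue distance in degrees.
hue_distance <- function(h, h_ref) {
  d <- abs(((h - h_ref) %% 360))
  pmin(d, 360 - d)
}

# Per-pixel redness weight: saturation times a Gaussian kernel on circular
# hue distance to the reference (product colour) hue.
redness_weight <- function(h, s, h_ref = 0, sigma_h = 20) {
  w <- s * exp(-hue_distance(h, h_ref)^2 / (2 * sigma_h^2))
  w[is.na(w)] <- 0  # achromatic pixels (undefined hue) carry no redness
  w
}

# HSV (h degrees, s, v in 0-1) for the pixels of an RGB array selected by a
# logical mask (or all pixels when mask is NULL).
pixels_to_hsv <- function(px, mask = NULL) {
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  if (!is.null(mask)) { r <- r[mask]; g <- g[mask]; b <- b[mask] }
  hsv <- grDevices::rgb2hsv(rbind(as.numeric(r), as.numeric(g), as.numeric(b)),
                            maxColorValue = 1)
  list(h = hsv[1, ] * 360, s = hsv[2, ], v = hsv[3, ])
}

# Circular mean of hues (degrees), weighted; NA when no chromatic pixels.
circular_mean_hue <- function(h, w = NULL) {
  keep <- !is.na(h)
  if (!is.null(w)) keep <- keep & w > 0
  if (!any(keep)) return(NA_real_)
  w <- if (is.null(w)) rep(1, sum(keep)) else w[keep]
  th <- h[keep] * pi / 180
  (atan2(sum(w * sin(th)), sum(w * cos(th))) * 180 / pi) %% 360
}

#' Measure HSV colour and redness of a colony region
#'
#' Converts the pixels of `mask` (colony) and `halo_annulus` (diffusion ring)
#' to HSV and computes the saturation-weighted, hue-kernel redness: each pixel
#' contributes `w = s * exp(-d(h, h_ref)^2 / (2 * sigma_h^2))` with `d` the
#' circular hue distance, and the redness sum is
#' `R = sum over mask + halo of max(0, w - w_bg)` where `w_bg` is the redness
#' of the local background estimate. A fully saturated red pixel contributes
#' exactly 1; achromatic (white/gray) pixels contribute 0.
#'
#' @param image RGB array (or [plate_image()]/`plate_render`).
#' @param mask Logical matrix of colony pixels (same height/width as image).
#' @param halo_annulus Optional logical matrix of halo pixels.
#' @param background Background estimate: either a length-3 RGB triple (its
#'   redness is used as `w_bg`) or a single number giving `w_bg` directly,
#'   e.g. the mean per-pixel redness of the surrounding agar, which also
#'   captures the sensor-noise redness floor. Default black (no correction).
#' @param h_ref Reference hue in degrees (default 0, the red hydrolysis
#'   product).
#' @param sigma_h Hue kernel width in degrees (default 20).
#' @return A list: `mean_hue` (circular mean over chromatic mask pixels,
#'   degrees; `NA` when the region is achromatic), `mean_saturation`,
#'   `mean_value`, `redness_sum`.
#' @export
measure_color <- function(image, mask, halo_annulus = NULL,
                          background = c(0, 0, 0), h_ref = 0, sigma_h = 20) {
  px <- if (is.list(image)) image$pixels %||% image$image else image
  if (!any(mask) && (is.null(halo_annulus) || !any(halo_annulus))) {
    abort("`mask` and `halo_annulus` are both empty")
  }
  w_bg <- if (length(background) == 1L) background else {
    bgh <- pixels_to_hsv(array(background, c(1, 1, 3)))
    redness_weight(bgh$h[1], bgh$s[1], h_ref, sigma_h)
  }
  region <- mask | (if (is.null(halo_annulus)) FALSE else halo_annulus)
  hsv <- pixels_to_hsv(px, region)
  w <- redness_weight(hsv$h, hsv$s, h_ref, sigma_h)
  redness_sum <- sum(pmax(w - w_bg, 0))

  if (any(mask)) {
    mh <- pixels_to_hsv(px, mask)
    mean_hue <- circular_mean_hue(mh$h, mh$s)
    mean_saturation <- mean(mh$s)
    mean_value <- mean(mh$v)
  } else {
    mean_hue <- NA_real_; mean_saturation <- NA_real_; mean_value <- NA_real_
  }
  list(mean_hue = mean_hue, mean_saturation = mean_saturation,
       mean_value = mean_value, redness_sum = redness_sum)
}

#' CPRG score of a colony measurement
#'
#' The CPRG score is the background-corrected, saturation-weighted hue-kernel
#' redness summed over the colony mask and (by default) its halo annulus, as
#' produced by [measure_color()]: an extensive quantity, zero on white
#' colonies, strictly increasing in pigment at fixed geometry, with a wide
#' dynamic range, conventionally displayed on a log10 axis ("units").
#' An optional per-plate calibration divisor supports plate-median
#' normalisation.
#'
#' @param redness_sum Redness sum `R` from [measure_color()].
#' @param plate_calibration Positive divisor (default 1 = raw scores).
#' @return Non-negative score.
#' @export
cprg_score <- function(redness_sum, plate_calibration = 1) {
  if (any(plate_calibration <= 0)) abort("`plate_calibration` must be positive")
  pmax(redness_sum, 0) / plate_calibration
}
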