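# Small 96-pin plate used by fast unit tests; 8 x 12 is a standard format so
# no non-standard-format warning is emitted.
small_spec <- function(..., seed = 42L) {
  plate_spec(rows = 8L, cols = 12L, seed = seed, ...)
}

# Analytic background field oracle, written out independently of the
# renderer: linear gradient along x times a radial vignette, quantised to
# 8-bit like the rendered image.
oracle_background <- function(spec) {
  d <- plate_dims(spec)
  h <- d[["height"]]; w <- d[["width"]]
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  y <- matrix(seq_len(h), h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  dmax2 <- (h - cy)^2 + (w - cx)^2
  bg <- (spec$background_level + spec$background_gradient * (x - cx)) *
    (1 - spec$vignette_strength * ((y - cy)^2 + (x - cx)^2) / dmax2)
  round(pmin(pmax(bg, 0), 1) * 255) / 255
}

# Brute-force per-pixel redness oracle: independent HSV conversion and
# kernel evaluation, one pixel at a time.
oracle_redness_sum <- function(px, mask, w_bg = 0, h_ref = 0, sigma_h = 20) {
  total <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j]) next
      hsv <- grDevices::rgb2hsv(px[i, j, 1], px[i, j, 2], px[i, j, 3],
                                maxColorValue = 1)
      hh <- hsv[1] * 360
      dh <- min(abs(hh - h_ref) %% 360, 360 - abs(hh - h_ref) %% 360)
      w <- hsv[2] * exp(-dh^2 / (2 * sigma_h^2))
      total <- total + max(w - w_bg, 0)
    }
  }
  total
}

# Tiny solid-colour image helper.
solid_image <- function(rgb, h = 5, w = 5) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}
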