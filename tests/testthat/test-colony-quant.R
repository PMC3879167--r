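test_that("the redness kernel is the identity on saturated red and zero on gray", {
  red <- solid_image(c(1, 0, 0))
  mask <- matrix(TRUE, 5, 5)
  mc <- measure_color(red, mask)
  expect_equal(mc$redness_sum, 25)          # w = 1 per pixel
  expect_equal(mc$mean_hue, 0)
  expect_equal(mc$mean_saturation, 1)

  gray <- solid_image(c(0.7, 0.7, 0.7))
  mc2 <- measure_color(gray, mask)
  expect_identical(mc2$redness_sum, 0)
  expect_true(is.na(mc2$mean_hue))          # achromatic: hue undefined

  expect_error(measure_color(red, matrix(FALSE, 5, 5)), "empty")
})

test_that("redness agrees with a brute-force per-pixel recomputation and orders pigment", {
  spec <- small_spec(position_jitter_sd = 0, colony_radius_sd = 0, noise_sd = 0)
  redness <- rep(0, 96); redness[c(1, 3)] <- c(0.2, 0.8)
  tr <- make_colony_truths(spec, redness = redness)
  rp <- render_plate(spec, tr, elapsed_time = 1)
  g <- fit_grid(rp$image, 8, 12)
  vals <- lapply(c(1, 3), function(i) {
    seg <- segment_colony(rp$image, g, tr$row[i], tr$col[i])
    cell <- rp$image[seg$bbox$ys, seg$bbox$xs, , drop = FALSE]
    mc <- measure_color(cell, seg$mask, background = seg$background)
    oracle <- oracle_redness_sum(cell, seg$mask)
    list(mc = mc, oracle = oracle)
  })
  expect_equal(vals[[1]]$mc$redness_sum, vals[[1]]$oracle, tolerance = 1e-9)
  expect_equal(vals[[2]]$mc$redness_sum, vals[[2]]$oracle, tolerance = 1e-9)
  expect_gt(vals[[2]]$mc$redness_sum, vals[[1]]$mc$redness_sum)
})

test_that("segmented area of a clean disc matches the pixel-count oracle within 10%", {
  spec <- small_spec(position_jitter_sd = 0, colony_radius_sd = 0, noise_sd = 0)
  tr <- make_colony_truths(spec)
  keep <- tr$row == 3 & tr$col == 5
  tr$radius[keep] <- 8
  tr$is_empty[tr$row == 0 & tr$col == 0] <- TRUE
  tr$radius[tr$row == 0 & tr$col == 0] <- 0
  rp <- render_plate(spec, tr)
  g <- fit_grid(rp$image, 8, 12)
  seg <- segment_colony(rp$image, g, 3, 5)
  expect_lte(abs(seg$area - pi * 64) / (pi * 64), 0.1)
  # oracle: count foreground pixels of the rendered image inside the cell
  bg <- oracle_background(spec)
  fg_count <- sum((rp$image[, , 1] > bg + 0.05)[seg$bbox$ys, seg$bbox$xs])
  expect_identical(as.integer(seg$area), as.integer(fg_count))
  # the emptied cell is flagged empty
  seg_empty <- segment_colony(rp$image, g, 0, 0)
  expect_identical(seg_empty$flag, "empty")
  expect_identical(seg_empty$area, 0)
})

test_that("CPRG scores are zero on a white plate and strictly increase with pigment", {
  spec <- small_spec(position_jitter_sd = 0, colony_radius_sd = 0, noise_sd = 0)
  white <- quantify_plate(render_plate(spec, make_colony_truths(spec)),
                          rows = 8, cols = 12)
  expect_true(all(white$cprg_score == 0))

  redness <- rep(0, 96); redness[1:10] <- seq(0.1, 1, by = 0.1)
  rp <- render_plate(spec, make_colony_truths(spec, redness = redness))
  m <- quantify_plate(rp, rows = 8, cols = 12)
  scored <- m[order(m$row * 12 + m$col), ][1:10, ]
  expect_true(all(diff(scored$cprg_score) > 0))
  # cross-check against brute-force sums over mask + annulus
  g <- attr(m, "grid")
  tr <- rp$truth
  for (i in c(2, 9)) {
    seg <- segment_colony(rp$image, g, tr$row[i], tr$col[i])
    cell <- rp$image[seg$bbox$ys, seg$bbox$xs, , drop = FALSE]
    r_eff <- sqrt(seg$area / pi)
    dy <- seg$bbox$ys - seg$centroid[["y"]]; dx <- seg$bbox$xs - seg$centroid[["x"]]
    dist <- sqrt(outer(dy^2, dx^2, `+`))
    hw <- attr(m, "params")$halo_width
    halo <- !seg$mask & dist > r_eff & dist <= r_eff + hw
    # background redness recomputed independently from the RGB estimate
    bh <- grDevices::rgb2hsv(seg$background[1], seg$background[2],
                             seg$background[3], maxColorValue = 1)
    dh <- min(bh[1] * 360, 360 - bh[1] * 360)
    wbg <- bh[2] * exp(-dh^2 / (2 * 20^2))
    expect_equal(scored$cprg_score[i],
                 oracle_redness_sum(cell, seg$mask | halo, w_bg = wbg),
                 tolerance = 1e-6)
  }
})

test_that("redness sums are additive over disjoint regions with shared background", {
  px <- solid_image(c(0.8, 0.3, 0.3), h = 6, w = 6)
  m1 <- matrix(FALSE, 6, 6); m1[1:3, ] <- TRUE
  m2 <- matrix(FALSE, 6, 6); m2[4:6, ] <- TRUE
  r1 <- measure_color(px, m1, background = 0.05)$redness_sum
  r2 <- measure_color(px, m2, background = 0.05)$redness_sum
  r12 <- measure_color(px, m1 | m2, background = 0.05)$redness_sum
  expect_equal(r12, r1 + r2, tolerance = 1e-12)
})

test_that("a small uniform gray offset barely changes colony scores", {
  spec <- small_spec(position_jitter_sd = 0, colony_radius_sd = 0, noise_sd = 0)
  redness <- rep(0, 96); redness[1:10] <- seq(0.2, 2, by = 0.2)
  rp <- render_plate(spec, make_colony_truths(spec, redness = redness))
  m0 <- quantify_plate(rp, rows = 8, cols = 12)
  shifted <- pmin(rp$image + 0.01, 1)
  m1 <- quantify_plate(shifted, rows = 8, cols = 12)
  s0 <- m0$cprg_score[order(m0$row * 12 + m0$col)][1:10]
  s1 <- m1$cprg_score[order(m1$row * 12 + m1$col)][1:10]
  expect_true(all(abs(s1 - s0) / s0 < 0.02))
})

test_that("quantification is equivariant under a 180-degree image rotation", {
  spec <- small_spec(noise_sd = 0.005, seed = 21)
  redness <- rep(0, 96); redness[c(5, 40, 77)] <- c(0.5, 1, 2)
  rp <- render_plate(spec, make_colony_truths(spec, redness = redness))
  m <- quantify_plate(rp, rows = 8, cols = 12)
  rot <- rp$image[dim(rp$image)[1]:1, dim(rp$image)[2]:1, ]
  mr <- quantify_plate(rot, rows = 8, cols = 12)
  mr$row <- 7L - mr$row; mr$col <- 11L - mr$col
  j <- dplyr::inner_join(m, mr, by = c("row", "col"), suffix = c("", ".rot"))
  big <- j$cprg_score > 5
  expect_true(any(big))
  expect_true(all(abs(j$cprg_score.rot[big] - j$cprg_score[big]) / j$cprg_score[big] < 0.01))
})

test_that("halo spill flags exactly the 8 neighbours of an isolated red colony", {
  spec <- small_spec(position_jitter_sd = 0, noise_sd = 0,
                     halo_diffusion_sigma_per_hour = 0.2)
  redness <- rep(0, 96)
  redness[3 * 12 + 6 + 1] <- 3   # row 3, col 6
  rp <- render_plate(spec, make_colony_truths(spec, redness = redness),
                     elapsed_time = 30)  # late: sigma = 6 px, halos reach neighbours
  m <- quantify_plate(rp, rows = 8, cols = 12)
  mf <- flag_neighbor_contamination(m, threshold = 10)
  flagged <- mf[grepl("neighbor_contaminated", mf$flags), c("row", "col")]
  expect_identical(nrow(flagged), 8L)
  expect_true(all(abs(flagged$row - 3) <= 1 & abs(flagged$col - 6) <= 1))
  # the red colony itself is not flagged
  expect_false(grepl("neighbor_contaminated",
                     mf$flags[mf$row == 3 & mf$col == 6]))
  # an all-white plate carries no contamination flags
  mw <- quantify_plate(render_plate(spec, make_colony_truths(spec)),
                       rows = 8, cols = 12)
  expect_false(any(grepl("neighbor_contaminated",
                         flag_neighbor_contamination(mw, 10)$flags)))
})
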