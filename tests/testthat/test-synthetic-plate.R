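test_that("an all-empty noiseless plate renders exactly the analytic background field", {
  spec <- small_spec(noise_sd = 0)
  tr <- make_colony_truths(spec, empty = TRUE)
  rp <- render_plate(spec, tr, elapsed_time = 10)
  bg <- oracle_background(spec)
  for (ch in 1:3) expect_equal(rp$image[, , ch], bg)
})

test_that("rendered disc pixel count matches its area and a brute-force count", {
  spec <- small_spec(position_jitter_sd = 0, colony_radius_sd = 0, noise_sd = 0)
  tr <- make_colony_truths(spec, empty = TRUE)
  tr$is_empty[tr$row == 4 & tr$col == 6] <- FALSE
  tr$radius[tr$row == 4 & tr$col == 6] <- 10
  rp <- render_plate(spec, tr, elapsed_time = 0)
  bg <- oracle_background(spec)
  rendered_fg <- rp$image[, , 1] > bg + 0.05
  expect_lt(abs(sum(rendered_fg) - pi * 10^2) / (pi * 10^2), 0.05)
  # brute-force: pixels within 10 px of the (unjittered) centre
  ctr <- tr[tr$row == 4 & tr$col == 6, ]
  d <- plate_dims(spec)
  dist <- sqrt(outer((seq_len(d[["height"]]) - ctr$center_y)^2,
                     (seq_len(d[["width"]]) - ctr$center_x)^2, `+`))
  expect_identical(sum(rendered_fg), sum(dist <= 10))
})

test_that("the default plate format is 384 positions (16 x 24) with deterministic dimensions", {
  spec <- plate_spec()
  expect_identical(spec$rows * spec$cols, 384L)
  rmax <- ceiling(spec$colony_radius_mean + 4 * spec$colony_radius_sd)
  expect_identical(plate_dims(spec)[["height"]],
                   as.integer(2 * spec$margin + spec$pin_spacing * 15 + 2 * rmax))
  expect_warning(plate_spec(rows = 5, cols = 5), "non-standard")
})

test_that("rendering is bit-identical for identical seeds and truths", {
  spec <- small_spec(seed = 9)
  tr <- make_colony_truths(spec, redness = 0.5)
  a <- render_plate(spec, tr, elapsed_time = 12)
  b <- render_plate(spec, tr, elapsed_time = 12)
  expect_identical(a$image, b$image)
  expect_identical(make_colony_truths(spec, redness = 0.5), tr)
})

test_that("with zero jitter, truth centres equal the analytic pin positions", {
  spec <- small_spec(position_jitter_sd = 0)
  tr <- make_colony_truths(spec)
  pc <- chromopin:::pin_centers(spec)
  expect_equal(tr$center_y, pc$y[tr$row + 1], tolerance = 1e-12)
  expect_equal(tr$center_x, pc$x[tr$col + 1], tolerance = 1e-12)
})

test_that("mean rendered colony saturation is strictly increasing in planted redness", {
  spec <- small_spec(position_jitter_sd = 0, colony_radius_sd = 0, noise_sd = 0)
  redness <- rep(0, 96)
  redness[1:10] <- seq(0.1, 1, by = 0.1)
  tr <- make_colony_truths(spec, redness = redness)
  rp <- render_plate(spec, tr, elapsed_time = 1)
  sat <- vapply(1:10, function(i) {
    ctr <- tr[i, ]
    ys <- round(ctr$center_y + (-4:4)); xs <- round(ctr$center_x + (-4:4))
    cell <- rp$image[ys, xs, ]
    s <- 1 - pmin(cell[, , 2], cell[, , 3]) / pmax(cell[, , 1], 1e-9)
    mean(s)
  }, numeric(1))
  expect_true(all(diff(sat) > 0))
})

test_that("truth positions outside the grid are rejected by name and overlaps warn", {
  spec <- small_spec()
  tr <- make_colony_truths(spec)
  bad <- tr
  bad$row[1] <- 8L
  expect_error(render_plate(spec, bad), "\\(8,0\\)")
  two <- tr[1:2, ]
  two$center_x <- c(30, 33)
  two$center_y <- c(30, 30)
  two$radius <- c(6, 6)
  expect_warning(render_plate(spec, two), "max-blend")
})

test_that("colony-size simulation is deterministic, degenerate at zero noise, and unbiased for neutral genes", {
  genes <- sprintf("g%03d", 1:50)
  spec0 <- gi_sim_spec(base_size = 400, plate_effect_sd = 0, noise_sd = 0, seed = 5)
  sim0 <- simulate_colony_sizes(spec0, genes)
  expect_true(all(sim0$sizes$size == 400))
  expect_identical(simulate_colony_sizes(spec0, genes), sim0)

  # neutral-gene mean converges to base_size: 1000 replicates, 3-SE band
  spec1 <- gi_sim_spec(base_size = 400, plate_effect_sd = 0, noise_sd = 0.1,
                       replicates = 1000L, seed = 7)
  sim1 <- simulate_colony_sizes(spec1, "neutral")
  mu <- mean(sim1$sizes$size)
  se <- stats::sd(sim1$sizes$size) / sqrt(1000)
  # lognormal noise: E[size] = base * exp(sd^2/2)
  expect_lt(abs(mu - 400 * exp(0.1^2 / 2)), 3 * se)
  expect_error(simulate_colony_sizes(spec1, character()), "non-empty")
})

test_that("planted CPRG+ counts behave like binomial draws (resampling oracle)", {
  n <- 384
  counts <- vapply(1:20, function(sd) {
    tr <- make_screen_truth(sprintf("m%03d", 1:n), conditions = "c1",
                            cprg_fraction = 0.02, seed = sd)
    sum(tr$true_class == "CPRG+")
  }, numeric(1))
  expect_equal(mean(counts), n * 0.02, tolerance = 0.35)
  # resampling oracle: direct binomial draws bound the plausible range
  set.seed(99)
  ref <- stats::rbinom(20000, n, 0.02)
  expect_true(all(counts >= min(ref) & counts <= max(ref)))
})
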