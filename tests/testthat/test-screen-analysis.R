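make_meas <- function(mutant_id, condition, score, flags = "") {
  tibble::tibble(mutant_id = mutant_id, condition = condition,
                 cprg_score = score, flags = flags)
}

test_that("replicate averaging is the arithmetic clone mean, order-invariant, oracle-checked", {
  m <- make_meas(c("mA", "mA"), "c1", c(1000, 3000))
  s <- average_replicates(m)
  expect_equal(s$score, 2000)
  expect_identical(s$n_clones, 2L)
  expect_equal(average_replicates(m[2:1, ])$score, 2000)

  # random fixture vs independent group-by oracle
  set.seed(4)
  big <- make_meas(rep(sprintf("m%03d", 1:192), each = 2),
                   rep(c("c1", "c2"), each = 192), stats::rexp(384, 1 / 50))
  s2 <- average_replicates(big)
  oracle <- tapply(big$cprg_score, paste(big$mutant_id, big$condition, sep = "\r"), mean)
  expect_equal(s2$score[match(names(oracle),
                              paste(s2$mutant_id, s2$condition, sep = "\r"))],
               as.numeric(oracle))

  # single available clone: averaged over one and flagged
  s3 <- average_replicates(make_meas("mB", "c1", 500))
  expect_equal(s3$score, 500)
  expect_match(s3$flags, "single_clone_pos")
})

test_that("hit calling is strict and monotone in the threshold", {
  s <- tibble::tibble(mutant_id = sprintf("m%d", 1:6), condition = "c1",
                      score = c(10, 100, 1000, 5000, 5011.87, 20000))
  expect_identical(sum(call_hits(s, 1e6)$is_hit), 0L)
  # strict ">": a score exactly at the cut-off is not a hit
  expect_false(call_hits(s, 5011.87)$is_hit[5])
  taus <- c(5, 50, 500, 5000, 50000)
  hit_sets <- lapply(taus, function(t) s$mutant_id[call_hits(s, t)$is_hit])
  for (i in seq_len(length(taus) - 1)) {
    expect_true(all(hit_sets[[i + 1]] %in% hit_sets[[i]]))
  }
  # contaminated rows are excluded before calling
  s$flags <- c("", "", "neighbor_contaminated", "", "", "")
  expect_false("m3" %in% call_hits(s, 500)$mutant_id)
})

test_that("condition comparison enumerates membership classes exactly", {
  h <- function(mut, cond, hit = TRUE) {
    tibble::tibble(mutant_id = mut, condition = cond, score = 1,
                   threshold = 0.5, is_hit = hit)
  }
  same <- dplyr::bind_rows(h(c("a", "b"), "c1"), h(c("a", "b"), "c2"))
  expect_equal(compare_conditions(same)$condition_specific_fraction, 0)
  disj <- dplyr::bind_rows(h("a", "c1"), h("b", "c2"))
  expect_equal(compare_conditions(disj)$condition_specific_fraction, 1)

  # random 100 mutants x 4 conditions vs exhaustive enumeration oracle
  set.seed(8)
  conds <- cprg_conditions()
  calls <- tidyr::expand_grid(mutant_id = sprintf("m%03d", 1:100),
                              condition = conds) |>
    dplyr::mutate(score = 1, threshold = 0.5, is_hit = stats::runif(400) < 0.3)
  cmp <- compare_conditions(calls)
  expect_identical(nrow(cmp$classes), 15L)
  # oracle: per-mutant membership patterns by explicit loops
  sizes <- integer(0)
  for (i in seq_len(nrow(cmp$classes))) {
    cls <- strsplit(cmp$classes$conditions[i], " & ", fixed = TRUE)[[1]]
    n <- 0L
    for (mu in unique(calls$mutant_id)) {
      got <- sort(calls$condition[calls$mutant_id == mu & calls$is_hit])
      if (identical(got, sort(cls))) n <- n + 1L
    }
    sizes <- c(sizes, n)
  }
  expect_identical(cmp$classes$size, sizes)
  expect_identical(sum(cmp$classes$size), cmp$union_size)
  expect_equal(cmp$condition_specific_fraction,
               sum(cmp$classes$size[cmp$classes$n_conditions == 1]) / cmp$union_size)
  expect_identical(nrow(tidy(cmp)), 15L)
  expect_identical(glance(cmp)$union_size, cmp$union_size)
})

test_that("hypergeometric enrichment matches exhaustive combinatorial enumeration", {
  universe <- sprintf("g%02d", 1:10)
  ann <- tibble::tibble(gene = universe[1:4], term = "T")
  hits <- universe[c(1, 2, 3)]       # k = 3 of K = 4 annotated, n = 3
  res <- enrich_terms(hits, universe, ann)
  expect_equal(res$p, 4 / 120)
  # oracle: enumerate all C(10,3) draws and count those with >= 3 annotated
  draws <- utils::combn(universe, 3, simplify = FALSE)
  p_oracle <- mean(vapply(draws, function(d) sum(d %in% universe[1:4]) >= 3, logical(1)))
  expect_equal(res$p, p_oracle)
  expect_equal(res$q, res$p)          # single term: q = p

  # hits = universe forces k = K and p = 1
  res_all <- enrich_terms(universe, universe, ann)
  expect_identical(res_all$k, res_all$K)
  expect_equal(res_all$p, 1)

  # BH q-values are nondecreasing in p rank and >= p
  set.seed(3)
  ann2 <- tibble::tibble(gene = sample(universe, 40, replace = TRUE),
                         term = rep(sprintf("t%d", 1:8), each = 5))
  res2 <- enrich_terms(universe[1:4], universe, ann2)
  expect_true(all(res2$q >= res2$p))
  expect_true(all(diff(res2$q[order(res2$p)]) >= -1e-12))

  expect_error(enrich_terms(c("gX"), universe, ann), "not in universe")
})

test_that("timepoint selection prefers the earliest grown image and falls back with warning", {
  m <- tibble::tibble(timepoint = rep(c(12, 23), each = 10),
                      mask_area = c(rep(50, 10), rep(60, 10)))
  expect_identical(select_timepoint(m), 12)
  expect_identical(select_timepoint(m[m$timepoint == 23, ]), 23)
  ungrown <- tibble::tibble(timepoint = rep(c(6, 9), each = 10),
                            mask_area = rep(c(0, 5), 10))
  expect_warning(tp <- select_timepoint(ungrown), "last")
  expect_identical(tp, 9)
})

test_that("simulated pigment grows linearly with incubation time", {
  spec <- small_spec(seed = 12)
  layout <- make_screen_layout(sprintf("mut%02d", 1:48), rows = 8, cols = 12)
  truth <- make_screen_truth(sprintf("mut%02d", 1:48), conditions = "c1",
                             cprg_fraction = 0.1, seed = 12)
  sim <- simulate_screen(layout, truth, timepoints = c(12, 23), spec = spec)
  t1 <- sim$truth[[which(sim$timepoint == 12)[1]]]
  t2 <- sim$truth[[which(sim$timepoint == 23)[1]]]
  pos <- t1$redness_true > 0
  expect_true(any(pos))
  expect_equal(t2$redness_true[pos] / t1$redness_true[pos],
               rep(23 / 12, sum(pos)))
  # geometry is shared across timepoints
  expect_identical(t1$center_x, t2$center_x)
  expect_error(simulate_screen(layout, truth, timepoints = c(12, 12), spec = spec),
               "strictly increasing")
  bad_truth <- truth
  bad_truth$mutant_id[1] <- "phantom"
  expect_error(simulate_screen(layout, bad_truth, spec = spec), "phantom")
})

test_that("the paper-scale synthetic score reader round-trips a condition tab", {
  st <- simulate_score_table(n_mutants = 200, seed = 5)
  one <- st[st$condition == "30 LB0", c("mutant_id", "score")]
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(one, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_score_table(path, "30 LB0")
  expect_equal(back$score, one$score)
  expect_identical(back$condition[1], "30 LB0")
})
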