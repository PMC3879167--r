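#' Plant ground-truth CPRG classes for a simulated screen
#'
#' Assigns each mutant a CPRG class per condition. Per condition, each mutant
#' is CPRG+ with probability `cprg_fraction` (so per-condition hit counts are
#' Binomial); cross-condition membership is structured so that an expected
#' `specific_fraction` of the union of hits is positive in exactly one
#' condition, emulating the strong condition specificity of
#' temperature-by-salt envelope screens. Each CPRG+ mutant carries one effect
#' size (redness accumulated per hour of incubation), shared across its
#' positive conditions.
#'
#' @param mutant_ids Character vector of mutant identifiers.
#' @param conditions Condition labels (default [cprg_conditions()]).
#' @param cprg_fraction Per-condition probability that a mutant is CPRG+.
#' @param specific_fraction Expected fraction of union hits positive in
#'   exactly one condition (default 0.75).
#' @param effect_size_range Log-uniform range for the per-mutant effect size
#'   (redness units per hour).
#' @param seed Integer seed.
#' @return A tibble with one row per mutant x condition: `mutant_id`,
#'   `condition`, `true_class` (`"CPRG+"`/`"CPRG-"`), `effect_size` (0 for
#'   CPRG-).
#' @export
make_screen_truth <- function(mutant_ids, conditions = cprg_conditions(),
                              cprg_fraction = 0.02, specific_fraction = 0.75,
                              effect_size_range = c(0.04, 0.12), seed = 1L) {
  k <- length(conditions)
  n <- length(mutant_ids)
  withr::with_seed(derive_seed(seed, "screen-truth"), {
    slots <- stats::rbinom(k, n, cprg_fraction)
    members <- list()
    pool <- sample(mutant_ids)
    while (sum(slots) > 0 && length(pool) > 0) {
      open <- which(slots > 0)
      m <- if (length(open) == 1L || stats::runif(1) < specific_fraction) 1L else {
        sizes <- 2:length(open)
        if (length(sizes) == 1L) sizes else sample(sizes, 1L, prob = 0.5^sizes)
      }
      m <- min(m, length(open))
      conds <- if (length(open) == 1L) open else sample(open, m, prob = slots[open])
      members[[pool[1]]] <- conditions[conds]
      pool <- pool[-1]
      slots[conds] <- slots[conds] - 1L
    }
    effect <- exp(stats::runif(length(members),
                               log(effect_size_range[1]), log(effect_size_range[2])))
    names(effect) <- names(members)
  })
  tidyr::expand_grid(mutant_id = mutant_ids, condition = conditions) |>
    dplyr::mutate(
      true_class = ifelse(purrr::map2_lgl(.data$mutant_id, .data$condition,
                                          ~ .y %in% (members[[.x]] %||% character())),
                          "CPRG+", "CPRG-"),
      effect_size = ifelse(.data$true_class == "CPRG+",
                           unname(effect[.data$mutant_id]), 0)
    )
}

#' Simulate a multi-condition, multi-timepoint screen as plate images
#'
#' Renders one image per plate per condition per timepoint. The redness of a
#' CPRG+ colony at elapsed time `t` is `effect_size * t` (pigment accumulation
#' directly proportional to incubation time); CPRG- colonies stay white.
#' Colony geometry (centres, radii) is drawn once per plate-condition pair and
#' shared across timepoints, so only colour and halo width change with time.
#'
#' @param layout A `plate_layout` (shared across conditions) from
#'   [make_screen_layout()] or [read_layout()].
#' @param truth Screen truth from [make_screen_truth()]; every mutant named
#'   there must appear in `layout`.
#' @param timepoints Strictly increasing imaging times in hours (default
#'   `c(12, 23)`, the early/late acquisition pair of the screen design).
#' @param spec A [plate_spec()].
#' @param out_dir Optional directory; when given, each image is written as
#'   PNG + JSON sidecar, each truth table as TSV, and the simulation
#'   configuration is echoed to `config.json`.
#' @return A tibble manifest with one row per image: `condition`, `plate`,
#'   `timepoint`, `render` (list-column of `plate_render`), `truth`
#'   (list-column of per-plate truth tables joined to layout), and `path`
#'   (PNG path or `NA`).
#' @export
simulate_screen <- function(layout, truth, timepoints = c(12, 23), spec = plate_spec(),
                            out_dir = NULL) {
  if (any(diff(timepoints) <= 0)) abort("`timepoints` must be strictly increasing")
  conditions <- unique(truth$condition)
  missing_m <- setdiff(unique(truth$mutant_id), layout$mutant_id)
  if (length(missing_m)) {
    abort(sprintf("mutants in truth but absent from layout: %s",
                  paste(utils::head(missing_m, 10), collapse = ", ")))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- c(unclass(spec), list(timepoints = timepoints, conditions = conditions))
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = 10)
  }
  plates <- unique(layout$plate)
  grid <- tidyr::expand_grid(condition = conditions, plate = plates,
                             timepoint = timepoints)
  out <- purrr::pmap(grid, function(condition, plate, timepoint) {
    lp <- layout[layout$plate == plate, ]
    lp <- lp[order(lp$row * attr(layout, "cols") %||% max(lp$col + 1L) + lp$col), ]
    eff <- truth$effect_size[truth$condition == condition][
      match(lp$mutant_id, truth$mutant_id[truth$condition == condition])]
    eff[is.na(eff)] <- 0
    truths <- make_colony_truths(
      spec,
      redness = eff * timepoint,
      mutant_id = ifelse(lp$is_empty, "", lp$mutant_id),
      empty = lp$is_empty,
      plate_id = paste(condition, plate)
    )
    truths$clone_index <- lp$clone_index
    rp <- render_plate(spec, truths, elapsed_time = timepoint,
                       plate_id = paste(condition, plate))
    path <- NA_character_
    if (!is.null(out_dir)) {
      stem <- sprintf("%s_%s_t%gh", plate, condition, timepoint)
      path <- file.path(out_dir, paste0(stem, ".png"))
      write_plate_image(plate_image(rp$image, plate_id = plate,
                                    condition = condition, timepoint = timepoint),
                        path)
      tt <- dplyr::mutate(truths, plate = plate, condition = condition,
                          timepoint = timepoint, .before = 1)
      utils::write.table(as.data.frame(tt), file.path(out_dir, paste0(stem, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(render = rp, truth = truths, path = path)
  })
  grid$render <- purrr::map(out, "render")
  grid$truth <- purrr::map(out, "truth")
  grid$path <- purrr::map_chr(out, "path")
  grid
}

#' Simulate a paper-scale screen score table (synthetic stand-in)
#'
#' Generates replicate-averaged CPRG score tables at the scale and shape of a
#' full ordered-library screen, without rendering images: a log-normal bulk of
#' low scores for CPRG- mutants and a heavy right tail above the hit cut-off
#' for CPRG+ mutants, with per-condition hit counts and ~75% condition
#' specificity emulating the published screen composition. This is a synthetic
#' stand-in for the screen's supplementary score spreadsheet, for exercising
#' hit counting and cross-condition comparison at realistic scale.
#'
#' @param n_mutants Library size (default 3985, an ordered single-gene
#'   deletion library).
#' @param conditions Condition labels.
#' @param hits_per_condition Two-element range; each condition's planted hit
#'   count is drawn uniformly from it (default `c(120, 200)`).
#' @param specific_fraction Expected condition-specific fraction of union hits.
#' @param log10_cutoff Hit cut-off on the log10 score scale (default 3.7).
#' @param bulk_meanlog10,bulk_sdlog10 Location/scale of the log10-normal bulk.
#' @param seed Integer seed.
#' @return Tibble `mutant_id, condition, score, true_class`.
#' @export
simulate_score_table <- function(n_mutants = 3985L, conditions = cprg_conditions(),
                                 hits_per_condition = c(120L, 200L),
                                 specific_fraction = 0.75,
                                 log10_cutoff = 3.7,
                                 bulk_meanlog10 = 2.2, bulk_sdlog10 = 0.4,
                                 seed = 1L) {
  mutant_ids <- sprintf("g%04d", seq_len(n_mutants))
  withr::with_seed(derive_seed(seed, "score-table"), {
    counts <- sample(hits_per_condition[1]:hits_per_condition[2], length(conditions),
                     replace = TRUE)
    truth <- make_screen_truth(mutant_ids, conditions,
                               cprg_fraction = mean(counts) / n_mutants,
                               specific_fraction = specific_fraction,
                               seed = derive_seed(seed, "score-table-truth"))
    n <- nrow(truth)
    bulk <- 10^stats::rnorm(n, bulk_meanlog10, bulk_sdlog10)
    bulk <- pmin(bulk, 10^(log10_cutoff - 0.05))           # bulk stays below cut-off
    tail <- 10^(log10_cutoff + 0.05 + stats::rexp(n, rate = 2.5))
    truth$score <- ifelse(truth$true_class == "CPRG+", tail, bulk)
  })
  truth[, c("mutant_id", "condition", "score", "true_class")]
}

#' Read a per-condition score table (TSV export of a score spreadsheet tab)
#'
#' Reads a two-column (gene, score) tab-separated table such as a TSV export
#' of one condition tab of a screen score spreadsheet, returning the long
#' format used by [call_hits()].
#'
#' @param path TSV path; first column gene/mutant id, second column average
#'   CPRG score. A header row is detected and skipped when the second field is
#'   non-numeric.
#' @param condition Condition label to attach.
#' @return Tibble `mutant_id, condition, score`.
#' @export
read_score_table <- function(path, condition) {
  first <- utils::read.delim(path, sep = "\t", header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  has_header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  df <- utils::read.delim(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  tibble(mutant_id = as.character(df[[1]]), condition = condition,
         score = as.numeric(df[[2]]))
}
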