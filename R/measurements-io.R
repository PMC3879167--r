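# Column order of the measurement TSV; kept stable so files diff cleanly.
measurement_columns <- c(
  "plate", "condition", "timepoint", "row", "col", "mutant_id", "clone_index",
  "center_y", "center_x", "mask_area", "mean_hue", "mean_saturation",
  "mean_value", "redness_sum", "cprg_score", "size_score",
  paste0("halo_", c("E", "SE", "S", "SW", "W", "NW", "N", "NE")),
  "flags"
)

provenance_digest <- function(params) {
  fnv1a_hex(jsonlite::toJSON(params[order(names(params))], auto_unbox = TRUE, digits = 10))
}

#' Write a colony measurement table
#'
#' Writes the per-colony measurement table as TSV with a stable column order
#' and `#`-prefixed header comments carrying the source image id, package
#' version and a digest of the quantification parameters, so a measurement
#' file is traceable to the exact configuration that produced it. Re-reading
#' with [read_measurements()] round-trips the table exactly.
#'
#' @param measurements Measurement tibble from [quantify_plate()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  params <- attr(measurements, "params") %||% list()
  source_image <- attr(measurements, "source_image") %||% NA_character_
  header <- c(
    sprintf("# chromopin measurements v%s", as.character(utils::packageVersion("chromopin"))),
    sprintf("# source_image: %s", source_image),
    sprintf("# params_digest: %s", provenance_digest(params)),
    sprintf("# params: %s", jsonlite::toJSON(params, auto_unbox = TRUE, digits = 10))
  )
  cols <- intersect(measurement_columns, names(measurements))
  cols <- c(cols, setdiff(names(measurements), cols))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(measurements)[cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a colony measurement table written by [write_measurements()]
#'
#' @param path Path to a measurement TSV.
#' @return Measurement tibble; provenance (source image, parameter digest)
#'   is attached as attributes `source_image` and `params_digest`.
#' @export
read_measurements <- function(path) {
  head_lines <- readLines(path, n = 10L)
  meta <- head_lines[startsWith(head_lines, "#")]
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  out <- as_tibble(df)
  if ("flags" %in% names(out)) {
    out$flags <- as.character(out$flags)
    out$flags[is.na(out$flags)] <- ""
  }
  if ("mutant_id" %in% names(out)) out$mutant_id <- as.character(out$mutant_id)
  if ("condition" %in% names(out)) out$condition <- as.character(out$condition)
  if ("plate" %in% names(out)) out$plate <- as.character(out$plate)
  if ("clone_index" %in% names(out)) out$clone_index <- as.integer(out$clone_index)
  grab <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NA_character_
  }
  attr(out, "source_image") <- grab("source_image")
  attr(out, "params_digest") <- grab("params_digest")
  out
}
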