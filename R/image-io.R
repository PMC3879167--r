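#' Construct a plate image object
#'
#' @param pixels Height x width x 3 numeric array on a 0-1 scale (8-bit sRGB
#'   semantics).
#' @param plate_id Plate identifier.
#' @param condition Growth-condition label (free string; see
#'   [cprg_conditions()] for the default screen set).
#' @param timepoint Incubation time at acquisition, hours.
#' @param acquisition_tag Free-text acquisition note.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, plate_id = "p1", condition = NA_character_,
                        timepoint = NA_real_, acquisition_tag = "") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be a height x width x 3 RGB array")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) abort("image must be at least 1 x 1")
  structure(list(pixels = pixels, plate_id = plate_id, condition = condition,
                 timepoint = timepoint, acquisition_tag = acquisition_tag),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %s [%s, t = %s h]: %d x %d px\n",
              x$plate_id, x$condition %||% NA, format(x$timepoint),
              dim(x$pixels)[1], dim(x$pixels)[2]))
  invisible(x)
}

# Filename convention `plateID_condition_tXXh.(png|tif)`; condition may
# contain spaces but not underscores.
parse_image_filename <- function(path) {
  base <- sub("\\.(png|tif|tiff)$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(base, regexec("^([^_]+)_(.+)_t([0-9.]+)h$", base))[[1]]
  if (length(m) == 4L) {
    list(plate_id = m[2], condition = m[3], timepoint = as.numeric(m[4]))
  } else {
    list(plate_id = base, condition = NA_character_, timepoint = NA_real_)
  }
}

#' Read a plate photograph
#'
#' Reads an 8-bit RGB PNG or TIFF. RGBA input has its alpha channel dropped
#' with a warning; grayscale input is rejected because hue is undefined.
#' Acquisition metadata is taken from a JSON sidecar `<path>.json` when
#' present, otherwise parsed from the filename pattern
#' `plateID_condition_tXXh`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [plate_image()].
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read image: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) abort("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format: .%s (PNG or TIFF expected)", ext))
  )
  if (length(dim(px)) == 2L || dim(px)[3] == 1L) {
    abort("grayscale image: hue is undefined, an RGB plate photograph is required")
  }
  if (dim(px)[3] == 4L) {
    warn("RGBA image: dropping alpha channel")
    px <- px[, , 1:3, drop = FALSE]
  }
  if (dim(px)[3] != 3L) abort(sprintf("unsupported channel count: %d", dim(px)[3]))

  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    parse_image_filename(path)
  }
  plate_image(px,
              plate_id = meta$plate_id %||% basename(path),
              condition = meta$condition %||% NA_character_,
              timepoint = as.numeric(meta$timepoint %||% NA_real_),
              acquisition_tag = meta$acquisition_tag %||% "")
}

#' Write a plate image as 8-bit PNG plus JSON metadata sidecar
#'
#' @param image A [plate_image()] or `plate_render`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(image, path) {
  if (inherits(image, "plate_render")) {
    image <- plate_image(image$image, plate_id = image$plate_id,
                         timepoint = image$elapsed_time)
  }
  png::writePNG(image$pixels, path)
  jsonlite::write_json(
    list(plate_id = image$plate_id, condition = image$condition,
         timepoint = image$timepoint, acquisition_tag = image$acquisition_tag),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}
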