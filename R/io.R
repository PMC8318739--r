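#' Read a grayscale PNG or TIFF image
#'
#' Reads a single-channel grayscale image into a `gray_image`. The
#' number of gray levels is inferred from the stored bit depth (8-bit
#' gives `H = 256`, 16-bit `H = 65536`). Multi-channel (RGB/RGBA) files
#' are rejected rather than silently converted.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A `gray_image`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L)
      stop(sprintf("%s has %d channels; only single-channel grayscale is supported",
                   path, dim(arr)[3L]))
    # readPNG scales to [0, 1]; recover the integer code at 8- or 16-bit
    px8 <- arr * 255
    if (max(abs(px8 - round(px8))) < 1e-6) {
      pix <- round(px8); h <- 256L
    } else {
      px16 <- arr * 65535
      if (max(abs(px16 - round(px16))) < 1e-3) {
        pix <- round(px16); h <- 65536L
      } else stop(sprintf("%s: unsupported PNG bit depth", path))
    }
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(arr)) == 3L)
      stop(sprintf("%s has %d channels; only single-channel grayscale is supported",
                   path, dim(arr)[3L]))
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(arr) > 255) 16L else 8L
    if (!bits %in% c(8L, 16L))
      stop(sprintf("%s: unsupported TIFF bit depth %d", path, bits))
    pix <- arr; h <- 2L^bits
  } else stop(sprintf("unsupported image format: .%s (use PNG or TIFF)", ext))
  gray_image(matrix(as.integer(pix), nrow(pix), ncol(pix)), levels = h)
}

#' Write a grayscale image or binary mask
#'
#' `write_gray_image()` writes a `gray_image` as 8-bit grayscale PNG
#' (or 8/16-bit TIFF by extension). `write_mask()` writes a binary mask
#' as an 8-bit PNG with values 0 and 255.
#'
#' @param image A `gray_image`.
#' @param path Output path; format chosen by extension.
#' @return The path, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  h <- gray_levels(image)
  scaled <- unclass(image) / (h - 1L)
  attr(scaled, "levels") <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = if (h > 256) 16L else 8L)
  } else stop(sprintf("unsupported image format: .%s", ext))
  invisible(path)
}

#' @rdname write_gray_image
#' @param mask A `binary_mask` (0/1 matrix).
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask == 1L), nrow(mask), ncol(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Parses `key = value` lines (`#` comments and blank lines ignored)
#' into a named list, with numeric-looking values converted to numbers.
#' The same format serves [fa_config_from_file] and
#' [phantom_spec_from_file], and its keys mirror the CLI flags.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop(sprintf("malformed config line: '%s' (expected key = value)", ln))
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Load an optimizer configuration from a key-value file
#'
#' Recognized keys: `population`, `sparks`, `amplitude`, `a`, `b`,
#' `gaussian_sparks`, `iterations`, `seed`. Missing keys keep the
#' [fa_config] defaults.
#'
#' @param path Path to the config file.
#' @return An `fa_config`.
#' @export
fa_config_from_file <- function(path) {
  kv <- read_config(path)
  args <- list()
  map <- c(population = "n", sparks = "sparks", amplitude = "amplitude",
           a = "a", b = "b", gaussian_sparks = "gaussian_sparks",
           iterations = "iterations", seed = "seed")
  for (key in names(map))
    if (!is.null(kv[[key]])) args[[map[[key]]]] <- kv[[key]]
  do.call(fa_config, args)
}

#' Load a phantom specification from a key-value file
#'
#' Recognized keys: `width`, `height`, `background`, `parenchyma`,
#' `lesion`, `liver_center_row`, `liver_center_col`, `liver_axis_row`,
#' `liver_axis_col`, `lesion_center_row`, `lesion_center_col`,
#' `lesion_radius`, `noise`, `noise_level`, `truth`, `seed`. Missing
#' keys keep the [phantom_spec] defaults.
#'
#' @param path Path to the config file.
#' @return A `phantom_spec`.
#' @export
phantom_spec_from_file <- function(path) {
  kv <- read_config(path)
  args <- list()
  for (key in c("width", "height", "background", "parenchyma", "lesion",
                "lesion_radius", "noise", "noise_level", "truth", "seed"))
    if (!is.null(kv[[key]])) args[[key]] <- kv[[key]]
  if (!is.null(kv$liver_center_row))
    args$liver_center <- c(kv$liver_center_row, kv$liver_center_col)
  if (!is.null(kv$liver_axis_row))
    args$liver_axes <- c(kv$liver_axis_row, kv$liver_axis_col)
  if (!is.null(kv$lesion_center_row))
    args$lesion_center <- c(kv$lesion_center_row, kv$lesion_center_col)
  do.call(phantom_spec, args)
}
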