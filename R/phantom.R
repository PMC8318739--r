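#' Synthetic liver-phantom specification
#'
#' Recipe for a synthetic liver-like grayscale test image: a dark
#' background, an elliptical organ ("parenchyma") and a bright circular
#' lesion inside it, with an optional noise model. The phantom stands in
#' for clinical abdominal MRI when exercising threshold segmentation: its
#' histogram is trimodal with the three region means, which is the
#' bimodal/multimodal gray-level structure histogram thresholding
#' assumes. Mean gray values must be strictly ordered
#' background < parenchyma < lesion, the lesion disk must lie fully
#' inside the liver ellipse, and the ellipse fully inside the frame.
#'
#' @param width,height Image size `q x p` in pixels (default 256 x 256).
#' @param background,parenchyma,lesion Mean gray values of the three
#'   regions (defaults 30, 110, 200 on the 8-bit scale).
#' @param liver_center,liver_axes Center `(row, col)` and semi-axes
#'   `(row, col)` of the liver ellipse. Defaults scale with the frame
#'   (semi-axes 80 x 96 on the default 256 x 256 frame).
#' @param lesion_center,lesion_radius Center `(row, col)` and radius of
#'   the lesion disk; defaults scale with the frame (radius 20 at
#'   256 x 256).
#' @param noise Noise model: `"none"`, `"gaussian"` (additive, sd =
#'   `noise_level`) or `"salt_pepper"` (a fraction `noise_level` of
#'   pixels forced to 0 or `H - 1`).
#' @param noise_level Noise strength: Gaussian sd in gray levels, or the
#'   salt-and-pepper corruption fraction in `[0, 1]`.
#' @param truth Which region the ground-truth mask labels as foreground:
#'   `"organ"` (liver plus lesion, matching binary thresholding) or
#'   `"lesion"` (lesion only, for three-class experiments).
#' @param levels Number of gray levels `H` (default 256).
#' @param seed Integer seed making image and mask reproducible.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width = 256L, height = 256L,
                         background = 30, parenchyma = 110, lesion = 200,
                         liver_center = c(height / 2, width / 2),
                         liver_axes = c(0.3125 * height, 0.375 * width),
                         lesion_center = liver_center +
                           c(-0.06 * height, 0.1 * width),
                         lesion_radius = 0.078125 * min(width, height),
                         noise = c("none", "gaussian", "salt_pepper"),
                         noise_level = 0, truth = c("organ", "lesion"),
                         levels = 256L, seed = NULL) {
  noise <- match.arg(noise)
  truth <- match.arg(truth)
  spec <- list(width = as.integer(width), height = as.integer(height),
               background = background, parenchyma = parenchyma,
               lesion = lesion, liver_center = as.numeric(liver_center),
               liver_axes = as.numeric(liver_axes),
               lesion_center = as.numeric(lesion_center),
               lesion_radius = as.numeric(lesion_radius),
               noise = noise, noise_level = as.numeric(noise_level),
               truth = truth, levels = as.integer(levels),
               seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$width < 8L || s$height < 8L)
    stop("phantom_spec: image must be at least 8 x 8")
  if (!(s$background < s$parenchyma && s$parenchyma < s$lesion))
    stop("phantom_spec: need background < parenchyma < lesion mean gray")
  if (any(c(s$background, s$lesion) < 0) || s$lesion > s$levels - 1L)
    stop("phantom_spec: region means must lie in [0, H - 1]")
  if (s$noise == "gaussian" && s$noise_level < 0)
    stop("phantom_spec: Gaussian noise sd must be >= 0")
  if (s$noise == "salt_pepper" &&
      (s$noise_level < 0 || s$noise_level > 1))
    stop("phantom_spec: salt-and-pepper fraction must lie in [0, 1]")
  geom <- phantom_geometry(s)
  if (any(geom$liver & !geom$frame_ok))
    stop("phantom_spec: liver ellipse extends outside the frame")
  if (any(geom$lesion & !geom$liver))
    stop("phantom_spec: lesion disk extends outside the liver ellipse")
  invisible(s)
}

# Rasterized region membership: liver ellipse and lesion disk on the
# pixel grid, plus an interior-frame indicator used for containment.
phantom_geometry <- function(s) {
  rows <- matrix(seq_len(s$height), s$height, s$width)
  cols <- matrix(seq_len(s$width), s$height, s$width, byrow = TRUE)
  liver <- ((rows - s$liver_center[1]) / s$liver_axes[1])^2 +
    ((cols - s$liver_center[2]) / s$liver_axes[2])^2 <= 1
  lesion <- (rows - s$lesion_center[1])^2 + (cols - s$lesion_center[2])^2 <=
    s$lesion_radius^2
  frame_ok <- rows > 1 & rows < s$height & cols > 1 & cols < s$width
  list(liver = liver, lesion = lesion, frame_ok = frame_ok)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d x %d, means %g/%g/%g, ",
                     "noise = %s(%g), truth = %s\n"),
              x$height, x$width, x$background, x$parenchyma, x$lesion,
              x$noise, x$noise_level, x$truth))
  invisible(x)
}

#' Generate a phantom image with its ground-truth mask
#'
#' Paints the three region means onto the pixel grid (background, liver
#' ellipse, lesion disk), derives the ground-truth mask from the clean
#' geometry, then applies the spec's noise model. The truth mask is thus
#' always noise-free. With a seed set, image and mask are bit-identical
#' across calls.
#'
#' @param spec A [phantom_spec].
#' @return List with `image` (a `gray_image`), `truth` (a
#'   `binary_mask`), and `clean` (the noise-free `gray_image`).
#' @examples
#' ph <- generate_phantom(phantom_spec(width = 64, height = 64, seed = 1))
#' table(ph$truth)
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  pix <- matrix(round(spec$background), spec$height, spec$width)
  pix[geom$liver] <- round(spec$parenchyma)
  pix[geom$lesion] <- round(spec$lesion)
  clean <- gray_image(pix, levels = spec$levels)
  fg <- if (spec$truth == "lesion") geom$lesion else geom$liver | geom$lesion
  truth <- structure(matrix(as.integer(fg), spec$height, spec$width),
                     class = "binary_mask")
  img <- if (spec$noise == "none") clean else {
    if (!is.null(spec$seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(restore_rng(old), add = TRUE)
      set.seed(spec$seed)
    }
    add_noise(clean, model = spec$noise, level = spec$noise_level)
  }
  list(image = img, truth = truth, clean = clean)
}

#' Corrupt an image with noise
#'
#' `"gaussian"` adds independent `Normal(0, level)` deviates to every
#' pixel, rounds, and clips to `[0, H - 1]` (gray values saturate rather
#' than wrap). `"salt_pepper"` flips each pixel independently with
#' probability `level` to 0 or `H - 1` with equal chance. Draws come from
#' the current RNG stream; seed beforehand for reproducibility.
#'
#' @param image A `gray_image` (or integer matrix).
#' @param model `"none"`, `"gaussian"` or `"salt_pepper"`.
#' @param level Gaussian sd (gray levels) or corruption fraction.
#' @return The corrupted `gray_image`.
#' @export
add_noise <- function(image, model = c("none", "gaussian", "salt_pepper"),
                      level = 0) {
  model <- match.arg(model)
  image <- as_gray_image(image)
  h <- gray_levels(image)
  if (model == "none" || level == 0) return(image)
  if (level < 0) stop("noise `level` must be >= 0")
  pix <- unclass(image); attr(pix, "levels") <- NULL
  if (model == "gaussian") {
    pix <- round(pix + stats::rnorm(length(pix), 0, level))
    pix <- pmin(pmax(pix, 0L), h - 1L)
  } else {
    if (level > 1) stop("salt-and-pepper fraction must lie in [0, 1]")
    hit <- stats::runif(length(pix)) < level
    pix[hit] <- ifelse(stats::runif(sum(hit)) < 0.5, 0L, h - 1L)
  }
  gray_image(matrix(pix, nrow(image), ncol(image)), levels = h)
}
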