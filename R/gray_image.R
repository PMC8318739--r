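#' Grayscale image container
#'
#' A `gray_image` is an integer matrix of gray values on a `p x q` grid
#' together with its number of gray levels `H`. Every pixel must be an
#' integer in `[0, H - 1]`.
#'
#' @param pixels Numeric or integer matrix of gray values.
#' @param levels Number of gray levels `H` (default 256 for 8-bit images).
#' @return An object of class `gray_image`: an integer matrix with a
#'   `levels` attribute.
#' @examples
#' img <- gray_image(matrix(c(0, 0, 1, 1), 2, 2), levels = 2)
#' gray_levels(img)
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a nonempty matrix")
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("`levels` must be an integer >= 2")
  if (anyNA(pixels))
    stop("`pixels` contains missing values")
  if (any(pixels != floor(pixels)))
    stop("`pixels` must contain integer gray values")
  bad <- pixels < 0 | pixels > levels - 1L
  if (any(bad)) {
    v <- pixels[which(bad)[1L]]
    stop(sprintf("gray value %s outside the valid range [0, %d]",
                 format(v), levels - 1L))
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, levels = levels, class = "gray_image")
}

#' @rdname gray_image
#' @param x A `gray_image`.
#' @export
gray_levels <- function(x) {
  h <- attr(x, "levels")
  if (is.null(h)) 256L else as.integer(h)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, H = %d, range [%d, %d]\n",
              nrow(x), ncol(x), gray_levels(x), min(x), max(x)))
  invisible(x)
}

# Coerce a plain matrix, inferring H = 256 unless values exceed it.
as_gray_image <- function(x, levels = NULL) {
  if (inherits(x, "gray_image")) return(x)
  if (is.null(levels)) {
    levels <- if (max(x) > 255) 65536L else 256L
  }
  gray_image(x, levels = levels)
}

#' Binarize an image at a threshold
#'
#' Splits the gray-level range at threshold `x`: pixels with value `<= x`
#' belong to the background class `R0` (label 0) and pixels with value
#' `> x` to the foreground class `R1` (label 1).
#'
#' @param image A `gray_image` (or integer matrix).
#' @param x Integer threshold, `0 <= x <= H - 2`, so that both classes are
#'   nonempty gray-level ranges.
#' @return A `binary_mask`: an integer matrix of 0/1 labels with the same
#'   dimensions as `image`.
#' @examples
#' img <- gray_image(matrix(0:3, 1), levels = 4)
#' apply_threshold(img, 0)
#' @export
apply_threshold <- function(image, x) {
  image <- as_gray_image(image)
  h <- gray_levels(image)
  check_threshold(x, h)
  m <- matrix(as.integer(image > x), nrow(image), ncol(image))
  structure(m, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground pixel(s)\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

check_threshold <- function(x, levels) {
  if (length(x) != 1L || is.na(x) || x != floor(x))
    stop("threshold `x` must be a single integer")
  if (x < 0 || x > levels - 2L)
    stop(sprintf("threshold %d outside the valid range [0, %d]",
                 as.integer(x), levels - 2L))
  invisible(as.integer(x))
}
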