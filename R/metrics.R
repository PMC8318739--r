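#' Difference function (DF) between two segmentations
#'
#' The fraction of pixels whose labels disagree between a reference mask
#' and a test mask: `DF = sum(udf(i,j)) / (p*q)` with `udf = 0` where the
#' labels agree and `1` where they differ. In the anti-noise protocol the
#' reference is the segmentation of the clean image and the test the
#' segmentation of its noise-corrupted copy, so `DF` close to 0 indicates
#' strong noise robustness and close to 1 weak robustness. `DF` is
#' symmetric in its arguments and 0 iff the masks are equal.
#'
#' @param mask_ref,mask_test Binary masks (0/1 matrices) of identical
#'   dimensions.
#' @return DF in `[0, 1]`.
#' @examples
#' a <- matrix(c(0, 0, 1, 1), 2, 2)
#' b <- matrix(c(0, 1, 1, 1), 2, 2)
#' difference_function(a, b) # 0.25
#' @export
difference_function <- function(mask_ref, mask_test) {
  if (!identical(dim(mask_ref), dim(mask_test)))
    stop("masks must have identical dimensions")
  mean(mask_ref != mask_test)
}

#' Regional contrast (GC) of a segmentation
#'
#' Normalized gray-level contrast between the segmented region and its
#' immediate surroundings: `GC = |d1 - d2| / (d1 + d2)`, where `d1` is
#' the mean gray value over the foreground (mask label 1) and `d2` the
#' mean over the adjacency ring - background pixels within Chebyshev
#' distance `ring_radius` of any foreground pixel. Values lie in
#' `[0, 1]`; larger means a better-delineated segmentation.
#'
#' @param image A `gray_image` (or integer matrix).
#' @param mask Binary mask with at least one foreground pixel, same
#'   dimensions as `image`.
#' @param ring_radius Chebyshev radius of the adjacency ring, in pixels
#'   (default 5).
#' @return GC in `[0, 1]`.
#' @export
regional_contrast <- function(image, mask, ring_radius = 5L) {
  image <- as_gray_image(image)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have identical dimensions")
  if (ring_radius < 1L) stop("`ring_radius` must be >= 1")
  fg <- mask == 1L
  if (!any(fg)) stop("degenerate region: mask has no foreground pixels")
  ring <- chebyshev_dilate(fg, ring_radius) & !fg
  if (!any(ring)) stop("degenerate region: adjacency ring is empty")
  d1 <- mean(image[fg])
  d2 <- mean(image[ring])
  if (d1 + d2 == 0) stop("degenerate region: both regions are all-black")
  abs(d1 - d2) / (d1 + d2)
}

# Binary dilation with a (2r+1) x (2r+1) square structuring element,
# i.e. Chebyshev distance <= r, done as row- then column-wise running
# OR so the cost is O(r * p * q) rather than O(r^2 * p * q).
chebyshev_dilate <- function(fg, r) {
  out <- fg
  p <- nrow(fg); q <- ncol(fg)
  zr <- matrix(FALSE, 1L, q)
  for (d in seq_len(r))
    out <- out | rbind(out[-1L, , drop = FALSE], zr) |
      rbind(zr, out[-p, , drop = FALSE])
  zc <- matrix(FALSE, p, 1L)
  for (d in seq_len(r))
    out <- out | cbind(out[, -1L, drop = FALSE], zc) |
      cbind(zc, out[, -q, drop = FALSE])
  out
}

#' Assemble a metric report row
#'
#' Bundles the quality metrics of one segmentation into the flat record
#' used by the benchmark harness and its CSV/JSON writers.
#'
#' @param method Method label (`"otsu"`, `"ksw"` or `"fao"`).
#' @param threshold Integer threshold used.
#' @param noise_sd Noise level of the test image (numeric; 0 for clean).
#' @param DF,GC Metric values in `[0, 1]`.
#' @param runtime_s Wall-clock seconds (informational only).
#' @return A one-row `data.frame`.
#' @export
metric_report <- function(method, threshold, noise_sd, DF, GC,
                          runtime_s = NA_real_) {
  stopifnot(DF >= 0, DF <= 1, GC >= 0, GC <= 1)
  data.frame(method = method, threshold = as.integer(threshold),
             noise_sd = noise_sd, DF = DF, GC = GC, runtime_s = runtime_s,
             stringsAsFactors = FALSE)
}
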