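#' Gray-level histogram of an image
#'
#' Counts pixels per gray level `i` in `[0, H - 1]` and converts counts
#' `m_i` to probabilities `T_i = m_i / m`, where `m` is the pixel total.
#' The probabilities sum to 1 by construction.
#'
#' @param image A `gray_image`, or an integer matrix (levels inferred).
#' @return A `gray_histogram`: list with `counts`, `total`, `probs` and
#'   `levels`.
#' @examples
#' img <- gray_image(matrix(c(0, 1, 2, 3), 2, 2), levels = 4)
#' compute_histogram(img)$probs
#' @export
compute_histogram <- function(image) {
  image <- as_gray_image(image)
  h <- gray_levels(image)
  counts <- tabulate(as.integer(image) + 1L, nbins = h)
  total <- sum(counts)
  new_gray_histogram(counts, total, h)
}

new_gray_histogram <- function(counts, total, levels) {
  structure(list(counts = as.integer(counts), total = as.integer(total),
                 probs = counts / total, levels = as.integer(levels)),
            class = "gray_histogram")
}

#' Build a histogram directly from counts
#'
#' @param counts Non-negative integer counts per gray level; their length
#'   sets the number of levels `H`.
#' @return A `gray_histogram`.
#' @export
gray_histogram <- function(counts) {
  if (length(counts) < 2L || anyNA(counts) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("`counts` must be >= 2 non-negative integers")
  total <- sum(counts)
  if (total < 1) stop("histogram must contain at least one pixel")
  new_gray_histogram(counts, total, length(counts))
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram> H = %d levels, %d pixel(s)\n",
              x$levels, x$total))
  invisible(x)
}

as_gray_histogram <- function(x) {
  if (inherits(x, "gray_histogram")) return(x)
  if (inherits(x, "gray_image") || is.matrix(x)) return(compute_histogram(x))
  stop("expected a gray_histogram or gray_image")
}

# Vectorized partition statistics for every candidate threshold
# x = 0..H-2 at once, from cumulative sums over the probability vector.
# Empty classes get mean/variance 0 so sigmaJ^2 + sigmaN^2 stays equal to
# the global variance identically. Returns parallel vectors indexed by x+1.
partition_table <- function(hist) {
  p <- hist$probs
  h <- hist$levels
  i <- seq_len(h) - 1
  thz <- sum(i * p)
  glob <- sum(i^2 * p) - thz^2
  n <- h - 1L # candidate thresholds 0..H-2
  v0 <- cumsum(p)[seq_len(n)]
  v1 <- 1 - v0
  c1 <- cumsum(i * p)[seq_len(n)]
  c2 <- cumsum(i^2 * p)[seq_len(n)]
  th0 <- ifelse(v0 > 0, c1 / v0, 0)
  th1 <- ifelse(v1 > 0, (sum(i * p) - c1) / v1, 0)
  # class variance around the class mean; clamp tiny negative cancellation
  s0 <- ifelse(v0 > 0, pmax(0, c2 / v0 - th0^2), 0)
  s1 <- ifelse(v1 > 0, pmax(0, (sum(i^2 * p) - c2) / v1 - th1^2), 0)
  sJ <- v0 * (th0 - thz)^2 + v1 * (th1 - thz)^2
  sN <- v0 * s0 + v1 * s1
  list(x = 0:(n - 1L), V0 = v0, V1 = v1, theta0 = th0, theta1 = th1,
       thetaZ = thz, sigma0_sq = s0, sigma1_sq = s1,
       sigmaJ_sq = sJ, sigmaN_sq = sN, global_var = glob)
}

#' Class statistics for one candidate threshold
#'
#' For a threshold `x` the gray levels split into `R0 = [0..x]` and
#' `R1 = [x+1..H-1]`. Returns the class probabilities `V0`, `V1`, class
#' means `theta0`, `theta1`, global mean `thetaZ`, class variances, and
#' the between-class (`sigmaJ_sq`) and within-class (`sigmaN_sq`)
#' variances. When a class is empty its mean and variance are defined as
#' 0, which keeps `sigmaJ_sq + sigmaN_sq` equal to the global histogram
#' variance for every `x`.
#'
#' @param hist A `gray_histogram` (or an image, which is histogrammed).
#' @param x Integer threshold in `[0, H - 2]`.
#' @return A `threshold_partition` list.
#' @examples
#' h <- gray_histogram(c(1, 1, 1, 1))
#' class_statistics(h, 1)$sigmaJ_sq # 1.0
#' @export
class_statistics <- function(hist, x) {
  hist <- as_gray_histogram(hist)
  x <- check_threshold(x, hist$levels)
  tab <- partition_table(hist)
  k <- x + 1L
  structure(list(threshold = x, V0 = tab$V0[k], V1 = tab$V1[k],
                 theta0 = tab$theta0[k], theta1 = tab$theta1[k],
                 thetaZ = tab$thetaZ,
                 sigma0_sq = tab$sigma0_sq[k], sigma1_sq = tab$sigma1_sq[k],
                 sigmaJ_sq = tab$sigmaJ_sq[k], sigmaN_sq = tab$sigmaN_sq[k]),
            class = "threshold_partition")
}

#' @export
print.threshold_partition <- function(x, ...) {
  cat(sprintf(paste0("<threshold_partition> x = %d: V0 = %.4f, ",
                     "sigmaJ^2 = %.4f, sigmaN^2 = %.4f\n"),
              x$threshold, x$V0, x$sigmaJ_sq, x$sigmaN_sq))
  invisible(x)
}

# Regularizer keeping the variance ratio finite on perfectly separable
# histograms (sigmaN^2 = 0) without moving its maximizer.
OTSU_EPS <- 1e-12

#' Otsu variance-ratio fitness
#'
#' The thresholding criterion maximized by the optimizer: the ratio of
#' between-class to within-class variance,
#' `sigmaJ^2(x) / (sigmaN^2(x) + eps)` with `eps = 1e-12`. Because
#' `sigmaJ^2 + sigmaN^2` is constant in `x` (the global variance), the
#' ratio has the same argmax as the classic between-class-variance Otsu
#' criterion.
#'
#' @inheritParams class_statistics
#' @return Non-negative finite fitness value.
#' @examples
#' h <- gray_histogram(c(1, 1, 1, 1))
#' otsu_ratio_fitness(h, 1) # 4
#' @export
otsu_ratio_fitness <- function(hist, x) {
  hist <- as_gray_histogram(hist)
  x <- check_threshold(x, hist$levels)
  tab <- partition_table(hist)
  tab$sigmaJ_sq[x + 1L] / (tab$sigmaN_sq[x + 1L] + OTSU_EPS)
}

#' Kapur-Sahoo-Wong maximum-entropy fitness
#'
#' The KSW criterion: the sum of the Shannon entropies (natural log) of
#' the two classes' normalized gray-level distributions,
#' `H0 + H1` with `H0 = -sum_{i<=x} (T_i/V0) ln(T_i/V0)` and `H1`
#' analogous over `i > x`. Zero-probability levels contribute 0. If a
#' class has zero total probability the fitness is `-Inf`, so such
#' thresholds are never selected.
#'
#' @inheritParams class_statistics
#' @return Finite entropy sum, or `-Inf` for an empty class.
#' @export
ksw_entropy_fitness <- function(hist, x) {
  hist <- as_gray_histogram(hist)
  x <- check_threshold(x, hist$levels)
  ksw_entropy_all(hist)[x + 1L]
}

# Entropy sum for every candidate threshold at once.
ksw_entropy_all <- function(hist) {
  p <- hist$probs
  h <- hist$levels
  n <- h - 1L
  plogp <- ifelse(p > 0, p * log(p), 0)
  v0 <- cumsum(p)[seq_len(n)]
  v1 <- 1 - v0
  cp <- cumsum(plogp)[seq_len(n)]
  tot <- sum(plogp)
  h0 <- ifelse(v0 > 0, log(v0) - cp / v0, -Inf)
  h1 <- ifelse(v1 > 0, log(v1) - (tot - cp) / v1, -Inf)
  out <- h0 + h1
  out[v0 <= 0 | v1 <= 0] <- -Inf
  out
}

#' Exhaustive best threshold
#'
#' Brute-force search over every candidate threshold `x` in `[0, H - 2]`,
#' returning the argmax of a fitness function. Ties break to the smallest
#' `x`. This is the oracle the fireworks optimizer is validated against,
#' and the implementation of the plain Otsu and KSW comparator methods.
#'
#' @param hist A `gray_histogram` (or image).
#' @param fitness A fitness function `f(hist, x)`; default
#'   [otsu_ratio_fitness]. [ksw_entropy_fitness] is also accepted, and
#'   both are dispatched to fast vectorized paths.
#' @return List with `threshold` (the argmax) and `fitness` (its value).
#' @examples
#' exhaustive_best_threshold(gray_histogram(c(1, 1, 1, 1)))
#' @export
exhaustive_best_threshold <- function(hist, fitness = otsu_ratio_fitness) {
  hist <- as_gray_histogram(hist)
  vals <- fitness_profile(hist, fitness)
  best <- which.max(vals) # first maximum = smallest x
  list(threshold = as.integer(best - 1L), fitness = vals[best])
}

# Fitness at every x in 0..H-2, using the vectorized path for the two
# built-in criteria and a plain loop otherwise.
fitness_profile <- function(hist, fitness) {
  if (identical(fitness, otsu_ratio_fitness)) {
    tab <- partition_table(hist)
    return(tab$sigmaJ_sq / (tab$sigmaN_sq + OTSU_EPS))
  }
  if (identical(fitness, ksw_entropy_fitness)) return(ksw_entropy_all(hist))
  vapply(0:(hist$levels - 2L), function(x) fitness(hist, x), numeric(1))
}

#' Thresholding objective for the optimizer
#'
#' Wraps a histogram fitness function as a vectorized real-valued
#' objective over continuous positions: a position is rounded and clamped
#' to the integer threshold domain `[0, H - 2]` before evaluation.
#' Evaluations are cached per integer threshold, so repeated probes of
#' the same level are free.
#'
#' @inheritParams exhaustive_best_threshold
#' @return A function `f(positions) -> fitness values`, vectorized.
#' @export
threshold_objective <- function(hist, fitness = otsu_ratio_fitness) {
  hist <- as_gray_histogram(hist)
  hmax <- hist$levels - 2L
  cache <- rep(NA_real_, hmax + 1L)
  force(fitness)
  function(pos) {
    x <- pmin(pmax(as.integer(round(pos)), 0L), hmax)
    miss <- unique(x[is.na(cache[x + 1L])])
    for (m in miss) cache[m + 1L] <<- fitness(hist, m)
    cache[x + 1L]
  }
}
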