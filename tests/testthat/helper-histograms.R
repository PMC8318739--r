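# Random-histogram generators used across the suite. Draws come from the
# current RNG stream; callers seed before use.

# Bimodal Gaussian-mixture histogram: the gray-level structure binary
# thresholding targets (two populations of pixel intensities).
random_bimodal_histogram <- function(levels = 256L, n_pixels = 20000L) {
  m1 <- runif(1, 0.15, 0.40) * (levels - 1)
  m2 <- runif(1, 0.55, 0.85) * (levels - 1)
  s1 <- runif(1, 8, 25)
  s2 <- runif(1, 8, 25)
  w <- runif(1, 0.2, 0.8)
  v <- c(rnorm(round(n_pixels * w), m1, s1),
         rnorm(round(n_pixels * (1 - w)), m2, s2))
  v <- pmin(pmax(round(v), 0), levels - 1)
  gray_histogram(tabulate(v + 1L, nbins = levels))
}

# Jagged stress histogram: independent Poisson counts per level, no
# smoothness assumptions at all.
random_jagged_histogram <- function(levels = 256L) {
  counts <- rpois(levels, lambda = runif(levels, 1, 50))
  counts[counts == 0L] <- 1L
  gray_histogram(counts)
}

# Small deterministic images reused across files.
uniform4_histogram <- function() gray_histogram(c(1, 1, 1, 1))

global_variance <- function(hist) {
  i <- seq_len(hist$levels) - 1
  sum(i^2 * hist$probs) - sum(i * hist$probs)^2
}
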