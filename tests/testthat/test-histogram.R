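test_that("compute_histogram counts pixels and normalizes probabilities", {
  h2 <- compute_histogram(gray_image(matrix(c(0, 0, 1, 1), 2, 2), levels = 2))
  expect_equal(h2$probs, c(0.5, 0.5))

  h1 <- compute_histogram(gray_image(matrix(7L, 1, 1), levels = 256))
  expect_equal(h1$probs[8], 1)
  expect_equal(sum(h1$probs), 1)
  expect_equal(sum(h1$counts), 1)

  h4 <- compute_histogram(gray_image(matrix(c(0, 1, 2, 3), 2, 2), levels = 4))
  expect_equal(h4$probs, rep(0.25, 4))
  expect_equal(h4$total, 4)
})

test_that("out-of-range pixels are rejected with the offending value named", {
  expect_error(gray_image(matrix(c(0, 4), 1, 2), levels = 4), "4")
  expect_error(gray_image(matrix(-1, 1, 1)), "-1")
  expect_error(gray_image(matrix(0.5, 1, 1)), "integer")
})

test_that("class_statistics matches the hand-derived uniform 4-level case", {
  p <- class_statistics(uniform4_histogram(), 1)
  expect_equal(p$V0, 0.5)
  expect_equal(p$theta0, 0.5)
  expect_equal(p$theta1, 2.5)
  expect_equal(p$thetaZ, 1.5)
  expect_equal(p$sigmaJ_sq, 1.0)
  expect_equal(p$sigma0_sq, 0.25)
  expect_equal(p$sigma1_sq, 0.25)
  expect_equal(p$sigmaN_sq, 0.25)
})

test_that("degenerate one-class histograms give zero variances", {
  h <- gray_histogram(c(10, 0, 0, 0))
  p <- class_statistics(h, 0)
  expect_equal(p$V1, 0)
  expect_equal(p$sigmaJ_sq, 0)
  expect_equal(p$sigmaN_sq, 0)
  expect_equal(p$theta1, 0) # empty class mean defined as 0
})

test_that("threshold range is enforced across operations", {
  h <- uniform4_histogram()
  for (f in list(function(x) class_statistics(h, x),
                 function(x) otsu_ratio_fitness(h, x),
                 function(x) ksw_entropy_fitness(h, x)))
    for (bad in c(-1, 3)) expect_error(f(bad), "range")
  img <- gray_image(matrix(0:3, 2, 2), levels = 4)
  expect_error(apply_threshold(img, 3), "range")
})

test_that("otsu_ratio_fitness matches hand-evaluated ratios", {
  h <- uniform4_histogram()
  expect_equal(otsu_ratio_fitness(h, 1), 4.0, tolerance = 1e-9)
  expect_equal(otsu_ratio_fitness(h, 0), 1.5, tolerance = 1e-9)
  hc <- gray_histogram(c(0, 5, 0, 0)) # constant image
  for (x in 0:2) expect_equal(otsu_ratio_fitness(hc, x), 0)
})

test_that("ksw entropy is zero for point-mass classes and -Inf for empty", {
  h2 <- gray_histogram(c(1, 1))
  expect_equal(ksw_entropy_fitness(h2, 0), 0)
  hempty <- gray_histogram(c(3, 4, 0, 0))
  expect_identical(ksw_entropy_fitness(hempty, 2), -Inf)
})

test_that("exhaustive search finds the argmax with smallest-x tie-break", {
  best <- exhaustive_best_threshold(uniform4_histogram())
  expect_equal(best$threshold, 1L)
  expect_equal(best$fitness, 4.0, tolerance = 1e-9)

  hc <- gray_histogram(c(0, 5, 0, 0))
  bc <- exhaustive_best_threshold(hc)
  expect_equal(bc$threshold, 0L)
  expect_equal(bc$fitness, 0)

  hu <- gray_histogram(rep(1, 256))
  expect_equal(exhaustive_best_threshold(hu, ksw_entropy_fitness)$threshold,
               127L)
})

test_that("apply_threshold puts pixels equal to x in class R0", {
  img <- gray_image(matrix(c(0, 0, 3, 3), 2, 2, byrow = TRUE), levels = 4)
  expect_equal(unclass(apply_threshold(img, 1)),
               matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(as.integer(apply_threshold(gray_image(matrix(5L, 1, 1)), 5)), 0L)
  expect_equal(as.integer(apply_threshold(gray_image(matrix(0:3, 1, 4),
                                                     levels = 4), 0)),
               c(0L, 1L, 1L, 1L))
})

test_that("probabilities, mean decomposition and variance conservation hold
           on random histograms", {
  set.seed(41)
  for (k in 1:50) {
    h <- if (k %% 2) random_bimodal_histogram() else random_jagged_histogram()
    expect_equal(sum(h$probs), 1, tolerance = 1e-12)
    gv <- global_variance(h)
    xs <- sample(0:(h$levels - 2L), 8)
    for (x in xs) {
      p <- class_statistics(h, x)
      expect_equal(p$V0 + p$V1, 1, tolerance = 1e-12)
      expect_equal(p$thetaZ, p$V0 * p$theta0 + p$V1 * p$theta1,
                   tolerance = 1e-9)
      expect_equal(p$sigmaJ_sq + p$sigmaN_sq, gv, tolerance = 1e-9)
      expect_gte(p$sigmaJ_sq, 0)
      expect_gte(p$sigmaN_sq, 0)
    }
  }
})

test_that("variance-ratio argmax coincides with classic between-class Otsu", {
  set.seed(42)
  for (k in 1:50) {
    h <- if (k %% 2) random_bimodal_histogram() else random_jagged_histogram()
    ratio_best <- exhaustive_best_threshold(h, otsu_ratio_fitness)$threshold
    sj <- vapply(0:(h$levels - 2L),
                 function(x) class_statistics(h, x)$sigmaJ_sq, numeric(1))
    expect_equal(ratio_best, which.max(sj) - 1L)
  }
})

test_that("mask label counts match the histogram split exactly", {
  set.seed(7)
  pix <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  img <- gray_image(pix)
  h <- compute_histogram(img)
  for (x in c(0, 63, 127, 254)) {
    mask <- apply_threshold(img, x)
    expect_identical(sum(mask == 0L), sum(h$counts[seq_len(x + 1L)]))
  }
})

test_that("threshold_objective rounds, clamps and caches consistently", {
  h <- random_bimodal_histogram()
  obj <- threshold_objective(h)
  expect_equal(obj(100.4), otsu_ratio_fitness(h, 100))
  expect_equal(obj(100.6), otsu_ratio_fitness(h, 101))
  expect_equal(obj(-3), otsu_ratio_fitness(h, 0))
  expect_equal(obj(c(10.2, 10.2, 254.9)),
               c(otsu_ratio_fitness(h, 10), otsu_ratio_fitness(h, 10),
                 otsu_ratio_fitness(h, 254)))
})
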