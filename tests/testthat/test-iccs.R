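test_that("FFT-based masked correlation equals the brute-force pair sums", {
  withr::with_seed(10, {
    a <- matrix(rpois(24 * 20, 20), 24, 20)
    b <- matrix(rpois(24 * 20, 15), 24, 20)
  })
  m <- matrix(TRUE, 24, 20)
  m[1:4, ] <- FALSE; m[, 1:3] <- FALSE   # irregular mask
  s <- masked_correlation(a, b, m, max_lag = 6, min_mask_px = 100)
  expect_lt(max(abs(s$values - brute_masked_correlation(a, b, m, 6)), na.rm = TRUE),
            1e-8)
  expect_equal(s$n_pairs[7, 7], sum(m))
  # autocorrelation zero lag equals var/mean^2 of the realized image
  sa <- masked_correlation(a, a, m, max_lag = 4, min_mask_px = 100)
  va <- a[m]
  expect_equal(sa$values[5, 5], mean((va - mean(va))^2) / mean(va)^2)
})

test_that("correlation surface contracts: flat images, small masks, symmetry", {
  const <- matrix(3, 32, 32)
  s <- masked_correlation(const, const, matrix(TRUE, 32, 32), max_lag = 5)
  expect_true(all(s$values == 0))
  expect_error(masked_correlation(const, const, matrix(FALSE, 32, 32)), "pixels")
  zero <- matrix(0, 32, 32)
  expect_error(masked_correlation(zero, const, matrix(TRUE, 32, 32)), "zero")
  # ACF symmetric under lag negation
  withr::with_seed(3, img <- matrix(rpois(1024, 10), 32))
  sa <- masked_correlation(img, img, matrix(TRUE, 32, 32), max_lag = 6)
  expect_equal(sa$values, sa$values[rev(seq_len(13)), rev(seq_len(13))],
               tolerance = 1e-10)
})

test_that("correlation is invariant to channel scaling and joint translation", {
  withr::with_seed(4, {
    a <- matrix(rpois(40 * 40, 30), 40)
    b <- matrix(rpois(40 * 40, 30), 40)
  })
  m <- matrix(FALSE, 40, 40); m[8:35, 6:32] <- TRUE
  base <- coloc_fractions(a, b, m, max_lag = 8)
  scaled <- coloc_fractions(2.5 * a, 0.7 * b, m, max_lag = 8)
  expect_equal(scaled$f1, base$f1, tolerance = 1e-8)
  expect_equal(scaled$f2, base$f2, tolerance = 1e-8)
  # translate images and mask together
  sh <- function(x) chromodyn:::shift_matrix(x, 3, -2)
  moved <- coloc_fractions(sh(a), sh(b), sh(m) > 0, max_lag = 8)
  expect_equal(moved$f1, base$f1, tolerance = 1e-8)
})

test_that("amplitude fit recovers Gaussian surfaces and skips the zero-lag spike", {
  f <- fit_amplitude(model_surface(0.5, 16), exclude_zero_lag = FALSE)
  expect_true(f$success)
  expect_equal(f$g0, 0.5, tolerance = 1e-6)
  expect_equal(f$width_px, 4, tolerance = 1e-6)
  expect_equal(f$offset, 0, tolerance = 1e-8)
  # +0.3 spike at r = 0 ignored by the extrapolated amplitude
  fs <- fit_amplitude(model_surface(0.5, 16, spike = 0.3), exclude_zero_lag = TRUE)
  expect_equal(fs$g0, 0.5, tolerance = 1e-6)
  # negative amplitudes preserved
  fn <- fit_amplitude(model_surface(-0.2, 16))
  expect_equal(fn$g0, -0.2, tolerance = 1e-6)
})

test_that("colocalization fractions hit the 1 / 0 / -1 landmarks", {
  m <- matrix(TRUE, 128, 128)
  tex <- synth_texture(shape = c(128, 128), seed = 41)
  dup <- coloc_fractions(tex, tex, m)
  expect_equal(dup$f1, 1, tolerance = 0.05)
  expect_equal(dup$f2, 1, tolerance = 0.05)
  # independent textures: mean f1 near zero
  f1s <- vapply(1:8, function(s) {
    coloc_fractions(synth_texture(shape = c(128, 128), seed = 100 + 2 * s),
                    synth_texture(shape = c(128, 128), seed = 101 + 2 * s), m)$f1
  }, numeric(1))
  expect_lt(abs(mean(f1s)), 0.05)
  # equal-mean inversion: delta2 = -delta1 forces Gcc(0) = -Gac2(0)
  inv <- 2 * mean(tex) - tex
  anti <- coloc_fractions(tex, inv, m)
  expect_equal(anti$f1, -1, tolerance = 0.05)
  expect_lt(anti$gcc0, 0)
})

test_that("per-frame colocalization series honors its contracts", {
  tex <- synth_texture(shape = c(96, 96), seed = 9)
  n <- 4
  arr <- array(0, dim = c(96, 96, 2, n))
  for (f in seq_len(n)) { arr[, , 1, f] <- tex; arr[, , 2, f] <- tex }
  stack <- timelapse_stack(arr, c(-1.3, 2.6, 5.6, 8.6))
  full <- matrix(1L, 96, 96)
  masks <- list(full, full, matrix(0L, 96, 96), full)
  res <- timelapse_iccs(stack, masks)
  expect_true(is.na(res$f1[1]))            # pre-bleach frame not analyzed
  expect_true(is.na(res$f1[3]))            # empty mask: missing, not zero
  expect_equal(res$f1[c(2, 4)], c(1, 1), tolerance = 0.05)
  expect_error(timelapse_iccs(stack, masks[1:2]), "align")
})

test_that("heterochromatin-biased damage raises early colocalization", {
  # paired comparison at the first post-bleach frame: bias 1 vs bias 0
  f1_at_first <- function(bias, seed) {
    nuc <- synth_nucleus(shape = c(128, 128), n_blobs = 15, contrast = 3,
                         seed = seed)
    sch <- acq_schedule(n_post = 3)
    sim <- synth_timelapse(nuc, kinetics_truth(recruit_amplitude = 0.3),
                           roi = default_roi(nuc, "internal"), schedule = sch,
                           damage_bias = bias, seed = seed)
    region <- truth_region(sim)
    f <- which(sim$stack$time_s > 0)[1]
    cf <- coloc_fractions(sim$stack$data[, , 1, f], sim$stack$data[, , 2, f],
                          region)
    cf$gcc0 / cf$gac2_0    # unclipped ratio keeps the comparison informative
  }
  seeds <- 1:6
  hi <- vapply(seeds, function(s) f1_at_first(1, s), numeric(1))
  lo <- vapply(seeds, function(s) f1_at_first(0, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})
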