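make_stack <- function(frames_dna, frames_dmg = NULL, dt = 1) {
  n <- length(frames_dna)
  nr <- nrow(frames_dna[[1]]); nc <- ncol(frames_dna[[1]])
  nch <- if (is.null(frames_dmg)) 1L else 2L
  arr <- array(0, dim = c(nr, nc, nch, n))
  for (f in seq_len(n)) {
    if (nch == 2L) {
      arr[, , 1, f] <- frames_dmg[[f]]
      arr[, , 2, f] <- frames_dna[[f]]
    } else arr[, , 1, f] <- frames_dna[[f]]
  }
  roles <- if (nch == 2L) c(damage = 1L, dna = 2L) else c(dna = 1L)
  timelapse_stack(arr, seq_len(n) * dt, channel_roles = roles)
}

disk <- function(nr, nc, cy, cx, r, value = 100) {
  m <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- value
  }
  m
}

test_that("nucleus segmentation matches a direct thresholding oracle", {
  one <- disk(80, 80, 40, 40, 20)
  stack <- make_stack(list(one, one))
  labs <- segment_nuclei(stack, min_area = 50)
  expect_equal(max(labs[[1]]), 1)
  # oracle: direct threshold at the isodata level selects the same pixels
  thr <- isodata_threshold(one)
  expect_identical(labs[[1]] > 0, one > thr)
  # disk interior contained in the mask
  interior <- disk(80, 80, 40, 40, 18) > 0
  expect_true(all(labs[[1]][interior] > 0))
  # all-zero frame: empty mask, no error
  labs0 <- segment_nuclei(make_stack(list(matrix(0, 80, 80))), min_area = 50)
  expect_true(all(labs0[[1]] == 0))
})

test_that("two nuclei keep distinct, stable labels across frames", {
  two <- disk(80, 80, 25, 25, 12) + disk(80, 80, 60, 60, 12)
  # second frame: slight shift of the lower-right nucleus
  two_b <- disk(80, 80, 25, 25, 12) + disk(80, 80, 62, 61, 12)
  labs <- segment_nuclei(make_stack(list(two, two_b)), min_area = 50)
  expect_equal(max(labs[[1]]), 2)
  expect_equal(max(labs[[2]]), 2)
  # identity preserved: the object at (25,25) carries the same label
  expect_equal(labs[[1]][25, 25], labs[[2]][25, 25])
  expect_equal(labs[[1]][60, 60], labs[[2]][62, 61])
  expect_false(labs[[1]][25, 25] == labs[[1]][60, 60])
})

test_that("segmentation is idempotent on its own binarized output", {
  img <- disk(80, 80, 40, 40, 20)
  labs <- segment_nuclei(make_stack(list(img)), min_area = 50)
  rebin <- (labs[[1]] > 0) * 100
  labs2 <- segment_nuclei(make_stack(list(rebin)), min_area = 50)
  expect_identical(labs[[1]], labs2[[1]])
})

test_that("damage-area mask is the exact nucleus/ROI intersection", {
  img <- disk(80, 80, 40, 40, 20)
  labs <- segment_nuclei(make_stack(list(img)), min_area = 50)
  # whole-frame ROI: identity
  whole <- damage_area_mask(labs, roi_rect(0, 0, 80, 80))
  expect_identical(whole[[1]], labs[[1]])
  # disjoint ROI: all zero
  far <- damage_area_mask(labs, roi_rect(0, 0, 10, 10))
  expect_true(all(far[[1]] == 0))
  # half-overlapping ROI: pixel count equals brute-force set intersection
  roi <- roi_rect(40, 0, 40, 80)
  cut <- damage_area_mask(labs, roi)
  sel <- matrix(FALSE, 80, 80); sel[, 41:80] <- TRUE
  expect_equal(sum(cut[[1]] > 0), sum(labs[[1]] > 0 & sel))
  # subset property
  expect_true(all(cut[[1]][cut[[1]] > 0] == labs[[1]][cut[[1]] > 0]))
  expect_error(damage_area_mask(labs, roi_rect(70, 0, 20, 20)), "outside")
})

test_that("foci threshold selects pixels at a fraction of the frame max", {
  f <- matrix(c(100, 85, 80, 79, 50, 10, 0, 0, 0), 3, 3)
  m <- foci_mask(f, 0.8)
  expect_identical(unname(as.vector(m)), as.vector(f >= 80))
  # constant positive frame: every pixel equals the max
  expect_true(all(foci_mask(matrix(5, 4, 4), 0.8)))
  # fraction 1: only the argmax pixels
  expect_identical(which(foci_mask(f, 1)), which(f == 100))
  # all-zero frame: empty mask with warning flag
  z <- foci_mask(matrix(0, 4, 4))
  expect_false(any(z))
  expect_true(attr(z, "undefined"))
  # monotonicity: raising the fraction never adds pixels
  withr::with_seed(1, img <- matrix(rpois(400, 20), 20))
  prev <- foci_mask(img, 0.5)
  for (fr in c(0.7, 0.9, 1)) {
    cur <- foci_mask(img, fr)
    expect_true(all(prev[cur]))
    prev <- cur
  }
})

test_that("background subtraction removes offsets and keeps small features", {
  # constant frame: flat background fully removed
  const <- make_stack(list(matrix(7, 64, 64)))
  out <- subtract_background(const, smooth_px = 1, rolling_ball_px = 20)
  expect_true(all(out$data == 0))
  # blob of sigma 2 on offset 10: peak preserved within 5%, offset removed
  blob <- matrix(0, 64, 64); blob[32, 32] <- 1
  blob <- as.matrix(EBImage::gblur(blob, 2)); blob <- 50 * blob / max(blob)
  img <- blob + 10
  st <- make_stack(list(img))
  res <- subtract_background(st, smooth_px = 1, rolling_ball_px = 20)$data[, , 1, 1]
  expect_equal(max(res), 50, tolerance = 0.05)
  expect_lt(stats::median(res), 1)   # offset gone over most of the frame
  # oracle: direct flat-disc grayscale opening (min filter then max filter)
  gray_open <- function(x, r) {
    off <- expand.grid(dr = -r:r, dc = -r:r)
    off <- off[off$dr^2 + off$dc^2 <= r^2, ]
    er <- matrix(Inf, nrow(x), ncol(x))
    for (k in seq_len(nrow(off))) {
      er <- pmin(er, chromodyn:::shift_matrix(x, off$dr[k], off$dc[k], fill = Inf))
    }
    di <- matrix(-Inf, nrow(x), ncol(x))
    for (k in seq_len(nrow(off))) {
      di <- pmax(di, chromodyn:::shift_matrix(er, off$dr[k], off$dc[k], fill = -Inf))
    }
    di
  }
  open_bg <- gray_open(img, 10)
  expect_equal(max(img - open_bg), 50, tolerance = 0.05)
  expect_equal(stats::median(img - open_bg), 0, tolerance = 1e-8)
  # non-negativity and never increasing any pixel
  withr::with_seed(2, noisy <- matrix(rpois(64 * 64, 30), 64))
  st2 <- make_stack(list(noisy))
  res2 <- subtract_background(st2, smooth_px = 3, rolling_ball_px = 20)$data[, , 1, 1]
  smoothed <- chromodyn:::mean_filter(noisy, 3)
  expect_true(all(res2 >= 0))
  expect_true(all(res2 <= smoothed + 1e-9))
  expect_error(subtract_background(st2, rolling_ball_px = 1000), "exceeds")
})
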