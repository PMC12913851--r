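# Independent oracles and small fixture builders used across test files.

# Brute-force masked correlation: nested-loop pair sums over all lags.
brute_masked_correlation <- function(a, b, m, L) {
  ma <- mean(a[m]); mb <- mean(b[m])
  da <- (a - ma) * m; db <- (b - mb) * m
  nr <- nrow(a); nc <- ncol(a)
  V <- matrix(NA_real_, 2 * L + 1, 2 * L + 1)
  for (i in -L:L) for (j in -L:L) {
    s <- 0; n <- 0
    for (x in seq_len(nr)) for (y in seq_len(nc)) {
      x2 <- x + i; y2 <- y + j
      if (x2 >= 1 && x2 <= nr && y2 >= 1 && y2 <= nc && m[x, y] && m[x2, y2]) {
        s <- s + da[x, y] * db[x2, y2]; n <- n + 1
      }
    }
    if (n > 0) V[i + L + 1, j + L + 1] <- (s / n) / (ma * mb)
  }
  V
}

# Fabricate a noiseless radially-Gaussian correlation surface
# g(r) = g0 * exp(-r^2 / w2) + offset, optionally with a zero-lag spike.
model_surface <- function(g0, w2, offset = 0, L = 10, spike = 0) {
  lags <- -L:L
  r2 <- outer(lags^2, lags^2, "+")
  v <- g0 * exp(-r2 / w2) + offset
  v[L + 1, L + 1] <- v[L + 1, L + 1] + spike
  structure(list(values = v, lags_px = lags,
                 n_pairs = matrix(1000, 2 * L + 1, 2 * L + 1),
                 mean_a = 1, mean_b = 1, mask_px = 1000),
            class = "corr_surface")
}

# Small nucleus + internal-ROI simulation used by pipeline tests.
small_sim <- function(seed = 1, condition = "control", ...) {
  synth_condition(seed, condition, shape = c(128, 128), ...)
}

# Region of ground-truth analysis: ROI intersected with the true nucleus.
truth_region <- function(sim) {
  nuc <- sim$truth$nucleus
  m <- matrix(FALSE, nrow(nuc$nucleus_mask), ncol(nuc$nucleus_mask))
  roi <- sim$truth$roi
  m[roi$y0 + seq_len(roi$height), roi$x0 + seq_len(roi$width)] <- TRUE
  m & nuc$nucleus_mask
}

# Raw per-frame region trace of one channel role.
region_trace <- function(sim, role, region, frames = NULL) {
  idx <- sim$stack$channel_roles[[role]]
  if (is.null(frames)) frames <- seq_along(sim$stack$time_s)
  vapply(frames, function(f) mean(sim$stack$data[, , idx, f][region]), numeric(1))
}

region_cv_trace <- function(sim, region, frames) {
  idx <- sim$stack$channel_roles[["dna"]]
  vapply(frames, function(f) {
    v <- sim$stack$data[, , idx, f][region]
    sqrt(mean((v - mean(v))^2)) / mean(v)
  }, numeric(1))
}
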