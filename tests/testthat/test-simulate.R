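test_that("nucleus synthesis is deterministic and respects its contracts", {
  n1 <- synth_nucleus(shape = c(96, 96), n_blobs = 20, contrast = 3, seed = 7)
  n2 <- synth_nucleus(shape = c(96, 96), n_blobs = 20, contrast = 3, seed = 7)
  expect_identical(n1, n2)
  # heterochromatin inside nucleus; density zero outside
  expect_true(all(n1$nucleus_mask[n1$heterochromatin_mask]))
  expect_true(all(n1$chromatin_density_map[!n1$nucleus_mask] == 0))
  # zero contrast: featureless in-nucleus density
  n0 <- synth_nucleus(shape = c(96, 96), n_blobs = 20, contrast = 1, seed = 7)
  expect_equal(stats::sd(n0$chromatin_density_map[n0$nucleus_mask]), 0)
  # texture contrast raises in-nucleus density CV
  cv_of <- function(n) {
    v <- n$chromatin_density_map[n$nucleus_mask]
    stats::sd(v) / mean(v)
  }
  expect_gt(cv_of(n1), cv_of(n0))
  expect_error(synth_nucleus(shape = c(32, 96)), "64")
  expect_error(synth_nucleus(shape = c(96, 96), blob_sigma_px = 0), "positive")
})

test_that("identical seeds give bit-identical stacks", {
  s1 <- small_sim(11)
  s2 <- small_sim(11)
  expect_identical(s1$stack$data, s2$stack$data)
  expect_identical(s1$truth$foci, s2$truth$foci)
})

test_that("pixel values are Poisson around the expected rates", {
  # static stack (no dynamics), many frames: per-pixel variance ~ mean
  nuc <- synth_nucleus(shape = c(96, 96), n_blobs = 10, contrast = 3, seed = 2)
  kin <- kinetics_truth(relax_amplitude = 0, recruit_amplitude = 0)
  sch <- acq_schedule(n_pre = 0, n_post = 60, dt_post = 1)
  sim <- synth_timelapse(nuc, kin, roi = default_roi(nuc, "internal"),
                         schedule = sch, seed = 5)
  px <- which(nuc$nucleus_mask)[seq(1, sum(nuc$nucleus_mask), by = 7)]
  dna <- apply(sim$stack$data[, , 2, ], 3, function(m) m[px])
  ratio <- apply(dna, 1, stats::var) / rowMeans(dna)
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("null dynamics keep both post-bleach region means flat", {
  nuc <- synth_nucleus(shape = c(128, 128), n_blobs = 15, contrast = 3, seed = 3)
  kin <- kinetics_truth(relax_amplitude = 0, recruit_amplitude = 0)
  sim <- synth_timelapse(nuc, kin, roi = default_roi(nuc, "internal"), seed = 3)
  region <- truth_region(sim)
  post <- which(sim$stack$time_s > 0)
  for (role in c("dna", "damage")) {
    tr <- region_trace(sim, role, region, post)
    early <- mean(tr[1:5]); late <- mean(tr[46:50])
    expect_equal(late / early, 1, tolerance = 0.03)
  }
})

test_that("focus placement follows the heterochromatin bias", {
  nuc <- synth_nucleus(shape = c(128, 128), n_blobs = 15, contrast = 3, seed = 4)
  frac_het <- function(bias, seed) {
    sim <- synth_timelapse(nuc, roi = default_roi(nuc, "internal"),
                           damage_bias = bias, n_foci = 20, seed = seed)
    idx <- cbind(sim$truth$foci$row, sim$truth$foci$col)
    mean(nuc$heterochromatin_mask[idx])
  }
  # forced placement: every focus center inside the heterochromatin mask
  expect_equal(frac_het(1, 1), 1)
  # monotone (non-decreasing) bias, averaged over seeds
  seeds <- 1:6
  f0 <- mean(vapply(seeds, function(s) frac_het(0, s), numeric(1)))
  f5 <- mean(vapply(seeds, function(s) frac_het(0.5, s), numeric(1)))
  f1 <- mean(vapply(seeds, function(s) frac_het(1, s), numeric(1)))
  expect_true(f0 <= f5 + 1e-9 && f5 <= f1 + 1e-9)
  expect_gt(f1, f0)
})

test_that("relaxing counterstain mean decays with the programmed constant", {
  # oracle: the analytic expected-rate trace recovers tau exactly
  kin <- kinetics_truth(relax_amplitude = 0.4, t_off_intensity = 30)
  ts <- schedule_times(acq_schedule())
  post <- ts[ts > 0]
  exact <- 100 * (1 - kin$relax_amplitude * (1 - exp(-post / kin$t_off_intensity)))
  expect_equal(fit_decay(post, exact, "at_first_post")$tau_s, 30, tolerance = 1e-4)
  # simulated stacks: mean fitted tau within 15% of truth
  taus <- vapply(1:5, function(s) {
    nuc <- synth_nucleus(shape = c(128, 128), n_blobs = 15, contrast = 3, seed = s)
    sim <- synth_timelapse(nuc, kin, roi = default_roi(nuc, "internal"), seed = s)
    region <- truth_region(sim)
    idx <- which(sim$stack$time_s > 0)
    fit_decay(sim$stack$time_s[idx], region_trace(sim, "dna", region, idx),
              "at_first_post")$tau_s
  }, numeric(1))
  expect_equal(mean(taus), 30, tolerance = 0.15)
})

test_that("simulator rejects a ROI that misses the nucleus", {
  nuc <- synth_nucleus(shape = c(96, 96), n_blobs = 5, contrast = 3, seed = 1)
  expect_error(synth_timelapse(nuc, roi = roi_rect(0, 0, 4, 4), seed = 1),
               "intersect")
})

test_that("synthetic output round-trips through TIFF and JSON sidecar", {
  nuc <- synth_nucleus(shape = c(96, 96), n_blobs = 8, contrast = 3, seed = 6)
  sim <- synth_timelapse(nuc, roi = default_roi(nuc, "internal"),
                         schedule = acq_schedule(n_post = 4), seed = 6)
  prefix <- file.path(withr::local_tempdir(), "sim")
  write_synthetic(sim, prefix)
  back <- read_stack_tiff(prefix)
  expect_equal(back$data, sim$stack$data)
  expect_equal(back$time_s, sim$stack$time_s)
  truth <- jsonlite::read_json(paste0(prefix, "_truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, 6)
  expect_equal(truth$kinetics$t_on, sim$truth$kinetics$t_on)
})
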