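#' Ground-truth kinetic parameters for the simulator
#'
#' Collects the kinetic constants driving a synthetic damage time-lapse:
#' recruitment of the damage marker into the irradiated region follows a
#' one-phase association with constant `t_on`, the counterstain mean inside
#' the region decays with constant `t_off_intensity` toward
#' `1 - relax_amplitude` of its initial level, and the counterstain
#' coefficient of variation decays with constant `t_off_cv` (chromatin
#' relaxation). After `decay_start_s` the damage-marker foci decay with
#' constant `t_off_damage` (signal release/redistribution).
#'
#' `relax_amplitude = 0` gives the PARP-inhibited regime (no relaxation);
#' intermediate values emulate graded inhibitor doses.
#'
#' @param t_on association time constant of the damage channel, seconds
#' @param t_off_intensity decay constant of the in-region counterstain mean,
#'   seconds
#' @param t_off_cv decay constant of the in-region counterstain CV, seconds
#' @param relax_amplitude fractional drop of the counterstain mean/CV at
#'   plateau, in `[0, 1]`; 0 disables relaxation
#' @param recruit_amplitude peak added focus rate relative to the base
#'   counterstain rate (>= 0); 0 disables recruitment
#' @param decay_start_s time at which the damage signal starts to decay;
#'   `Inf` keeps a sustained plateau (inhibitor-trapped regime)
#' @param t_off_damage decay constant of the damage signal after
#'   `decay_start_s`, seconds
#' @return An object of class `kinetics_truth`.
#' @export
kinetics_truth <- function(t_on = 6, t_off_intensity = 30, t_off_cv = 30,
                           relax_amplitude = 0.3, recruit_amplitude = 0.6,
                           decay_start_s = 53.6, t_off_damage = 40) {
  if (any(c(t_on, t_off_intensity, t_off_cv, t_off_damage) <= 0)) {
    stopf("time constants must be positive")
  }
  if (relax_amplitude < 0 || relax_amplitude > 1) {
    stopf("relax_amplitude must be in [0, 1]")
  }
  if (recruit_amplitude < 0) stopf("recruit_amplitude must be >= 0")
  structure(list(t_on = t_on, t_off_intensity = t_off_intensity,
                 t_off_cv = t_off_cv, relax_amplitude = relax_amplitude,
                 recruit_amplitude = recruit_amplitude,
                 decay_start_s = decay_start_s, t_off_damage = t_off_damage),
            class = "kinetics_truth")
}

#' Synthesize a nucleus with heterochromatin texture
#'
#' Builds an elliptical nucleus whose relative chromatin density is a base
#' level of 1 plus Gaussian blobs (heterochromatin foci) of the stated sigma,
#' each with peak amplitude `contrast - 1`, so an isolated blob reaches
#' `contrast` times the euchromatin level. The heterochromatin mask collects
#' in-nucleus pixels above the `hetero_quantile` density quantile. Density is
#' zero outside the nucleus.
#'
#' @param shape frame size in pixels, `c(rows, cols)` (>= 64 each)
#' @param n_blobs number of heterochromatin blobs
#' @param blob_sigma_px blob Gaussian sigma in pixels (> 0)
#' @param contrast peak-to-base density ratio of an isolated blob (>= 1);
#'   `contrast = 1` gives a featureless nucleus
#' @param hetero_quantile in-nucleus density quantile defining the
#'   heterochromatin mask
#' @param pixel_size_um pixel size in micrometres
#' @param seed integer seed; the same seed reproduces the nucleus exactly
#' @return An object of class `nucleus_truth` with fields `nucleus_mask`,
#'   `chromatin_density_map` (relative rate, base 1), `heterochromatin_mask`
#'   and `pixel_size_um`.
#' @export
synth_nucleus <- function(shape = c(512, 512), n_blobs = 150,
                          blob_sigma_px = 4, contrast = 3,
                          hetero_quantile = 0.75, pixel_size_um = 0.072,
                          seed = 1) {
  if (any(shape < 64)) stopf("shape must be at least 64 x 64")
  if (blob_sigma_px <= 0) stopf("blob_sigma_px must be positive")
  if (contrast < 1) stopf("contrast must be >= 1")
  nr <- shape[1]; nc <- shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  a <- 0.42 * nc; b <- 0.36 * nr    # semi-axes: cols, rows
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  nucleus <- ((cols - cx) / a)^2 + ((rows - cy) / b)^2 <= 1

  density <- matrix(1, nr, nc)
  if (n_blobs > 0 && contrast > 1) {
    withr::with_seed(seed, {
      idx <- sample(which(nucleus), n_blobs, replace = TRUE)
    })
    impulse <- matrix(0, nr, nc)
    # accumulate multiplicities for blobs landing on the same pixel
    tab <- table(idx)
    impulse[as.integer(names(tab))] <- as.integer(tab)
    blob <- as.matrix(EBImage::gblur(impulse, sigma = blob_sigma_px))
    blob <- pmax(blob, 0) * 2 * pi * blob_sigma_px^2   # unit peak per blob
    density <- density + (contrast - 1) * blob
  }
  density[!nucleus] <- 0
  qv <- stats::quantile(density[nucleus], hetero_quantile, names = FALSE)
  hetero <- nucleus & (density > qv)
  structure(list(nucleus_mask = nucleus, chromatin_density_map = density,
                 heterochromatin_mask = hetero, pixel_size_um = pixel_size_um,
                 centroid = c(row = cy, col = cx), semi_axes = c(col = a, row = b),
                 seed = seed),
            class = "nucleus_truth")
}

#' Full-frame chromatin-like texture
#'
#' Poisson-count image of Gaussian blobs on a uniform base over the whole
#' frame (no nucleus boundary) — the standard structured test image for
#' correlation analyses, where any two seeds give statistically independent
#' textures.
#'
#' @inheritParams synth_nucleus
#' @param mean_counts expected counts per pixel at the base level
#' @return Integer matrix of photon counts.
#' @export
synth_texture <- function(shape = c(256, 256), n_blobs = NULL,
                          blob_sigma_px = 3, contrast = 3,
                          mean_counts = 50, seed = 1) {
  if (is.null(n_blobs)) n_blobs <- round(prod(shape) / 1750)
  nr <- shape[1]; nc <- shape[2]
  withr::with_seed(seed, {
    idx <- sample.int(nr * nc, n_blobs, replace = TRUE)
    impulse <- matrix(0, nr, nc)
    tab <- table(idx)
    impulse[as.integer(names(tab))] <- as.integer(tab)
    blob <- pmax(as.matrix(EBImage::gblur(impulse, sigma = blob_sigma_px)), 0)
    rate <- mean_counts * (1 + (contrast - 1) * blob * 2 * pi * blob_sigma_px^2)
    matrix(stats::rpois(nr * nc, rate), nr, nc)
  })
}

#' Default irradiation ROI for a synthetic nucleus
#'
#' `preset = "edge"` places an 18 um x 4 um rectangle straddling the upper
#' nuclear boundary (peripheral damage); `preset = "internal"` centres a
#' 6 um x 4 um rectangle inside the nucleus (interior damage).
#'
#' @param nucleus a [synth_nucleus()] result
#' @param preset `"edge"` or `"internal"`
#' @return A [roi_rect()].
#' @export
default_roi <- function(nucleus, preset = c("edge", "internal")) {
  preset <- match.arg(preset)
  px <- nucleus$pixel_size_um
  cy <- nucleus$centroid["row"]; cx <- nucleus$centroid["col"]
  if (preset == "edge") {
    w <- as.integer(floor(18 / px + 0.5)); h <- as.integer(floor(4 / px + 0.5))
    y0 <- as.integer(round(cy - nucleus$semi_axes["row"]))
  } else {
    w <- as.integer(floor(6 / px + 0.5)); h <- as.integer(floor(4 / px + 0.5))
    y0 <- as.integer(round(cy - h / 2))
  }
  x0 <- as.integer(round(cx - w / 2))
  dims <- dim(nucleus$nucleus_mask)
  x0 <- max(0L, min(x0, dims[2] - w)); y0 <- max(0L, min(y0, dims[1] - h))
  roi_rect(x0, y0, w, h)
}

# 8-neighbour local maxima of `img` restricted to `mask` (plateaus count).
local_maxima <- function(img, mask) {
  is_max <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (img >= shift_matrix(img, dr, dc, fill = -Inf))
  }
  is_max
}

# Relax factor of the counterstain mean at time t (t <= 0 -> 1).
relax_factor <- function(t, kin) {
  ifelse(t <= 0, 1,
         1 - kin$relax_amplitude * (1 - exp(-t / kin$t_off_intensity)))
}

# Damage-focus amplitude (0..1 scale) at time t.
focus_amplitude <- function(t, kin) {
  out <- numeric(length(t))
  up <- t > 0 & t <= kin$decay_start_s
  dn <- t > kin$decay_start_s
  out[up] <- 1 - exp(-t[up] / kin$t_on)
  if (any(dn)) {
    peak <- 1 - exp(-kin$decay_start_s / kin$t_on)
    out[dn] <- peak * exp(-(t[dn] - kin$decay_start_s) / kin$t_off_damage)
  }
  out
}

# Blur the rate map and renormalize so the region mean is preserved exactly;
# only the region is replaced, the rest of the map is untouched.
blur_region <- function(rate, region, sigma) {
  if (sigma <= 0) return(rate)
  g <- pmax(as.matrix(EBImage::gblur(rate, sigma = sigma)), 0)
  g <- g * (mean(rate[region]) / mean(g[region]))
  out <- rate
  out[region] <- g[region]
  out
}

# Calibrate the per-frame blur sigma so the *measured* region CV (including
# the Poisson shot-noise term: expected sample variance of counts = spatial
# variance of rates + mean rate) follows
#   CV(t) = CV_inf + (CV_0 - CV_inf) * exp(-t / t_off_cv),
# with CV_0 the measured CV of the unblurred map and
# CV_inf = CV_0 * (1 - relax_amplitude). Returns sigma per post time stamp;
# clamps at the largest calibrated sigma when the target is below the
# shot-noise floor.
calibrate_cv_blur <- function(rate, region, times_post, kin,
                              sigma_grid = c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16)) {
  # the blur kernel must fit inside the frame
  sigma_cap <- (min(dim(rate)) - 1) / 7
  sigma_grid <- sigma_grid[sigma_grid <= sigma_cap]
  m0 <- mean(rate[region])
  spatial_var <- vapply(sigma_grid, function(s) {
    b <- blur_region(rate, region, s)
    mean((b[region] - m0)^2)
  }, numeric(1))
  spatial_var <- cummin(spatial_var)   # enforce monotone decrease for inversion
  cv_meas <- function(v, rf) sqrt(rf^2 * v + rf * m0) / (rf * m0)
  cv0 <- cv_meas(spatial_var[1], 1)
  cv_inf <- cv0 * (1 - kin$relax_amplitude)
  vapply(times_post, function(t) {
    target <- cv_inf + (cv0 - cv_inf) * exp(-t / kin$t_off_cv)
    rf <- relax_factor(t, kin)
    v_req <- ((target * rf * m0)^2 - rf * m0) / rf^2
    if (v_req >= spatial_var[1]) return(0)
    if (v_req <= spatial_var[length(spatial_var)]) return(max(sigma_grid))
    # spatial_var is decreasing in sigma: interpolate on the reversed curve,
    # skipping plateaus introduced by the monotone clamp
    keep <- c(TRUE, diff(spatial_var) < 0)
    stats::approx(rev(spatial_var[keep]), rev(sigma_grid[keep]),
                  xout = v_req)$y
  }, numeric(1))
}

#' Simulate a two-channel damage time-lapse with known ground truth
#'
#' Generates Poisson photon-count frames for a counterstain channel (expected
#' rate = `mean_counts` times the nucleus density map, with post-bleach
#' relaxation inside the irradiated region: multiplicative intensity decay
#' with constant `t_off_intensity` and progressive in-region blurring
#' calibrated so the measured CV decays with constant `t_off_cv`) and a
#' damage-marker channel (uniform nucleoplasmic background plus Gaussian
#' foci placed at local density maxima, preferentially in heterochromatin
#' with probability `damage_bias`, whose amplitude follows a one-phase
#' association with constant `t_on` and decays after `decay_start_s`).
#'
#' @param nucleus a [synth_nucleus()] result
#' @param kinetics a [kinetics_truth()]
#' @param roi irradiation [roi_rect()]; default from [default_roi()]
#' @param schedule an [acq_schedule()]
#' @param damage_bias probability in `[0, 1]` that each focus is drawn from
#'   heterochromatin candidates rather than from all in-region candidates
#' @param mean_counts expected counterstain counts per pixel at the
#'   euchromatin base level
#' @param n_foci number of damage foci
#' @param foci_sigma_px focus Gaussian sigma in pixels
#' @param damage_base_fraction nucleoplasmic damage-channel rate as a
#'   fraction of `mean_counts`
#' @param hoechst_bleach_fraction optional fraction of counterstain signal
#'   lost at bleach (default 0: no photobleaching)
#' @param seed integer seed; identical seeds and parameters give
#'   bit-identical stacks
#' @return An object of class `synthetic_stack`: a list with the
#'   [timelapse_stack()] in `$stack` and the full ground truth (nucleus,
#'   kinetics, ROI, foci coordinates, per-frame expected in-region means and
#'   blur sigmas, seed) in `$truth`.
#' @export
synth_timelapse <- function(nucleus, kinetics = kinetics_truth(),
                            roi = default_roi(nucleus),
                            schedule = acq_schedule(),
                            damage_bias = 0.9, mean_counts = 50,
                            n_foci = 12, foci_sigma_px = 2.5,
                            damage_base_fraction = 0.2,
                            hoechst_bleach_fraction = 0, seed = 1) {
  dims <- dim(nucleus$nucleus_mask)
  region <- roi_mask(roi, dims) & nucleus$nucleus_mask
  if (!any(region)) stopf("ROI does not intersect the nucleus")
  times <- schedule_times(schedule)
  n_frames <- length(times)
  rate_dna0 <- mean_counts * nucleus$chromatin_density_map
  base_damage <- damage_base_fraction * mean_counts

  # foci placement: local maxima of the density map inside the region
  cand <- which(local_maxima(nucleus$chromatin_density_map, region))
  cand_het <- which(local_maxima(nucleus$chromatin_density_map,
                                 region & nucleus$heterochromatin_mask))
  if (!length(cand)) stopf("no candidate focus sites inside ROI and nucleus")

  arr <- array(0, dim = c(dims[1], dims[2], 2L, n_frames))
  truth_sigma <- rep(0, n_frames)

  withr::with_seed(seed, {
    pick_het <- stats::runif(n_foci) < damage_bias & length(cand_het) > 0
    foci_idx <- integer(n_foci)
    if (any(pick_het)) foci_idx[pick_het] <- sample(cand_het, sum(pick_het), replace = TRUE)
    if (any(!pick_het)) foci_idx[!pick_het] <- sample(cand, sum(!pick_het), replace = TRUE)

    impulse <- matrix(0, dims[1], dims[2])
    tab <- table(foci_idx)
    impulse[as.integer(names(tab))] <- as.integer(tab)
    foci_field <- pmax(as.matrix(EBImage::gblur(impulse, sigma = foci_sigma_px)), 0)
    foci_field <- foci_field * 2 * pi * foci_sigma_px^2

    post_sigma <- NULL
    post_idx <- post_bleach_index(schedule)
    if (kinetics$relax_amplitude > 0 && length(post_idx)) {
      post_sigma <- calibrate_cv_blur(rate_dna0, region, times[post_idx], kinetics)
    }

    for (f in seq_len(n_frames)) {
      t <- times[f]
      rate_dna <- rate_dna0
      field_t <- foci_field
      if (t > 0) {
        if (kinetics$relax_amplitude > 0) {
          s <- post_sigma[match(f, post_idx)]
          truth_sigma[f] <- s
          rate_dna <- blur_region(rate_dna0, region, s)
          # the recruited signal redistributes with the relaxing chromatin:
          # mass-conserving spread of the focal pattern with the same sigma
          if (s > 0) {
            field_t <- pmax(as.matrix(EBImage::gblur(foci_field, sigma = s)), 0)
            # conserve the in-region focal mass so the region-mean trace
            # follows the association kinetics exactly
            leak <- sum(field_t[region])
            if (leak > 0) field_t <- field_t * (sum(foci_field[region]) / leak)
          }
        }
        rf <- relax_factor(t, kinetics)
        rate_dna[region] <- rate_dna[region] * rf
        if (hoechst_bleach_fraction > 0) {
          rate_dna <- rate_dna * (1 - hoechst_bleach_fraction)
        }
      }
      amp <- focus_amplitude(t, kinetics)
      rate_dmg <- base_damage * nucleus$nucleus_mask +
        amp * kinetics$recruit_amplitude * mean_counts * field_t
      arr[, , 1, f] <- matrix(stats::rpois(length(rate_dmg), pmax(rate_dmg, 0)),
                              dims[1], dims[2])
      arr[, , 2, f] <- matrix(stats::rpois(length(rate_dna), pmax(rate_dna, 0)),
                              dims[1], dims[2])
    }
  })

  stack <- timelapse_stack(arr, times, nucleus$pixel_size_um,
                           c(damage = 1L, dna = 2L))
  foci_rc <- arrayInd(foci_idx, dims)
  truth <- list(nucleus = nucleus, kinetics = kinetics, roi = roi,
                schedule = schedule, damage_bias = damage_bias,
                mean_counts = mean_counts,
                foci = data.frame(row = foci_rc[, 1], col = foci_rc[, 2]),
                blur_sigma = truth_sigma, seed = seed)
  structure(list(stack = stack, truth = truth, seed = seed),
            class = "synthetic_stack")
}

#' @export
print.synthetic_stack <- function(x, ...) {
  cat("Synthetic damage time-lapse (seed ", x$seed, ")\n", sep = "")
  print(x$stack)
  k <- x$truth$kinetics
  cat(sprintf("  truth: t_on %.3g s, t_off(int) %.3g s, t_off(cv) %.3g s, relax %.2g, %d foci\n",
              k$t_on, k$t_off_intensity, k$t_off_cv, k$relax_amplitude,
              nrow(x$truth$foci)))
  invisible(x)
}

#' Write a synthetic stack plus its ground truth to disk
#'
#' Writes the stack via [write_stack_tiff()], the nucleus/heterochromatin
#' masks as label TIFF, and the full truth record (kinetics, ROI, foci,
#' seed) as a JSON sidecar.
#'
#' @param sim a [synth_timelapse()] result
#' @param prefix output path prefix
#' @export
write_synthetic <- function(sim, prefix) {
  files <- write_stack_tiff(sim$stack, prefix)
  nmask <- sim$truth$nucleus$nucleus_mask
  hmask <- sim$truth$nucleus$heterochromatin_mask
  write_mask_tiff(list(nmask * 1L), sprintf("%s_nucleus_mask.tif", prefix))
  write_mask_tiff(list(hmask * 1L), sprintf("%s_hetero_mask.tif", prefix))
  tr <- sim$truth
  truth_json <- list(
    kinetics = unclass(tr$kinetics), roi = unclass(tr$roi),
    schedule = unclass(tr$schedule), damage_bias = tr$damage_bias,
    mean_counts = tr$mean_counts, foci = tr$foci,
    blur_sigma = tr$blur_sigma, seed = tr$seed)
  jsonlite::write_json(truth_json, sprintf("%s_truth.json", prefix),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Study-condition presets for desk-scale simulations
#'
#' Builds a complete synthetic experiment for one of two regimes:
#' `"control"` (fast recruitment, chromatin relaxation on) or
#' `"parp_inhibited"` (slow recruitment, sustained foci, relaxation off),
#' using the interior-damage geometry (6 um x 4 um ROI) on a reduced frame
#' so ensembles run quickly.
#'
#' @param seed integer seed
#' @param condition `"control"` or `"parp_inhibited"`
#' @param shape frame size in pixels
#' @param kinetics optional [kinetics_truth()] overriding the preset
#' @return A [synth_timelapse()] result.
#' @export
synth_condition <- function(seed = 1, condition = c("control", "parp_inhibited"),
                            shape = c(192, 192), kinetics = NULL) {
  condition <- match.arg(condition)
  nuc <- synth_nucleus(shape = shape, n_blobs = round(prod(shape) / 1750),
                       blob_sigma_px = 3, contrast = 3, seed = seed)
  if (is.null(kinetics)) {
    kinetics <- if (condition == "control") {
      kinetics_truth(t_on = 6, t_off_intensity = 30, t_off_cv = 30,
                     relax_amplitude = 0.3, recruit_amplitude = 2,
                     decay_start_s = 53.6)
    } else {
      kinetics_truth(t_on = 18, t_off_intensity = 30, t_off_cv = 30,
                     relax_amplitude = 0, recruit_amplitude = 2,
                     decay_start_s = Inf)
    }
  }
  synth_timelapse(nuc, kinetics, roi = default_roi(nuc, "internal"),
                  damage_bias = 0.9, seed = seed)
}
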