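#' Mask-restricted spatial correlation surface
#'
#' Computes the normalized spatial (cross-)correlation of two images over a
#' region of analysis:
#' \deqn{G(\xi,\eta) = \frac{\langle \delta a\,\delta b\rangle(\xi,\eta)}
#'                          {\langle a\rangle_M \langle b\rangle_M}}
#' where fluctuations \eqn{\delta x = x - \langle x\rangle_M} are taken about
#' the in-mask means, set to zero outside the mask, and the lagged product
#' sum is divided by the number of in-mask pixel pairs at that lag (obtained
#' from the mask's own correlation). With `img_a = img_b` this is the
#' autocorrelation function (ACF); otherwise the cross-correlation function
#' (CCF). Computed by zero-padded FFT, so no wrap-around pairs contribute.
#'
#' @param img_a,img_b numeric matrices of identical shape
#' @param mask logical/integer matrix; pixels > 0 define the region
#' @param max_lag largest lag (pixels) in each direction
#' @param min_mask_px minimum region size; smaller masks refuse analysis
#' @return An object of class `corr_surface`: `values` ((2L+1) x (2L+1)
#'   matrix, NA where no pixel pairs exist), `lags_px`, `n_pairs`, and the
#'   in-mask means `mean_a`, `mean_b`.
#' @export
masked_correlation <- function(img_a, img_b, mask, max_lag = 32,
                               min_mask_px = 100) {
  if (!all(dim(img_a) == dim(img_b)) || !all(dim(img_a) == dim(mask))) {
    stopf("images and mask must share one shape")
  }
  m <- mask > 0
  n_px <- sum(m)
  if (n_px < min_mask_px) {
    stopf("mask has %d pixels; at least %d required", n_px, min_mask_px)
  }
  mean_a <- mean(img_a[m]); mean_b <- mean(img_b[m])
  if (mean_a == 0 || mean_b == 0) stopf("zero in-mask mean: normalization undefined")

  # crop to the mask bounding box (plus lag margin) to keep FFTs small
  rr <- range(which(rowSums(m) > 0)); cr <- range(which(colSums(m) > 0))
  m2 <- m[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  da <- (img_a[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE] - mean_a) * m2
  db <- (img_b[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE] - mean_b) * m2

  L <- as.integer(max_lag)
  pr <- stats::nextn(nrow(m2) + L, c(2, 3)); pc <- stats::nextn(ncol(m2) + L, c(2, 3))
  pad <- function(x) { out <- matrix(0, pr, pc); out[seq_len(nrow(x)), seq_len(ncol(x))] <- x; out }
  # lagged product sum: S(l) = sum_x a(x) b(x + l), via conjugate FFT product
  xcorr <- function(a, b) {
    fa <- stats::fft(pad(a)); fb <- stats::fft(pad(b))
    Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / (pr * pc)
  }
  num <- xcorr(da, db)
  cnt <- xcorr(m2 * 1, m2 * 1)

  # gather circular-indexed lags -L..L into a centered matrix
  idx <- function(l, n) ((l %% n) + 1L)
  lags <- -L:L
  values <- matrix(NA_real_, 2 * L + 1, 2 * L + 1)
  n_pairs <- matrix(0, 2 * L + 1, 2 * L + 1)
  for (i in seq_along(lags)) {
    ri <- idx(lags[i], pr)
    cc <- cnt[ri, idx(lags, pc)]
    nm <- num[ri, idx(lags, pc)]
    cc <- round(cc)
    good <- cc > 0
    n_pairs[i, ] <- cc
    values[i, good] <- (nm[good] / cc[good]) / (mean_a * mean_b)
  }
  structure(list(values = values, lags_px = lags, n_pairs = n_pairs,
                 mean_a = mean_a, mean_b = mean_b, mask_px = n_px),
            class = "corr_surface")
}

#' @export
print.corr_surface <- function(x, ...) {
  L <- max(x$lags_px)
  g0 <- x$values[L + 1, L + 1]
  cat(sprintf("Correlation surface: lags +/-%d px, %d mask px, G(0,0) = %.4g\n",
              L, x$mask_px, g0))
  invisible(x)
}

# Radially average a correlation surface, grouping lags of equal radius.
radial_average <- function(surface) {
  L <- max(surface$lags_px)
  r <- sqrt(outer(surface$lags_px^2, surface$lags_px^2, "+"))
  ok <- is.finite(surface$values) & r <= L
  key <- round(r[ok], 9)
  g <- tapply(surface$values[ok], key, mean)
  out <- data.frame(r = as.numeric(names(g)), g = as.numeric(g))
  out[order(out$r), ]
}

#' Fit the zero-lag amplitude of a correlation surface
#'
#' Radially averages the surface and fits a Gaussian decay
#' \eqn{g(r) = g_0 \exp(-r^2/w^2) + c} by nonlinear least squares. With
#' `exclude_zero_lag` the r = 0 bin is omitted so the amplitude is the
#' extrapolation of the correlated structure to zero lag, free of the
#' uncorrelated shot-noise spike that detectors add only at r = 0. Negative
#' amplitudes (anti-correlation) are allowed.
#'
#' @param surface a [masked_correlation()] result
#' @param exclude_zero_lag drop the r = 0 bin before fitting
#' @param max_fit_lag largest radius included in the fit (default: all)
#' @return An object of class `corr_fit`: `g0`, `width_px`, `offset`,
#'   `success`, `residual_rms`.
#' @export
fit_amplitude <- function(surface, exclude_zero_lag = TRUE, max_fit_lag = NULL) {
  prof <- radial_average(surface)
  if (!is.null(max_fit_lag)) prof <- prof[prof$r <= max_fit_lag, ]
  if (exclude_zero_lag) prof <- prof[prof$r > 0, ]
  fail <- function() structure(list(g0 = NA_real_, width_px = NA_real_,
                                    offset = NA_real_, success = FALSE,
                                    residual_rms = NA_real_), class = "corr_fit")
  if (nrow(prof) < 4) return(fail())
  g0_init <- prof$g[1] - prof$g[nrow(prof)]
  if (!is.finite(g0_init) || g0_init == 0) g0_init <- prof$g[1]
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ g0 * exp(-(r / w)^2) + c0, data = prof,
                      start = list(g0 = g0_init, w = 4,
                                   c0 = mean(utils::tail(prof$g, 5))),
                      lower = c(-Inf, 0.3, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  p <- stats::coef(fit)
  structure(list(g0 = unname(p["g0"]), width_px = unname(p["w"]),
                 offset = unname(p["c0"]), success = TRUE,
                 residual_rms = sqrt(mean(stats::resid(fit)^2))),
            class = "corr_fit")
}

#' @export
print.corr_fit <- function(x, ...) {
  if (x$success) {
    cat(sprintf("Correlation fit: g0 = %.4g, width = %.3g px, offset = %.3g (rms %.2g)\n",
                x$g0, x$width_px, x$offset, x$residual_rms))
  } else cat("Correlation fit: failed\n")
  invisible(x)
}

#' Cross-correlation colocalization fractions
#'
#' The colocalized fraction of channel 1 is the ratio of the CCF zero-lag
#' amplitude to the fitted (zero-lag-extrapolated) ACF amplitude of channel
#' 2, and vice versa:
#' \deqn{f_1 = G_{cc}(0) / G_{ac,2}(0), \qquad f_2 = G_{cc}(0) / G_{ac,1}(0).}
#' The CCF central value is used as measured (shot noise is uncorrelated
#' between detectors, so it carries no spike), optionally smoothed over the
#' central 3 x 3 lags; ACF amplitudes come from [fit_amplitude()] with the
#' r = 0 bin excluded. Results are clipped to `[-1, 1]`: 1 is complete
#' colocalization, 0 none, -1 complete anti-correlation.
#'
#' @inheritParams masked_correlation
#' @param ch1,ch2 the two channel images
#' @param smooth_ccf average the CCF over the central 3 x 3 lags
#' @return An object of class `coloc_fractions`: `f1`, `f2`, `gcc0`,
#'   `gac1_0`, `gac2_0`, `valid`.
#' @export
coloc_fractions <- function(ch1, ch2, mask, max_lag = 32, min_mask_px = 100,
                            smooth_ccf = FALSE) {
  cc <- masked_correlation(ch1, ch2, mask, max_lag, min_mask_px)
  a1 <- masked_correlation(ch1, ch1, mask, max_lag, min_mask_px)
  a2 <- masked_correlation(ch2, ch2, mask, max_lag, min_mask_px)
  L <- max(cc$lags_px); ctr <- L + 1
  gcc0 <- if (smooth_ccf) {
    mean(cc$values[ctr + (-1:1), ctr + (-1:1)], na.rm = TRUE)
  } else cc$values[ctr, ctr]
  f1a <- fit_amplitude(a1); f2a <- fit_amplitude(a2)
  valid <- f1a$success && f2a$success &&
    is.finite(f1a$g0) && is.finite(f2a$g0) && f1a$g0 > 0 && f2a$g0 > 0
  clip <- function(x) max(-1, min(1, x))
  out <- list(f1 = NA_real_, f2 = NA_real_, gcc0 = gcc0,
              gac1_0 = f1a$g0, gac2_0 = f2a$g0, valid = valid)
  if (valid) {
    out$f1 <- clip(gcc0 / f2a$g0)
    out$f2 <- clip(gcc0 / f1a$g0)
  }
  structure(out, class = "coloc_fractions")
}

#' @export
print.coloc_fractions <- function(x, ...) {
  cat(sprintf("Colocalization fractions: f1 = %.3f, f2 = %.3f (%s)\n",
              x$f1, x$f2, if (x$valid) "valid" else "invalid"))
  invisible(x)
}

# Keep only the largest labelled object of a damage-area mask frame.
largest_object <- function(lab) {
  if (max(lab) <= 1) return(lab > 0)
  areas <- tabulate(lab[lab > 0])
  lab == which.max(areas)
}

#' Per-frame colocalization fractions over a time-lapse
#'
#' Runs [coloc_fractions()] of (damage channel, DNA channel) within each
#' post-bleach frame's damage-area mask (largest object when several nuclei
#' intersect the ROI). Pre-bleach frames and frames whose mask is too small
#' or whose fits fail carry `NA`, never zeros.
#'
#' @param stack a [timelapse_stack()] with both channel roles
#' @param damage_area_masks list of label matrices from [damage_area_mask()]
#' @inheritParams coloc_fractions
#' @return `data.frame` with columns `frame`, `time_s`, `f1`, `f2`, `valid`.
#' @export
timelapse_iccs <- function(stack, damage_area_masks, max_lag = 32,
                           min_mask_px = 100, smooth_ccf = FALSE) {
  n_frames <- dim(stack$data)[4]
  if (length(damage_area_masks) != n_frames) stopf("masks must align with frames")
  res <- data.frame(frame = seq_len(n_frames), time_s = stack$time_s,
                    f1 = NA_real_, f2 = NA_real_, valid = FALSE)
  for (f in which(stack$time_s > 0)) {
    m <- largest_object(damage_area_masks[[f]])
    if (sum(m) < min_mask_px) next
    cf <- tryCatch(
      coloc_fractions(stack_frame(stack, "damage", f),
                      stack_frame(stack, "dna", f), m,
                      max_lag, min_mask_px, smooth_ccf),
      error = function(e) NULL)
    if (!is.null(cf) && cf$valid) {
      res$f1[f] <- cf$f1; res$f2[f] <- cf$f2; res$valid[f] <- TRUE
    }
  }
  res
}
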