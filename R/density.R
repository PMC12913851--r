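#' Max-normalized DNA intensity image
#'
#' Divides a (background-subtracted) DNA-channel frame by its maximum over
#' the nucleus mask, giving values in `[0, 1]` inside the nucleus; pixels
#' outside the mask are set to `NA`. The normalizing maximum is taken from
#' the mask only, so bright pixels outside the nucleus cannot affect it.
#'
#' @param dna_frame numeric matrix
#' @param nucleus_mask logical/integer matrix; pixels > 0 define the nucleus
#' @return Matrix in `[0, 1]` inside the mask, `NA` outside.
#' @export
normalized_dna_image <- function(dna_frame, nucleus_mask) {
  m <- nucleus_mask > 0
  if (!any(m)) stopf("nucleus mask is empty")
  imax <- max(dna_frame[m])
  if (imax <= 0) stopf("in-mask maximum is not positive: normalization undefined")
  out <- dna_frame / imax
  out[!m] <- NA_real_
  out
}

#' DNA density at damage foci
#'
#' Mean of the max-normalized DNA intensity over the intersection of the
#' nucleus mask and the damage-foci mask — a chromatin-compaction readout:
#' values near 1 indicate damage on the densest (heterochromatic) pixels,
#' low values indicate euchromatic localization.
#'
#' @inheritParams normalized_dna_image
#' @param foci_mask logical matrix of damage-foci pixels
#' @return Scalar in `[0, 1]`, or `NA` with attribute `empty = TRUE` when
#'   the intersection is empty.
#' @export
dna_density <- function(dna_frame, nucleus_mask, foci_mask) {
  region <- (nucleus_mask > 0) & (foci_mask > 0)
  if (!any(region)) {
    out <- NA_real_
    attr(out, "empty") <- TRUE
    return(out)
  }
  norm <- normalized_dna_image(dna_frame, nucleus_mask)
  mean(norm[region])
}

#' Region mean, standard deviation and coefficient of variation
#'
#' Population (divide-by-n) statistics of the intensity over a region; the
#' coefficient of variation CV = sigma / mu measures staining heterogeneity
#' (high in compact, textured chromatin; low after relaxation).
#'
#' @param frame numeric matrix
#' @param mask logical/integer matrix; pixels > 0 define the region (>= 2)
#' @return Named list `mean`, `sd`, `cv` (`cv` is `NA` when the mean is 0).
#' @export
roi_stats <- function(frame, mask) {
  v <- frame[mask > 0]
  if (length(v) < 2) stopf("region must contain at least 2 pixels")
  mu <- mean(v); sdv <- pop_sd(v)
  list(mean = mu, sd = sdv, cv = if (mu == 0) NA_real_ else sdv / mu)
}

#' Normalize a metric trace to a reference point
#'
#' `mode = "first_post"` divides by the value at the first time stamp > 0
#' (first post-bleach frame); `mode = "peak"` divides by the trace maximum.
#' `NA` entries are carried through.
#'
#' @param series numeric vector
#' @param time_s matching time stamps (t = 0 at bleach onset)
#' @param mode `"first_post"` or `"peak"`
#' @return Normalized numeric vector.
#' @export
normalize_trace <- function(series, time_s, mode = c("first_post", "peak")) {
  mode <- match.arg(mode)
  if (length(series) != length(time_s)) stopf("series and time_s must align")
  ref <- if (mode == "first_post") {
    post <- which(time_s > 0)
    if (!length(post)) stopf("no post-bleach frames")
    series[post[1]]
  } else {
    max(series, na.rm = TRUE)
  }
  if (!is.finite(ref) || ref <= 0) stopf("normalization reference must be positive")
  series / ref
}
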