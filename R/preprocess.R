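#' Iterative intermeans (isodata) threshold
#'
#' Classic histogram threshold: starting from the image mean, alternate
#' between computing the means of pixels below/above the current threshold
#' and resetting the threshold to their average, until convergence. This is
#' the default automatic threshold of common bioimage tools.
#'
#' @param img numeric matrix
#' @param tol convergence tolerance
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
isodata_threshold <- function(img, tol = 1e-6) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  if (!length(v) || max(v) == min(v)) return(max(v, 0))
  thr <- mean(v)
  for (i in 1:500) {
    lo <- v[v <= thr]; hi <- v[v > thr]
    if (!length(hi) || !length(lo)) break
    new <- (mean(lo) + mean(hi)) / 2
    if (abs(new - thr) < tol) { thr <- new; break }
    thr <- new
  }
  thr
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged afterwards with a small union-find.
label_components <- function(mask, connectivity = 8) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  n <- max(lab)
  if (connectivity == 8 && n > 1) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (d in list(c(1, 1), c(1, -1))) {
      s <- shift_matrix(lab, d[1], d[2], fill = 0)
      touch <- lab > 0 & s > 0 & lab != s
      if (any(touch)) {
        pairs <- unique(cbind(lab[touch], s[touch]))
        for (k in seq_len(nrow(pairs))) {
          a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
          if (a != b) parent[b] <- a
        }
      }
    }
    root <- vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

#' Segment nuclei in the counterstain channel of a time-lapse
#'
#' Per frame: isodata threshold on the DNA channel, 8-connected labelling of
#' the binary image, removal of objects below `min_area` pixels, then linking
#' of object identity across frames by maximal centroid-region overlap so
#' each nucleus keeps one label through time (a per-frame count mask).
#'
#' @param stack a [timelapse_stack()] with a `"dna"` channel role
#' @param min_area minimum object area in pixels
#' @param connectivity 4 or 8 (default 8)
#' @return List of integer label matrices, one per frame; an all-zero frame
#'   yields an all-zero mask.
#' @export
segment_nuclei <- function(stack, min_area = 500, connectivity = 8) {
  if (!has_role(stack, "dna")) stopf("stack has no 'dna' channel role")
  n_frames <- dim(stack$data)[4]
  masks <- vector("list", n_frames)
  ref <- NULL
  for (f in seq_len(n_frames)) {
    img <- stack_frame(stack, "dna", f)
    if (all(img == 0)) { masks[[f]] <- matrix(0L, nrow(img), ncol(img)); next }
    thr <- isodata_threshold(img)
    lab <- label_components(img > thr, connectivity)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0])
      keep <- which(areas >= min_area)
      lab[!(lab %in% keep)] <- 0L
      lab[lab > 0] <- match(lab[lab > 0], keep)
    }
    if (!is.null(ref) && max(lab) > 0 && max(ref) > 0) {
      lab <- link_labels(ref, lab)
    }
    masks[[f]] <- lab
    if (max(lab) > 0) ref <- lab
  }
  masks
}

# Relabel `cur` so each object takes the label of the `prev` object it
# overlaps most; objects with no overlap get fresh labels above max(prev).
link_labels <- function(prev, cur) {
  out <- matrix(0L, nrow(cur), ncol(cur))
  next_label <- max(prev) + 1L
  for (k in sort(unique(cur[cur > 0]))) {
    sel <- cur == k
    hits <- prev[sel]
    hits <- hits[hits > 0]
    if (length(hits)) {
      out[sel] <- as.integer(names(which.max(table(hits))))
    } else {
      out[sel] <- next_label
      next_label <- next_label + 1L
    }
  }
  out
}

#' Restrict nucleus count masks to the irradiated ROI
#'
#' Per frame, keeps labels only inside the ROI rectangle (the damage-area
#' count mask: the irradiated part of each nucleus). An empty intersection
#' yields an all-zero frame.
#'
#' @param nuclei list of label matrices from [segment_nuclei()]
#' @param roi a [roi_rect()]
#' @return List of label matrices.
#' @export
damage_area_mask <- function(nuclei, roi) {
  dims <- dim(nuclei[[1]])
  rm_ <- roi_mask(roi, dims)   # errors if ROI is outside the frame
  lapply(nuclei, function(lab) {
    out <- lab
    out[!rm_] <- 0L
    out
  })
}

#' Damage-foci binary mask at a fraction of the frame maximum
#'
#' Marks pixels whose intensity is at least `fraction` times the per-frame
#' maximum of the damage channel (default 80 percent). For an all-zero frame
#' the mask is empty and the result carries attribute `undefined = TRUE`
#' rather than raising an error, so time-series processing continues.
#'
#' @param damage_frame numeric matrix
#' @param fraction threshold fraction of the maximum, in (0, 1]
#' @return Logical matrix; attribute `undefined` flags the degenerate case.
#' @export
foci_mask <- function(damage_frame, fraction = 0.8) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  mx <- max(damage_frame)
  if (mx <= 0) {
    out <- matrix(FALSE, nrow(damage_frame), ncol(damage_frame))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- damage_frame >= fraction * mx
  attr(out, "undefined") <- FALSE
  out
}

# 3x3 (or k x k) mean filter with edge replication.
mean_filter <- function(img, k = 3) {
  if (k <= 1) return(img)
  f <- matrix(1 / (k * k), k, k)
  as.matrix(EBImage::filter2(img, f, boundary = "replicate"))
}

# Rolling-ball background estimate. For large radii the image is shrunk
# (block minimum), a non-flat ball-cap grayscale opening is applied at the
# reduced radius, and the background is enlarged back by bilinear resize —
# the standard large-radius strategy of the original algorithm.
rolling_ball_background <- function(img, radius) {
  shrink <- if (radius <= 16) 1L else as.integer(max(2, floor(radius / 16)))
  small <- if (shrink > 1L) block_reduce_min(img, shrink) else img
  rb <- max(radius / shrink, 1)
  # ball cap height profile over integer offsets within the radius
  off <- expand.grid(dr = -floor(rb):floor(rb), dc = -floor(rb):floor(rb))
  d2 <- off$dr^2 + off$dc^2
  keep <- d2 <= rb^2
  off <- off[keep, ]; z <- sqrt(rb^2 - d2[keep])
  erode <- matrix(Inf, nrow(small), ncol(small))
  for (i in seq_len(nrow(off))) {
    erode <- pmin(erode, shift_matrix(small, off$dr[i], off$dc[i], fill = Inf) - z[i])
  }
  dilate <- matrix(-Inf, nrow(small), ncol(small))
  for (i in seq_len(nrow(off))) {
    dilate <- pmax(dilate, shift_matrix(erode, off$dr[i], off$dc[i], fill = -Inf) + z[i])
  }
  bg <- dilate
  if (shrink > 1L) {
    bg <- as.matrix(EBImage::resize(bg, w = nrow(img), h = ncol(img)))
  }
  pmin(bg, img)
}

# Block minimum for shrink-before-rolling; pads the border blocks.
block_reduce_min <- function(img, s) {
  nr <- ceiling(nrow(img) / s); nc <- ceiling(ncol(img) / s)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    rs <- ((i - 1) * s + 1):min(i * s, nrow(img))
    for (j in seq_len(nc)) {
      cs <- ((j - 1) * s + 1):min(j * s, ncol(img))
      out[i, j] <- min(img[rs, cs])
    }
  }
  out
}

#' Smooth and background-subtract the counterstain channel
#'
#' Reproduces the standard intensity-image preparation: each DNA-channel
#' frame is mean-smoothed (default 3 x 3) and a rolling-ball background
#' (default radius 100 px, roughly the largest heterochromatin feature) is
#' subtracted; results are clipped at zero. Other channels pass through
#' unchanged.
#'
#' @param stack a [timelapse_stack()]
#' @param smooth_px mean-filter kernel size in pixels (odd; 1 disables)
#' @param rolling_ball_px rolling-ball radius in pixels
#' @return A real-valued [timelapse_stack()] of the same shape.
#' @export
subtract_background <- function(stack, smooth_px = 3, rolling_ball_px = 100) {
  if (rolling_ball_px <= 0) stopf("rolling-ball radius must be positive")
  dims <- dim(stack$data)
  if (rolling_ball_px > max(dims[1:2])) {
    stopf("rolling-ball radius exceeds the frame size")
  }
  out <- stack
  ch <- stack$channel_roles[["dna"]]
  for (f in seq_len(dims[4])) {
    img <- mean_filter(stack$data[, , ch, f], smooth_px)
    bg <- rolling_ball_background(img, rolling_ball_px)
    out$data[, , ch, f] <- pmax(img - bg, 0)
  }
  out
}
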