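#' Two-channel time-lapse stack
#'
#' Container for a confocal time-lapse: a 4-D array of photon counts indexed
#' `[row, col, channel, frame]`, per-frame time stamps in seconds (t = 0 at
#' bleach onset), the pixel size in micrometres and the mapping from channel
#' roles to array indices. Role `"damage"` is the DNA-damage marker channel
#' (e.g. a PARP1 fusion), role `"dna"` the DNA counterstain (e.g. Hoechst).
#' Single-channel (counterstain only) stacks assign only the `"dna"` role.
#'
#' @param data numeric array `[row, col, channel, frame]`, non-negative
#' @param time_s numeric vector of frame time stamps, strictly increasing
#' @param pixel_size_um pixel size in micrometres
#' @param channel_roles named integer vector mapping roles (`"damage"`,
#'   `"dna"`) to channel indices
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(data, time_s, pixel_size_um = 0.072,
                            channel_roles = c(damage = 1L, dna = 2L)) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (length(dim(data)) != 4L) stopf("data must be a [row, col, channel, frame] array")
  if (any(data < 0, na.rm = TRUE)) stopf("pixel values must be non-negative")
  if (length(time_s) != dim(data)[4]) stopf("time_s length must equal the frame count")
  if (any(diff(time_s) <= 0)) stopf("time stamps must be strictly increasing")
  if (!all(names(channel_roles) %in% c("damage", "dna")) || is.null(names(channel_roles))) {
    stopf("channel_roles must be named with roles 'damage' and/or 'dna'")
  }
  if (any(channel_roles < 1 | channel_roles > dim(data)[3])) {
    stopf("channel role index out of range")
  }
  structure(list(data = data, time_s = as.numeric(time_s),
                 pixel_size_um = pixel_size_um,
                 channel_roles = channel_roles),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Time-lapse stack: %d x %d px, %d channel(s), %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel size %.3g um; t in [%.4g, %.4g] s; roles: %s\n",
              x$pixel_size_um, min(x$time_s), max(x$time_s),
              paste(sprintf("%s=%d", names(x$channel_roles), x$channel_roles),
                    collapse = ", ")))
  invisible(x)
}

# Extract one channel frame as a matrix, by role.
stack_frame <- function(stack, role, frame) {
  idx <- stack$channel_roles[[role]]
  stack$data[, , idx, frame]
}

has_role <- function(stack, role) role %in% names(stack$channel_roles)

#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle: columns `x0 .. x0+width-1`, rows
#' `y0 .. y0+height-1` (x along columns, y along rows).
#'
#' @param x0,y0 top-left corner (0-based pixels)
#' @param width,height extent in pixels (> 0)
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(x0, y0, width, height) {
  v <- c(x0, y0, width, height)
  if (any(v != round(v)) || x0 < 0 || y0 < 0 || width <= 0 || height <= 0) {
    stopf("roi_rect requires non-negative integer origin and positive size")
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_rect")
}

#' Physical-size ROI
#'
#' Converts an ROI given in micrometres to pixels (round-half-up) at a stated
#' pixel size. The defaults give the 18 um x 4 um irradiation rectangle used
#' for edge-of-nucleus damage; `width_um = 6` gives the internal-ROI preset.
#'
#' @param x0,y0 top-left corner in pixels
#' @param width_um,height_um extent in micrometres
#' @param pixel_size_um pixel size in micrometres
#' @export
roi_rect_um <- function(x0, y0, width_um = 18, height_um = 4,
                        pixel_size_um = 0.072) {
  px <- function(um) as.integer(floor(um / pixel_size_um + 0.5))
  roi_rect(x0, y0, px(width_um), px(height_um))
}

# Logical matrix marking the ROI within a frame of the given dimensions.
roi_mask <- function(roi, dim_px) {
  stopifnot(inherits(roi, "roi_rect"))
  if (roi$x0 + roi$width > dim_px[2] || roi$y0 + roi$height > dim_px[1]) {
    stopf("ROI extends outside the frame")
  }
  m <- matrix(FALSE, dim_px[1], dim_px[2])
  m[roi$y0 + seq_len(roi$height), roi$x0 + seq_len(roi$width)] <- TRUE
  m
}

#' Write a time-lapse stack to multi-page TIFF
#'
#' Writes one 16-bit multi-page TIFF per channel
#' (`<prefix>_ch<k>.tif`) plus a JSON sidecar `<prefix>_meta.json` with time
#' stamps, pixel size and channel roles. Counts are stored as integers in
#' 16-bit range.
#'
#' @param stack a [timelapse_stack()]
#' @param prefix output path prefix
#' @return Invisibly, the vector of files written.
#' @export
write_stack_tiff <- function(stack, prefix) {
  d <- dim(stack$data)
  files <- character(0)
  for (ch in seq_len(d[3])) {
    pages <- lapply(seq_len(d[4]), function(f) {
      m <- stack$data[, , ch, f]
      m[m > 65535] <- 65535
      m / 65535   # tiff package stores [0,1] scaled to bits.per.sample
    })
    path <- sprintf("%s_ch%d.tif", prefix, ch)
    tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
    files <- c(files, path)
  }
  meta <- list(time_s = stack$time_s, pixel_size_um = stack$pixel_size_um,
               channel_roles = as.list(stack$channel_roles), n_frames = d[4],
               shape_px = d[1:2])
  meta_path <- sprintf("%s_meta.json", prefix)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta_path))
}

#' Read a time-lapse stack written by [write_stack_tiff()]
#'
#' @param prefix path prefix used when writing
#' @return A [timelapse_stack()].
#' @export
read_stack_tiff <- function(prefix) {
  meta <- jsonlite::read_json(sprintf("%s_meta.json", prefix), simplifyVector = TRUE)
  chans <- sort(Sys.glob(sprintf("%s_ch*.tif", prefix)))
  if (!length(chans)) stopf("no channel TIFFs found for prefix %s", prefix)
  read_ch <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, function(p) round(p * 65535))
  }
  per_ch <- lapply(chans, read_ch)
  nr <- nrow(per_ch[[1]][[1]]); nc <- ncol(per_ch[[1]][[1]])
  nf <- length(per_ch[[1]])
  arr <- array(0, dim = c(nr, nc, length(per_ch), nf))
  for (ch in seq_along(per_ch)) {
    for (f in seq_len(nf)) arr[, , ch, f] <- per_ch[[ch]][[f]]
  }
  roles <- unlist(meta$channel_roles)
  timelapse_stack(arr, meta$time_s, meta$pixel_size_um, roles)
}

#' Write a label- or binary-mask sequence as multi-page TIFF
#'
#' Labels are stored as 16-bit integers (label / 65535 scaling of the tiff
#' package is undone on read by [read_mask_tiff()]).
#'
#' @param masks list of integer/logical matrices (one per frame)
#' @param path output file
#' @export
write_mask_tiff <- function(masks, path) {
  pages <- lapply(masks, function(m) {
    m <- pmin(as.matrix(m) * 1, 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) round(p * 65535))
}
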