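#' Acquisition schedule for a bleach time-lapse
#'
#' Describes a pre-bleach / bleach / post-bleach confocal time-lapse in the
#' convention where the start of micro-irradiation defines \eqn{t = 0}.
#' Pre-bleach frames carry negative time stamps; bleach iterations expose the
#' sample but emit no analyzed frames; the first post-bleach frame is stamped
#' at the end of the bleach exposure.
#'
#' The defaults reproduce a standard recruitment-imaging protocol:
#' 5 pre-bleach frames at 1.3 s, 2 bleach iterations of 1.3 s (2.6 s total
#' exposure) and 50 post-bleach frames at 3 s, so the first post-bleach frame
#' falls at 2.6 s and the last at 149.6 s.
#'
#' @param n_pre number of pre-bleach frames (>= 0)
#' @param dt_pre seconds per pre-bleach frame (> 0)
#' @param n_bleach number of bleach iterations (>= 0); dead time, no frames
#' @param dt_bleach seconds per bleach iteration (> 0)
#' @param n_post number of post-bleach frames (>= 0)
#' @param dt_post seconds per post-bleach frame (> 0)
#' @return An object of class `acq_schedule`.
#' @examples
#' sch <- acq_schedule()
#' schedule_times(sch)[6]   # 2.6 s, first post-bleach frame
#' @export
acq_schedule <- function(n_pre = 5, dt_pre = 1.3,
                         n_bleach = 2, dt_bleach = 1.3,
                         n_post = 50, dt_post = 3) {
  counts <- c(n_pre = n_pre, n_bleach = n_bleach, n_post = n_post)
  dts <- c(dt_pre = dt_pre, dt_bleach = dt_bleach, dt_post = dt_post)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("schedule counts must be non-negative integers")
  }
  if (any(!is.finite(dts)) || any(dts <= 0)) {
    stopf("schedule intervals must be positive")
  }
  structure(list(n_pre = as.integer(n_pre), dt_pre = dt_pre,
                 n_bleach = as.integer(n_bleach), dt_bleach = dt_bleach,
                 n_post = as.integer(n_post), dt_post = dt_post),
            class = "acq_schedule")
}

#' Frame time stamps of an acquisition schedule
#'
#' Emits one stamp per analyzed frame (`n_pre + n_post` in total): pre-bleach
#' frames end at `-dt_pre` and step back by `dt_pre`; the bleach occupies
#' `[0, n_bleach * dt_bleach)` without emitting frames; post-bleach frames
#' start at `n_bleach * dt_bleach` and step by `dt_post`.
#'
#' @param schedule an [acq_schedule()]
#' @return Numeric vector of time stamps in seconds, strictly increasing.
#' @export
schedule_times <- function(schedule) {
  stopifnot(inherits(schedule, "acq_schedule"))
  pre <- if (schedule$n_pre > 0) -rev(seq_len(schedule$n_pre)) * schedule$dt_pre else numeric(0)
  t0 <- schedule$n_bleach * schedule$dt_bleach
  post <- if (schedule$n_post > 0) t0 + (seq_len(schedule$n_post) - 1L) * schedule$dt_post else numeric(0)
  c(pre, post)
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf("Acquisition schedule: %d pre x %.3g s | %d bleach x %.3g s | %d post x %.3g s\n",
              x$n_pre, x$dt_pre, x$n_bleach, x$dt_bleach, x$n_post, x$dt_post))
  ts <- schedule_times(x)
  if (length(ts)) {
    cat(sprintf("  %d frames, t in [%.4g, %.4g] s (t = 0 at bleach onset)\n",
                length(ts), min(ts), max(ts)))
  }
  invisible(x)
}

# Indices of post-bleach frames in the emitted frame sequence.
post_bleach_index <- function(schedule) {
  if (schedule$n_post == 0) return(integer(0))
  schedule$n_pre + seq_len(schedule$n_post)
}
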