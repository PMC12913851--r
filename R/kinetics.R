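#' One-phase association fit (recruitment time constant)
#'
#' Fits \eqn{y(t) = y_0 + (P - y_0)(1 - e^{-(t - t_1)/\tau})} to a metric
#' trace over a fixed window (default: first post-bleach frame to 60 s,
#' the short-term recruitment phase), with \eqn{t_1} the first time in the
#' window. \eqn{\tau} is the recruitment time constant (T_on).
#'
#' @param time_s numeric, strictly increasing time stamps in seconds
#' @param y metric trace (NA entries dropped)
#' @param window_s fit interval `c(lo, hi)` in seconds
#' @return An object of class `kinetics_fit`: `tau_s`, `y0`, `plateau`,
#'   `r_squared`, `success`, `window_s`, `model`.
#' @export
fit_association <- function(time_s, y, window_s = c(2.6, 60)) {
  keep <- is.finite(time_s) & is.finite(y) &
    time_s >= window_s[1] & time_s <= window_s[2]
  t <- time_s[keep]; yy <- y[keep]
  if (length(t) >= 2 && any(diff(t) <= 0)) stopf("time must be strictly increasing")
  fail <- kinetics_fit_failure("association", window_s)
  if (length(t) < 4) return(fail)
  t1 <- t[1]
  dat <- data.frame(t = t, y = yy)
  span <- diff(range(t))
  starts <- lapply(c(5, 10, 2), function(d) {
    list(y0 = yy[1], plateau = max(yy), tau = span / d)
  })
  fit <- nls_first_success(y ~ y0 + (plateau - y0) * (1 - exp(-(t - t1) / tau)),
                           dat, starts)
  kinetics_fit_result(fit, dat, "association", window_s)
}

#' One-phase decay fit (release/relaxation time constant)
#'
#' Fits \eqn{y(t) = P + (y_s - P)e^{-(t - t_s)/\tau}} from a start point:
#' `start_mode = "at_peak"` starts at the trace maximum (3-point moving
#' average, for damage-marker traces that rise then fall);
#' `"at_first_post"` starts at the first post-bleach frame (for counterstain
#' intensity and CV traces that decay from the start). \eqn{\tau} is the
#' decay time constant (T_off). A trace that only increases after the start
#' point yields `success = FALSE`.
#'
#' @inheritParams fit_association
#' @param start_mode `"at_first_post"` or `"at_peak"`
#' @return An object of class `kinetics_fit`.
#' @export
fit_decay <- function(time_s, y, start_mode = c("at_first_post", "at_peak")) {
  start_mode <- match.arg(start_mode)
  keep <- is.finite(time_s) & is.finite(y)
  t <- time_s[keep]; yy <- y[keep]
  if (length(t) >= 2 && any(diff(t) <= 0)) stopf("time must be strictly increasing")
  start_idx <- if (start_mode == "at_peak") {
    sm <- stats::filter(yy, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- yy[is.na(sm)]
    which.max(sm)
  } else {
    idx <- which(t > 0)
    if (!length(idx)) return(kinetics_fit_failure("decay", range(t)))
    idx[1]
  }
  t <- t[start_idx:length(t)]; yy <- yy[start_idx:length(yy)]
  window_s <- range(t)
  fail <- kinetics_fit_failure("decay", window_s)
  if (length(t) < 4) return(fail)
  if (yy[length(yy)] >= yy[1] && all(diff(yy) >= 0)) return(fail)
  ts <- t[1]
  dat <- data.frame(t = t, y = yy)
  span <- diff(range(t))
  starts <- lapply(c(5, 10, 2), function(d) {
    list(plateau = min(yy), ystart = yy[1], tau = span / d)
  })
  fit <- nls_first_success(y ~ plateau + (ystart - plateau) * exp(-(t - ts) / tau),
                           dat, starts)
  out <- kinetics_fit_result(fit, dat, "decay", window_s)
  if (out$success) {
    out$y0 <- out$pars[["ystart"]]
    out$plateau <- out$pars[["plateau"]]
  }
  out
}

# Try a small grid of start values; first converged fit wins. Bounds keep
# tau in (0.1, 1000] s.
nls_first_success <- function(formula, dat, starts) {
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = dat, start = st,
                        lower = c(-Inf, -Inf, 0.1), upper = c(Inf, Inf, 1000),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

kinetics_fit_failure <- function(model, window_s) {
  structure(list(tau_s = NA_real_, y0 = NA_real_, plateau = NA_real_,
                 r_squared = NA_real_, success = FALSE,
                 window_s = window_s, model = model, pars = NULL),
            class = "kinetics_fit")
}

kinetics_fit_result <- function(fit, dat, model, window_s) {
  if (is.null(fit)) return(kinetics_fit_failure(model, window_s))
  p <- stats::coef(fit)
  tau <- unname(p["tau"])
  # a tau pinned to its bounds is not a converged estimate
  if (!is.finite(tau) || tau <= 0.1 + 1e-9 || tau >= 1000 - 1e-6) {
    return(kinetics_fit_failure(model, window_s))
  }
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((dat$y - mean(dat$y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  y0 <- if ("y0" %in% names(p)) unname(p["y0"]) else NA_real_
  plateau <- if ("plateau" %in% names(p)) unname(p["plateau"]) else NA_real_
  structure(list(tau_s = tau, y0 = y0, plateau = plateau,
                 r_squared = r2, success = TRUE, window_s = window_s,
                 model = model, pars = as.list(p)),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (x$success) {
    cat(sprintf("One-phase %s fit: tau = %.3g s, y0 = %.3g, plateau = %.3g, R2 = %.3f\n",
                x$model, x$tau_s, x$y0, x$plateau, x$r_squared))
  } else {
    cat(sprintf("One-phase %s fit: failed\n", x$model))
  }
  invisible(x)
}

#' @export
coef.kinetics_fit <- function(object, ...) {
  c(tau_s = object$tau_s, y0 = object$y0, plateau = object$plateau)
}
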