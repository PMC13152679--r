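#' Baseline convention for delta-F/F
#'
#' Two conventions are supported: `"prestim_mean"` — F0 is the mean of the
#' frames before the stimulus (frames `1:prestim_end`); `"trial_median"`
#' — F0 is the median over the whole trial. When `prestim_end` is `NULL`
#' the pre-stimulus window defaults to all frames before the first
#' stimulus frame of the input.
#'
#' @param mode `"prestim_mean"` or `"trial_median"`.
#' @param prestim_end last baseline frame (1-based count of leading
#'   frames); required >= 2 for `prestim_mean` unless the input carries
#'   stimulus frames.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(mode = c("prestim_mean", "trial_median"),
                          prestim_end = NULL) {
  mode <- match.arg(mode)
  if (!is.null(prestim_end)) {
    prestim_end <- as.integer(prestim_end)
    if (mode == "prestim_mean" && prestim_end < 2L)
      stopf("prestim_end must be >= 2 (need at least 2 baseline frames)")
  }
  structure(list(mode = mode, prestim_end = prestim_end),
            class = "baseline_spec")
}

resolve_prestim_end <- function(spec, stim_frames, n) {
  if (!is.null(spec$prestim_end)) return(spec$prestim_end)
  if (length(stim_frames) == 0L)
    stopf("prestim_mean baseline needs 'prestim_end' or stimulus frames on the input")
  pe <- stim_frames[1L] - 1L
  if (pe < 2L) stopf("fewer than 2 frames before the first stimulus")
  pe
}

#' Fractional fluorescence change dFF = (F - F0) / F0
#'
#' Applied elementwise; for movies F0 is computed per pixel, for traces
#' over the whole series. A nonpositive F0 signals a dead or clipped
#' region and is rejected with the offending location.
#'
#' @param x a `fluor_trace` or `movie_stack` in intensity units.
#' @param spec a [baseline_spec()].
#' @return same class as `x`, in dFF units.
#' @export
compute_dff <- function(x, spec = baseline_spec("trial_median")) {
  UseMethod("compute_dff")
}

#' @export
compute_dff.fluor_trace <- function(x, spec = baseline_spec("trial_median")) {
  f0 <- if (spec$mode == "trial_median") {
    stats::median(x$values)
  } else {
    stim <- if (x$t0_frame > 1L) x$t0_frame else integer()
    pe <- resolve_prestim_end(spec, stim, length(x$values))
    if (pe >= length(x$values))
      stopf("prestim_end (%d) must leave at least one post-baseline frame", pe)
    mean(x$values[seq_len(pe)])
  }
  if (!is.finite(f0) || f0 <= 0)
    stopf("baseline F0 = %g is not positive; trace cannot be normalised", f0)
  out <- x
  out$values <- (x$values - f0) / f0
  out
}

#' @export
compute_dff.movie_stack <- function(x, spec = baseline_spec("trial_median")) {
  d <- x$data
  f0 <- if (spec$mode == "trial_median") {
    apply(d, c(2L, 3L), stats::median)
  } else {
    pe <- resolve_prestim_end(spec, x$stim_frames, dim(d)[1L])
    apply(d[seq_len(pe), , , drop = FALSE], c(2L, 3L), mean)
  }
  if (any(f0 <= 0)) {
    bad <- which(f0 <= 0, arr.ind = TRUE)[1L, ]
    stopf("baseline F0 <= 0 at pixel (y=%d, x=%d): dead or clipped region",
          bad[1L], bad[2L])
  }
  out <- x
  out$data <- sweep(sweep(d, c(2L, 3L), f0, "-"), c(2L, 3L), f0, "/")
  out$units <- "dff"
  out
}

#' Remove slow photobleaching by double-exponential subtraction
#'
#' Fits `y(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2) + C` to the full trace
#' by Levenberg-Marquardt least squares and returns `x - y(t) + C`, so
#' the corrected trace keeps its asymptotic level. Initial values come
#' from a log-linear fit of the early and late thirds; time constants are
#' bounded to `(2 frame periods, 10 x trace duration]`. On
#' non-convergence the input is returned unchanged with
#' `converged = FALSE` — the data are never silently altered.
#'
#' @param x a `fluor_trace` (>= 8 frames).
#' @param weights optional per-frame weights for the fit (e.g. to
#'   emphasise the early decay); default uniform.
#' @return list with `trace` (corrected `fluor_trace`), `pars`
#'   (named `A1, tau1, A2, tau2, C`), `converged`, `sse`.
#' @export
correct_bleach <- function(x, weights = NULL) {
  stopifnot(inherits(x, "fluor_trace"))
  v <- x$values
  n <- length(v)
  if (n < 8L) stopf("bleach correction needs >= 8 frames (got %d)", n)
  t <- time_axis(x)
  dur <- t[n]
  lo_tau <- 2 / x$frame_rate
  hi_tau <- 10 * dur
  if (is.null(weights)) weights <- rep(1, n)

  # init: asymptote from the final 10%, fast component from the first
  # third, slow component from the middle-late section
  c0 <- mean(v[ceiling(0.9 * n):n])
  loglin_tau <- function(idx, fallback) {
    r <- v[idx] - c0
    if (all(r > 1e-12) && length(idx) >= 3L) {
      sl <- stats::coef(stats::lm(log(r) ~ t[idx]))[2L]
      if (is.finite(sl) && sl < 0) return(min(max(-1 / sl, lo_tau * 1.01), hi_tau))
    }
    fallback
  }
  tau1_0 <- loglin_tau(seq_len(max(3L, floor(n / 3))), max(dur / 10, lo_tau * 1.5))
  tau2_0 <- loglin_tau(seq(floor(n / 3) + 1L, floor(2 * n / 3)), dur / 2)
  if (tau2_0 <= tau1_0) tau2_0 <- min(tau1_0 * 5, hi_tau)
  amp0 <- max(v[1L] - c0, 0)
  rng <- diff(range(v))
  starts <- list(
    c(A1 = amp0 / 2, tau1 = tau1_0, A2 = amp0 / 2, tau2 = tau2_0, C = c0),
    c(A1 = amp0 * 0.8, tau1 = max(dur / 20, lo_tau * 1.5), A2 = amp0 * 0.2,
      tau2 = dur, C = c0),
    c(A1 = amp0 * 0.3, tau1 = max(dur / 5, lo_tau * 1.5), A2 = amp0 * 0.7,
      tau2 = 3 * dur, C = c0))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + C,
        start = as.list(st),
        lower = c(0, lo_tau, 0, lo_tau, min(v) - rng),
        upper = c(2 * rng + amp0 + 1, hi_tau, 2 * rng + amp0 + 1, hi_tau,
                  max(v) + rng),
        weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum((stats::resid(fit))^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    return(list(trace = x,
                pars = c(A1 = NA_real_, tau1 = NA_real_, A2 = NA_real_,
                         tau2 = NA_real_, C = NA_real_),
                converged = FALSE, sse = NA_real_))
  }
  p <- stats::coef(best$fit)
  yhat <- p[["A1"]] * exp(-t / p[["tau1"]]) + p[["A2"]] * exp(-t / p[["tau2"]]) + p[["C"]]
  out <- x
  out$values <- v - yhat + p[["C"]]
  list(trace = out, pars = p, converged = TRUE, sse = best$sse)
}

# Steady-state initial conditions for a direct-form-II-transposed filter
# (solves (I - A) zi = B for the companion matrix A of the AR polynomial),
# so that filtering a constant yields that constant from the first sample.
lfilter_zi <- function(b, a) {
  n <- length(a)
  A <- rbind(-a[2:n] / a[1L], cbind(diag(n - 2L), 0))
  B <- b[2:n] - a[2:n] * b[1L]
  solve(diag(n - 1L) - t(A), B)
}

lfilter <- function(b, a, x, zi) {
  n <- length(b)
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (n > 2L) for (k in 1:(n - 2L)) z[k] <- b[k + 1L] * xi + z[k + 1L] - a[k + 1L] * yi
    z[n - 1L] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

#' Butterworth low-pass filter
#'
#' Zero-phase by default: the trace is extended by odd reflection at both
#' ends, filtered forward and backward with steady-state initial
#' conditions, and trimmed. This preserves constants exactly, has unit DC
#' gain, introduces no time shift, and gives squared-magnitude gain 1/2 at
#' the cutoff. A causal single-pass mode (`zero_phase = FALSE`) is
#' available when physical causality matters more than timing fidelity.
#'
#' @param x a `fluor_trace`.
#' @param cutoff cutoff frequency in Hz (default 0.68).
#' @param order filter order (default 3).
#' @param zero_phase forward-backward filtering? (default `TRUE`).
#' @return filtered `fluor_trace`.
#' @export
lowpass <- function(x, cutoff = 0.68, order = 3L, zero_phase = TRUE) {
  stopifnot(inherits(x, "fluor_trace"))
  nyq <- x$frame_rate / 2
  if (cutoff >= nyq)
    stopf("cutoff %g Hz is at or above Nyquist (%g Hz at %g Hz sampling)",
          cutoff, nyq, x$frame_rate)
  check_number(cutoff, "cutoff")
  bf <- signal::butter(order, cutoff / nyq)
  b <- bf$b; a <- bf$a
  v <- x$values
  out <- x
  if (!zero_phase) {
    out$values <- lfilter(b, a, v, lfilter_zi(b, a) * v[1L])
    return(out)
  }
  n <- length(v)
  padlen <- min(n - 1L, max(3L * (length(a) - 1L) * 3L,
                            ceiling(3 * x$frame_rate / cutoff)))
  pre <- 2 * v[1L] - v[(padlen + 1L):2L]
  post <- 2 * v[n] - v[(n - 1L):(n - padlen)]
  ext <- c(pre, v, post)
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1L])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  out$values <- y[(padlen + 1L):(padlen + n)]
  out
}

#' Full width at half maximum of an intensity profile
#'
#' The minimum is subtracted, the two half-maximum crossings flanking the
#' peak are located by linear interpolation, and their separation is
#' returned. The result is invariant to affine rescaling of the
#' intensities. A profile whose peak touches either end, or that never
#' falls to half maximum on one side, is rejected (truncated stack).
#'
#' @param z positions (monotone increasing), any units.
#' @param intensity intensity values at `z`.
#' @return width in the units of `z`.
#' @export
profile_fwhm <- function(z, intensity) {
  if (length(z) != length(intensity) || length(z) < 3L)
    stopf("'z' and 'intensity' must be equal-length vectors (>= 3 points)")
  if (any(diff(z) <= 0)) stopf("'z' must be strictly increasing")
  y <- intensity - min(intensity)
  ymax <- max(y)
  if (ymax <= 0) stopf("profile is flat; FWHM undefined")
  i_lo <- which(y == ymax)[1L]
  i_hi <- which(y == ymax)[length(which(y == ymax))]
  if (i_lo == 1L || i_hi == length(y))
    stopf("profile maximum touches an endpoint; stack is truncated")
  half <- ymax / 2
  cross <- function(i0, i1) {
    # interpolate between samples i0 (below half) and i1 (above half)
    z[i0] + (half - y[i0]) * (z[i1] - z[i0]) / (y[i1] - y[i0])
  }
  left <- NA_real_
  for (i in seq(i_lo - 1L, 1L)) {
    if (y[i] <= half) { left <- cross(i, i + 1L); break }
  }
  right <- NA_real_
  for (i in seq(i_hi + 1L, length(y))) {
    if (y[i] <= half) { right <- cross(i, i - 1L); break }
  }
  if (is.na(left) || is.na(right))
    stopf("profile does not fall to half maximum on both sides; stack is truncated")
  right - left
}
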