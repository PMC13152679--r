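#' Rise-decay response model
#'
#' `y(x) = alpha * (1 - exp(-x/tau_on)) * exp(-x/tau_off) + beta` for
#' `x >= 0`: a first-order rise multiplied by a first-order decay, the
#' standard description of an indicator transient. Its maximum over x is
#' at [rise_decay_peak_time()] and the peak amplitude above `beta` is
#' `alpha * f` with `f < 1` (the model never reaches `alpha` because the
#' decay is already acting at the peak).
#'
#' @param x time since onset, seconds (vectorised, `x >= 0`).
#' @param alpha scale factor (dFF units).
#' @param beta constant offset (dFF units).
#' @param tau_on rise time constant, seconds.
#' @param tau_off decay time constant, seconds.
#' @return model values.
#' @export
rise_decay <- function(x, alpha, beta, tau_on, tau_off) {
  alpha * (1 - exp(-x / tau_on)) * exp(-x / tau_off) + beta
}

#' Analytic peak time of the rise-decay model
#'
#' Setting the derivative of `(1 - exp(-x/a)) exp(-x/b)` to zero gives
#' `x* = a * log(1 + b/a)`.
#'
#' @param tau_on,tau_off time constants, seconds.
#' @return peak time in seconds after onset.
#' @export
rise_decay_peak_time <- function(tau_on, tau_off)
  tau_on * log(1 + tau_off / tau_on)

# peak value of the (alpha = 1, beta = 0) model: the attenuation factor f
rise_decay_peak_factor <- function(tau_on, tau_off) {
  tp <- rise_decay_peak_time(tau_on, tau_off)
  (1 - exp(-tp / tau_on)) * exp(-tp / tau_off)
}

#' Fit the rise-decay model to a dFF trace
#'
#' Nonlinear least squares of
#' `y = alpha (1 - e^(-x/tau_on)) e^(-x/tau_off) + beta` over
#' `x = t - t0 >= 0`. Initialisation: `beta` from the pre-`t0` mean,
#' `alpha` from the observed peak corrected by the model's peak
#' attenuation, `tau_on` from half the time to peak, `tau_off` from the
#' post-peak 1/e fall time. Because the product model has shallow valleys
#' when the two constants are comparable, the fit is restarted from
#' jittered initials (+/-50% log-uniform on the taus, fixed internal
#' seed) and the lowest-SSE candidate is returned. Time constants are
#' bounded to `(frame period / 10, 10 x fit duration]`.
#'
#' @param trace a `fluor_trace` in dFF units.
#' @param t0 fit origin in seconds from trace start (stimulus onset);
#'   default the trace's `t0_frame`.
#' @param n_restarts number of jittered restarts beyond the base start.
#' @param seed seed for the restart jitter.
#' @return An object of class `kinetic_fit`: list with `alpha`, `beta`,
#'   `tau_on`, `tau_off`, `sse`, `converged`, `t0`, `n_points`.
#' @export
fit_rise_decay <- function(trace, t0 = NULL, n_restarts = 3L, seed = 1L) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (is.null(t0)) t0 <- (trace$t0_frame - 1) / trace$frame_rate
  tt <- time_axis(trace)
  sel <- tt >= t0
  if (sum(sel) < 8L)
    stopf("need >= 8 frames at or after t0 = %g s (got %d)", t0, sum(sel))
  x <- tt[sel] - t0
  y <- trace$values[sel]
  dt <- 1 / trace$frame_rate
  dur <- max(x)
  lo_tau <- dt / 10
  hi_tau <- 10 * dur

  # (near-)constant traces are a degenerate limit: alpha = 0 makes the
  # tau gradients vanish, so LM cannot move; return the exact answer
  yr0 <- diff(range(y))
  if (yr0 <= 1e-10 * max(1, abs(mean(y)))) {
    return(structure(list(alpha = 0, beta = mean(y), tau_on = dt, tau_off = dt,
                          sse = sum((y - mean(y))^2), converged = TRUE,
                          t0 = t0, n_points = length(y)),
                     class = "kinetic_fit"))
  }

  beta0 <- if (any(!sel)) mean(trace$values[!sel]) else min(y)
  ipk <- which.max(y)
  t_peak <- max(x[ipk], dt)
  tau_on0 <- min(max(t_peak / 2, lo_tau * 2), hi_tau / 2)
  peak_amp <- y[ipk] - beta0
  # 1/e fall time after the peak
  tau_off0 <- {
    below <- which(y[ipk:length(y)] < beta0 + peak_amp / exp(1))
    if (length(below)) max(x[ipk + below[1L] - 1L] - x[ipk], dt)
    else dur / 3
  }
  tau_off0 <- min(max(tau_off0, lo_tau * 2), hi_tau / 2)
  mk_start <- function(a, b) {
    f <- rise_decay_peak_factor(a, b)
    list(alpha = peak_amp / max(f, 1e-3), beta = beta0, tau_on = a, tau_off = b)
  }
  starts <- c(list(mk_start(tau_on0, tau_off0)),
              with_seed(seed, lapply(seq_len(n_restarts), function(i) {
                j <- exp(stats::runif(2L, log(0.5), log(1.5)))
                mk_start(min(max(tau_on0 * j[1L], lo_tau * 2), hi_tau / 2),
                         min(max(tau_off0 * j[2L], lo_tau * 2), hi_tau / 2))
              })))

  yr <- diff(range(y))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ alpha * (1 - exp(-x / tau_on)) * exp(-x / tau_off) + beta,
        start = st,
        lower = c(-10 * (yr + abs(peak_amp)) - 1, min(y) - yr - 1, lo_tau, lo_tau),
        upper = c(10 * (yr + abs(peak_amp)) + 1, max(y) + yr + 1, hi_tau, hi_tau),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    return(structure(list(alpha = peak_amp, beta = beta0, tau_on = tau_on0,
                          tau_off = tau_off0, sse = NA_real_,
                          converged = FALSE, t0 = t0, n_points = length(y)),
                     class = "kinetic_fit"))
  }
  p <- as.list(stats::coef(best$fit))
  structure(list(alpha = p$alpha, beta = p$beta, tau_on = p$tau_on,
                 tau_off = p$tau_off, sse = best$sse, converged = TRUE,
                 t0 = t0, n_points = length(y)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> alpha %.4g, beta %.4g, tau_on %.4g s, tau_off %.4g s (sse %.3g, %s)\n",
              x$alpha, x$beta, x$tau_on, x$tau_off, x$sse,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Average aligned repeated trials
#'
#' Pointwise mean and sample SD across trials of equal length, frame rate
#' and alignment.
#'
#' @param traces list of `fluor_trace`s aligned to their stimulus frames.
#' @return list with `mean` and `sd` (both `fluor_trace`s) and `n_trials`.
#' @export
average_trials <- function(traces) {
  if (!length(traces) || !all(vapply(traces, inherits, logical(1), "fluor_trace")))
    stopf("'traces' must be a non-empty list of fluor_trace objects")
  n <- vapply(traces, function(x) length(x$values), integer(1))
  fr <- vapply(traces, `[[`, numeric(1), "frame_rate")
  t0 <- vapply(traces, `[[`, integer(1), "t0_frame")
  if (length(unique(n)) != 1L || length(unique(fr)) != 1L || length(unique(t0)) != 1L)
    stopf("trials must share length, frame rate and alignment")
  m <- do.call(rbind, lapply(traces, `[[`, "values"))
  mu <- colMeans(m)
  sdv <- if (nrow(m) == 1L) {
    warning("single trial: SD is identically zero")
    rep(0, ncol(m))
  } else apply(m, 2L, stats::sd)
  list(mean = fluor_trace(mu, fr[1L], t0[1L]),
       sd = fluor_trace(sdv, fr[1L], t0[1L]),
       n_trials = length(traces))
}

#' Fit kinetics for every active grid square
#'
#' Runs [fit_rise_decay()] on the (trial-averaged) trace of each active
#' square of a [detect_active_rois()] result and summarises the tau
#' distributions as histograms with recorded bin edges. Squares whose fit
#' fails are reported with `converged = FALSE` and excluded from the
#' histograms.
#'
#' @param map a `grid_response_map`.
#' @param tau_breaks histogram break specification passed to
#'   [graphics::hist()] machinery (default `"FD"`).
#' @return list with `fits` (data.frame: square, row, col, alpha, beta,
#'   tau_on, tau_off, sse, converged), `tau_on_hist`, `tau_off_hist`
#'   (histogram objects with `$breaks`), and `n_failed`.
#' @export
fit_grid <- function(map, tau_breaks = "FD") {
  stopifnot(inherits(map, "grid_response_map"))
  act <- which(map$active)
  tr <- attr(map, "mean_traces")
  fr <- attr(map, "frame_rate")
  stim <- attr(map, "stim_frame")
  rows <- lapply(act, function(i) {
    f <- fit_rise_decay(fluor_trace(tr[i, ], fr, stim))
    data.frame(square = map$square[i], row = map$row[i], col = map$col[i],
               alpha = f$alpha, beta = f$beta, tau_on = f$tau_on,
               tau_off = f$tau_off, sse = f$sse, converged = f$converged)
  })
  fits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(square = integer(), row = integer(), col = integer(),
               alpha = numeric(), beta = numeric(), tau_on = numeric(),
               tau_off = numeric(), sse = numeric(), converged = logical())
  ok <- fits$converged
  hist_or_null <- function(v) {
    if (length(v) < 2L) return(NULL)
    graphics::hist(v, breaks = tau_breaks, plot = FALSE)
  }
  list(fits = fits,
       tau_on_hist = hist_or_null(fits$tau_on[ok]),
       tau_off_hist = hist_or_null(fits$tau_off[ok]),
       n_failed = sum(!ok))
}
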