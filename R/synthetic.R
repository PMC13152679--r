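#' Forward model of an indicator channel
#'
#' Hill-type equilibrium binding plus first-order rise/decay kinetics.
#' The steady-state fractional fluorescence change at ligand concentration
#' `C` is `dff_max * C^n / (C^n + kd^n)`; `tau_on`/`tau_off` parameterise
#' the temporal response kernel used by [simulate_concentration()].
#'
#' @param name sensor label.
#' @param kd dissociation constant, micromolar.
#' @param hill_n Hill coefficient (dimensionless, default 1).
#' @param dff_max maximal fractional fluorescence change.
#' @param tau_on rise time constant, seconds.
#' @param tau_off decay time constant, seconds.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(name, kd, hill_n = 1, dff_max, tau_on, tau_off) {
  check_number(kd, "kd"); check_number(hill_n, "hill_n")
  check_number(dff_max, "dff_max")
  check_number(tau_on, "tau_on"); check_number(tau_off, "tau_off")
  structure(list(name = name, kd = kd, hill_n = hill_n, dff_max = dff_max,
                 tau_on = tau_on, tau_off = tau_off),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf(
    "<sensor_model> %s: Kd %.4g uM (n=%.3g), dFF max %.3g, tau on/off %.3g/%.3g s\n",
    x$name, x$kd, x$hill_n, x$dff_max, x$tau_on, x$tau_off))
  invisible(x)
}

#' Built-in sensor presets
#'
#' `grab_da3m_model()`: high-affinity membrane-bound dopamine indicator
#' (Kd in the tens of nanomolar). `nircat_model()`: low-affinity
#' near-infrared nanotube catecholamine sensor (Kd in the tens of
#' micromolar), with slower rise/decay. `cal520_model()`: synthetic
#' high-SNR calcium-channel stand-in for the retinal simulations. With
#' equal `dff_max` the 1000-fold Kd contrast between the two dopamine
#' sensors makes their linear-regime responses differ by three orders of
#' magnitude.
#' @return a `sensor_model`.
#' @name sensor_presets
NULL

#' @rdname sensor_presets
#' @export
grab_da3m_model <- function()
  sensor_model("grab_da3m", kd = 0.03, hill_n = 1, dff_max = 1,
               tau_on = 1.0, tau_off = 3.0)

#' @rdname sensor_presets
#' @export
nircat_model <- function()
  sensor_model("nircat", kd = 30, hill_n = 1, dff_max = 1,
               tau_on = 2.0, tau_off = 6.0)

#' @rdname sensor_presets
#' @export
cal520_model <- function()
  sensor_model("cal520", kd = 0.5, hill_n = 1, dff_max = 1,
               tau_on = 0.8, tau_off = 4.0)

#' Spatial field of release hotspots
#'
#' Each hotspot is an isotropic Gaussian in space, normalised to 1 at its
#' centre, on top of a uniform background concentration.
#'
#' @param centers numeric matrix (or 2-column data.frame) of (y, x)
#'   positions in micrometres.
#' @param sigma Gaussian width in micrometres (shared across hotspots).
#' @param amplitudes peak dopamine concentration per hotspot, micromolar.
#' @param background uniform baseline concentration, micromolar.
#' @return An object of class `hotspot_field`.
#' @export
hotspot_field <- function(centers, sigma, amplitudes, background = 0) {
  centers <- as.matrix(centers)
  if (length(centers) && ncol(centers) != 2L)
    stopf("'centers' must have two columns (y, x) in micrometres")
  check_number(sigma, "sigma")
  amplitudes <- as.numeric(amplitudes)
  if (nrow(centers) != length(amplitudes))
    stopf("need one amplitude per hotspot centre")
  if (any(amplitudes < 0)) stopf("amplitudes must be >= 0")
  check_number(background, "background", positive = FALSE, nonneg = TRUE)
  structure(list(centers = centers, sigma = sigma, amplitudes = amplitudes,
                 background = background),
            class = "hotspot_field")
}

#' Stimulus / event timing
#'
#' @param event_frames strictly increasing 1-based frame indices.
#' @param kind one of `"electrical"`, `"k_puff"`, `"wave"`.
#' @param per_event_scale multiplicative amplitude per event (recycled to
#'   the number of events).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(event_frames, kind = c("electrical", "k_puff", "wave"),
                              per_event_scale = 1) {
  kind <- match.arg(kind)
  event_frames <- as.integer(event_frames)
  if (length(event_frames) && any(diff(event_frames) <= 0))
    stopf("event_frames must be strictly increasing")
  per_event_scale <- rep_len(as.numeric(per_event_scale), length(event_frames))
  structure(list(event_frames = event_frames, kind = kind,
                 per_event_scale = per_event_scale),
            class = "stimulus_protocol")
}

#' Geometry, acquisition and noise settings for a synthetic movie
#'
#' Defaults mirror the acquisition used throughout: 1.47 frames/s,
#' 256 x 256 pixels. Tests and packaged fixtures pass smaller fields
#' explicitly. The pixel size is free metadata (nothing downstream
#' derives it from the field of view).
#'
#' @param n_frames number of frames.
#' @param height,width frame size in pixels.
#' @param frame_rate acquisition rate, Hz.
#' @param pixel_size micrometres per pixel.
#' @param f0_mean baseline intensity, detector counts.
#' @param noise_sd additive Gaussian noise SD, counts (`0` for noiseless).
#' @param bleach length-4 numeric `(a1, tau1, a2, tau2)`: double-exponential
#'   photobleach weights and time constants (seconds). The curve is
#'   normalised so B(0) = 1, so `f0_mean` is the true t = 0 baseline.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise;
#'   `noise_sd` ignored).
#' @param seed integer RNG seed; all randomness in rendering flows from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_frames = 128L, height = 256L, width = 256L,
                             frame_rate = 1.47, pixel_size = 0.75,
                             f0_mean = 2000, noise_sd = 20,
                             bleach = c(0.3, 60, 0.7, 1e4),
                             noise_model = c("gaussian", "poisson"),
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_number(frame_rate, "frame_rate"); check_number(pixel_size, "pixel_size")
  check_number(f0_mean, "f0_mean")
  check_number(noise_sd, "noise_sd", positive = FALSE, nonneg = TRUE)
  if (length(bleach) != 4L || bleach[2L] <= 0 || bleach[4L] <= 0)
    stopf("'bleach' must be (a1, tau1, a2, tau2) with tau1, tau2 > 0")
  structure(list(n_frames = as.integer(n_frames), height = as.integer(height),
                 width = as.integer(width), frame_rate = frame_rate,
                 pixel_size = pixel_size, f0_mean = f0_mean,
                 noise_sd = noise_sd, bleach = as.numeric(bleach),
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Rise-decay response kernel
#'
#' `K(t) = (1 - exp(-t/tau_on)) * exp(-t/tau_off)` for `t >= 0`, zero
#' before. With `normalize = TRUE` the kernel is scaled to peak at 1; its
#' maximum sits at `t = tau_on * log(1 + tau_off/tau_on)`
#' (see [rise_decay_peak_time()]).
#'
#' @param t time in seconds (vectorised).
#' @param tau_on,tau_off rise and decay time constants, seconds.
#' @param normalize scale the peak to 1?
#' @return numeric vector of kernel values.
#' @export
rise_decay_kernel <- function(t, tau_on, tau_off, normalize = TRUE) {
  k <- ifelse(t >= 0, (1 - exp(-t / tau_on)) * exp(-t / tau_off), 0)
  if (normalize) {
    tp <- rise_decay_peak_time(tau_on, tau_off)
    k <- k / ((1 - exp(-tp / tau_on)) * exp(-tp / tau_off))
  }
  k
}

#' Simulate a dopamine concentration movie
#'
#' Superposes, for every stimulus event and every hotspot, a spatial
#' Gaussian (normalised to 1 at the hotspot centre) times the normalised
#' rise-decay kernel of the sensor model, on a uniform background:
#' `C(p, t) = background + sum_e sum_h amp_h * scale_e * G(p; h) * K(t - t_e)`.
#' Contributions add linearly; before the first event the movie equals the
#' background.
#'
#' @param field a [hotspot_field()]; centres must lie inside the field of
#'   view implied by `config`.
#' @param protocol a [stimulus_protocol()]; event frames must fall inside
#'   the movie.
#' @param model a [sensor_model()] (supplies the kernel time constants).
#' @param config a [synthetic_config()].
#' @return a `movie_stack` in micromolar units (`units = "uM"`).
#' @export
simulate_concentration <- function(field, protocol, model, config) {
  stopifnot(inherits(field, "hotspot_field"),
            inherits(protocol, "stimulus_protocol"),
            inherits(model, "sensor_model"),
            inherits(config, "synthetic_config"))
  nt <- config$n_frames
  check_frames(protocol$event_frames, nt, "event_frames")
  fov_y <- config$height * config$pixel_size
  fov_x <- config$width * config$pixel_size
  if (nrow(field$centers) &&
      (any(field$centers[, 1L] < 0 | field$centers[, 1L] > fov_y) ||
       any(field$centers[, 2L] < 0 | field$centers[, 2L] > fov_x)))
    stopf("hotspot centres must lie inside the %g x %g um field of view",
          fov_y, fov_x)

  t <- (seq_len(nt) - 1) / config$frame_rate
  # per-pixel coordinates in micrometres (pixel centres)
  yy <- (seq_len(config$height) - 0.5) * config$pixel_size
  xx <- (seq_len(config$width) - 0.5) * config$pixel_size
  arr <- array(field$background, dim = c(nt, config$height, config$width))
  if (nrow(field$centers) && length(protocol$event_frames)) {
    # spatial map per hotspot, temporal kernel per event; outer products
    for (h in seq_len(nrow(field$centers))) {
      g <- outer((yy - field$centers[h, 1L])^2, (xx - field$centers[h, 2L])^2, "+")
      g <- exp(-g / (2 * field$sigma^2)) * field$amplitudes[h]
      tk <- numeric(nt)
      for (e in seq_along(protocol$event_frames)) {
        te <- (protocol$event_frames[e] - 1) / config$frame_rate
        tk <- tk + protocol$per_event_scale[e] *
          rise_decay_kernel(t - te, model$tau_on, model$tau_off)
      }
      arr <- arr + outer(tk, g)  # nt x (height*width), reshaped below
    }
  }
  dim(arr) <- c(nt, config$height, config$width)
  movie_stack(arr, config$frame_rate, config$pixel_size,
              channel = model$name, stim_frames = protocol$event_frames,
              units = "uM")
}

#' Equilibrium sensor response to a concentration movie
#'
#' Pointwise Hill transform
#' `dFF = dff_max * C^n / (C^n + kd^n)`: monotone nondecreasing in `C`
#' and bounded by `dff_max`.
#'
#' @param conc a concentration `movie_stack` (micromolar, nonnegative).
#' @param model a [sensor_model()].
#' @return a `movie_stack` with `units = "dff"`.
#' @export
sensor_response <- function(conc, model) {
  stopifnot(inherits(conc, "movie_stack"), inherits(model, "sensor_model"))
  if (any(conc$data < 0)) stopf("concentrations must be >= 0")
  cn <- conc$data^model$hill_n
  out <- conc
  out$data <- model$dff_max * cn / (cn + model$kd^model$hill_n)
  out$units <- "dff"
  out$channel <- model$name
  out
}

# Normalised double-exponential bleach curve, B(0) = 1.
bleach_curve <- function(t, bleach) {
  a1 <- bleach[1L]; t1 <- bleach[2L]; a2 <- bleach[3L]; t2 <- bleach[4L]
  (a1 * exp(-t / t1) + a2 * exp(-t / t2)) / (a1 + a2)
}

#' Render a delta-F/F movie into detector counts
#'
#' `F(p, t) = f0_mean * (1 + dFF(p, t)) * B(t) + noise`, with the bleach
#' curve `B` normalised to 1 at t = 0 and i.i.d. Gaussian (or Poisson
#' shot) noise. Counts are rounded to integers (a digitising detector)
#' and clipped to `[0, 65535]` with a warning when clipping occurs.
#' Rendering is deterministic given `config$seed`.
#'
#' @param dff a `movie_stack` in dFF units (from [sensor_response()]).
#' @param config a [synthetic_config()].
#' @return a `movie_stack` in count units.
#' @export
render_movie <- function(dff, config) {
  stopifnot(inherits(dff, "movie_stack"), inherits(config, "synthetic_config"))
  nt <- dim(dff$data)[1L]
  t <- (seq_len(nt) - 1) / dff$frame_rate
  b <- bleach_curve(t, config$bleach)
  f <- config$f0_mean * (1 + dff$data) * b   # recycles b along dim 1
  f <- with_seed(config$seed, {
    if (config$noise_model == "poisson") {
      array(stats::rpois(length(f), lambda = pmax(f, 0)), dim = dim(f))
    } else if (config$noise_sd > 0) {
      f + array(stats::rnorm(length(f), 0, config$noise_sd), dim = dim(f))
    } else f
  })
  f <- round(f)
  n_clip <- sum(f < 0 | f > 65535)
  if (n_clip > 0) {
    warning(sprintf("render_movie: %d values clipped to [0, 65535]", n_clip))
    f[f < 0] <- 0; f[f > 65535] <- 65535
  }
  out <- dff
  out$data <- f
  out$units <- "counts"
  out
}
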