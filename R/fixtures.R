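#' Packaged striatal-style fixture: evoked release, two channels, trials
#'
#' Generates a dual-channel evoked-release experiment with known ground
#' truth: compact Gaussian dopamine hotspots, one stimulation per trial,
#' and two sensors with a 1000-fold affinity contrast (a high-affinity
#' GRAB-like channel that saturates at striatal concentrations, and a
#' low-affinity near-infrared channel that resolves the hotspots). Each
#' trial is an independent noise realisation of the same release pattern
#' — the "repeat the stimulation in the same field of view" protocol.
#'
#' Defaults are the study conditions of the packaged fixture: a 64 x 64
#' px field at 0.75 um/px (so an 8-px grid square is 6 um), 1.47
#' frames/s, 90-frame trials with the stimulus at frame 20, three
#' trials, and six hotspots of width 0.75 um centred on grid squares, in
#' two amplitude tiers (strong release sites at 30-45 uM and weak
#' near-threshold sites at 1.4-2 uM) over a 0.05 uM background. Centring
#' the compact hotspots
#' on grid squares and keeping them compact guarantees a wide gap
#' between the responses of hotspot squares and all others, so the
#' ground-truth ROI set is unambiguous. The evoked trials are only ~60 s
#' long and the striatal analysis has no bleach-correction stage, so the
#' fixture renders without photobleaching (bleach round-trips are
#' exercised by the retinal fixture and the rendering tests).
#'
#' The `truth` record includes, per channel, the active-ROI set the
#' detection criterion should find: squares whose noiseless peak dFF in
#' the response window exceeds `k` times the expected baseline noise of
#' a square-mean trace (`noise_sd / (f0_mean * square_px)`). The
#' response window brackets the known kernel peak
#' (`stim + tau_on log(1 + tau_off/tau_on)`).
#'
#' @param config a [synthetic_config()] (geometry, noise, seed).
#' @param field a [hotspot_field()]; default six hotspots centred on
#'   grid squares.
#' @param stim_frame stimulus frame within each trial.
#' @param n_trials number of repeated stimulations.
#' @param amplitude_scale multiplier on all hotspot amplitudes (e.g. 0.4
#'   for a D2-agonist suppressed condition).
#' @param square_px grid square used for the ground-truth ROI set.
#' @param k activity threshold in baseline SDs used for the truth set.
#' @param nir_model,vis_model sensor models for the two channels.
#' @param out_dir if non-`NULL`, trials are written as TIFF + JSON
#'   sidecar pairs plus a `ground_truth.json`.
#' @return list with `nir`, `vis` (lists of per-trial `movie_stack`s in
#'   counts), `nir_dff_true`, `vis_dff_true` (noiseless, bleach-free dFF
#'   movies shared by all trials), and `truth` (hotspot geometry,
#'   stimulus frame, response window, per-channel active-ROI sets,
#'   kinetic constants, seed).
#' @export
generate_striatal_fixture <- function(config = synthetic_config(
                                        n_frames = 90L, height = 64L, width = 64L,
                                        frame_rate = 1.47, pixel_size = 0.75,
                                        f0_mean = 2000, noise_sd = 20,
                                        bleach = c(0, 60, 1, 1e9), seed = 1L),
                                      field = NULL,
                                      stim_frame = 20L,
                                      n_trials = 3L,
                                      amplitude_scale = 1,
                                      square_px = 8L,
                                      k = 2,
                                      nir_model = nircat_model(),
                                      vis_model = grab_da3m_model(),
                                      out_dir = NULL) {
  if (is.null(field)) {
    # hotspots at the centres of grid squares (row, col), 1-based
    sq <- cbind(row = c(2L, 3L, 5L, 6L, 7L, 4L),
                col = c(2L, 6L, 4L, 7L, 2L, 5L))
    ctr <- (sq - 1) * square_px + (square_px / 2)      # pixel units
    field <- hotspot_field(
      centers = ctr * config$pixel_size,               # micrometres
      sigma = 0.75,
      # two amplitude tiers: strong hotspots (tens of uM) that survive a
      # 0.4x suppression, and weak near-threshold sites that do not
      amplitudes = c(45, 30, 38, 2.0, 1.7, 1.4) * amplitude_scale,
      background = 0.05)
  } else if (amplitude_scale != 1) {
    field$amplitudes <- field$amplitudes * amplitude_scale
  }
  protocol <- stimulus_protocol(stim_frame, kind = "electrical")

  conc_nir <- simulate_concentration(field, protocol, nir_model, config)
  conc_vis <- simulate_concentration(field, protocol, vis_model, config)
  dff_nir <- sensor_response(conc_nir, nir_model)
  dff_vis <- sensor_response(conc_vis, vis_model)

  # Ground truth: run the detection arithmetic on a noiseless (quantised)
  # rendering, thresholding at k times the expected baseline noise of a
  # square-mean trace.
  peak_frame <- stim_frame +
    round(rise_decay_peak_time(nir_model$tau_on, nir_model$tau_off) *
            config$frame_rate)
  response_window <- c(peak_frame, peak_frame + 1L)
  truth_active <- function(dff_true) {
    cfg0 <- config
    cfg0$noise_sd <- 0
    clean <- compute_dff(render_movie(dff_true, cfg0),
                         baseline_spec("prestim_mean", stim_frame - 1L))
    g <- apply_grid(clean, square_px)
    pk <- apply(g$traces[, seq(response_window[1L], response_window[2L]),
                         drop = FALSE], 1L, max)
    sigma_sq <- config$noise_sd / (config$f0_mean * square_px)
    which(pk > k * sigma_sq)
  }

  render_trials <- function(dff, seed0) {
    lapply(seq_len(n_trials), function(kk) {
      cfg <- config
      cfg$seed <- seed0 + kk
      render_movie(dff, cfg)
    })
  }
  nir <- render_trials(dff_nir, config$seed)
  vis <- render_trials(dff_vis, config$seed + 1000L)

  truth <- list(centers_um = field$centers, sigma_um = field$sigma,
                amplitudes_uM = field$amplitudes,
                background_uM = field$background,
                stim_frame = stim_frame, n_trials = n_trials,
                amplitude_scale = amplitude_scale,
                square_px = square_px, k = k,
                response_window = response_window,
                active_nir = truth_active(dff_nir),
                active_vis = truth_active(dff_vis),
                nir_tau = c(on = nir_model$tau_on, off = nir_model$tau_off),
                vis_tau = c(on = vis_model$tau_on, off = vis_model$tau_off),
                seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (kk in seq_len(n_trials)) {
      write_movie(nir[[kk]], file.path(out_dir, sprintf("nir_trial%02d.tif", kk)),
                  seed = config$seed + kk)
      write_movie(vis[[kk]], file.path(out_dir, sprintf("vis_trial%02d.tif", kk)),
                  seed = config$seed + 1000L + kk)
    }
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(nir = nir, vis = vis, nir_dff_true = dff_nir, vis_dff_true = dff_vis,
       truth = truth)
}

#' Packaged retinal-style fixture: global waves on two channels
#'
#' Generates a calcium channel and a near-infrared dopamine channel that
#' share spatially global transients at each wave frame (the transient
#' kinetics follow the calcium model — a wave is a fast depolarisation
#' event). The calcium channel is high-SNR; the nIR channel receives the
#' affinity-scaled, much smaller response, reproducing the poor
#' single-wave SNR that makes the calcium-triggered average the usable
#' readout of wave-dopamine coupling.
#'
#' Defaults: a 16 x 16 px field recorded for 2205 frames (25 min) at
#' 1.47 frames/s, with double-exponential photobleaching — waves must be
#' sparse in time for the 3-SD z-score criterion to have headroom, since
#' dense transients inflate the full-trace SD that defines the
#' threshold.
#'
#' @param config a [synthetic_config()]; its `noise_sd` applies to the
#'   calcium channel, the nIR channel uses `nir_noise_sd`.
#' @param wave_frames strictly increasing wave onset frames; consecutive
#'   waves must be separated by more than `min_sep_s` seconds (detection
#'   would otherwise be ambiguous).
#' @param ca_model,da_model sensor models for the two channels;
#'   `ca_model` also supplies the transient time constants.
#' @param wave_conc_uM dopamine concentration reached at each wave peak
#'   (micromolar): near-saturating for the calcium channel, linear
#'   regime for the nIR channel.
#' @param nir_noise_sd noise SD for the nIR channel, counts.
#' @param min_sep_s required wave separation, seconds.
#' @param out_dir if non-`NULL`, both channels and a ground-truth JSON
#'   are written there.
#' @return list with `ca`, `nir` (single `movie_stack` each, counts),
#'   `ca_dff_true`, `nir_dff_true` (noiseless, bleach-free dFF movies)
#'   and `truth` (wave frames, analytic peak frames, amplitudes, seed).
#' @export
generate_wave_fixture <- function(config = synthetic_config(
                                    n_frames = 2205L, height = 16L, width = 16L,
                                    frame_rate = 1.47, pixel_size = 0.75,
                                    f0_mean = 2000, noise_sd = 15,
                                    bleach = c(0.25, 45, 0.75, 8000), seed = 1L),
                                  wave_frames,
                                  ca_model = cal520_model(),
                                  da_model = nircat_model(),
                                  wave_conc_uM = 0.4,
                                  nir_noise_sd = 150,
                                  min_sep_s = 10,
                                  out_dir = NULL) {
  wave_frames <- check_frames(wave_frames, config$n_frames, "wave_frames")
  if (length(wave_frames) > 1L &&
      any(diff(wave_frames) / config$frame_rate <= min_sep_s))
    stopf("wave frames must be separated by more than %g s", min_sep_s)

  # Global (spatially uniform) transients: build the concentration trace
  # and broadcast it over the field of view.
  t <- (seq_len(config$n_frames) - 1) / config$frame_rate
  conc_t <- rep(0.02, config$n_frames)  # resting dopamine background, uM
  for (f in wave_frames) {
    te <- (f - 1) / config$frame_rate
    conc_t <- conc_t + wave_conc_uM *
      rise_decay_kernel(t - te, ca_model$tau_on, ca_model$tau_off)
  }
  broadcast <- function(v) {
    arr <- array(rep(v, times = config$height * config$width),
                 dim = c(config$n_frames, config$height, config$width))
    movie_stack(arr, config$frame_rate, config$pixel_size,
                stim_frames = wave_frames, units = "uM")
  }
  conc <- broadcast(conc_t)
  dff_ca <- sensor_response(conc, ca_model)   # near-saturating: high SNR
  dff_nir <- sensor_response(conc, da_model)  # linear regime: tiny dFF

  ca <- render_movie(dff_ca, config)
  ca$channel <- ca_model$name
  cfg_nir <- config
  cfg_nir$noise_sd <- nir_noise_sd
  cfg_nir$seed <- config$seed + 500L
  nir <- render_movie(dff_nir, cfg_nir)
  nir$channel <- da_model$name

  # peak frame of each noiseless transient on the sampling grid (the
  # discrete argmax, not the rounded continuous peak time: the two can
  # differ by a frame when the peak falls between samples)
  k_frames <- rise_decay_kernel((0:(config$n_frames - 1)) / config$frame_rate,
                                ca_model$tau_on, ca_model$tau_off)
  peak_frames <- wave_frames + (which.max(k_frames) - 1L)

  truth <- list(wave_frames = wave_frames, peak_frames = peak_frames,
                wave_conc_uM = wave_conc_uM,
                ca_dff_peak = max(dff_ca$data) - min(dff_ca$data),
                nir_dff_peak = max(dff_nir$data) - min(dff_nir$data),
                seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_movie(ca, file.path(out_dir, "calcium.tif"), seed = config$seed)
    write_movie(nir, file.path(out_dir, "nir.tif"), seed = cfg_nir$seed)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ca = ca, nir = nir, ca_dff_true = dff_ca, nir_dff_true = dff_nir,
       truth = truth)
}
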