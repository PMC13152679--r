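# Small builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except TIFFs the tests write themselves.

# Movie whose every pixel follows the supplied trace (plus optional
# per-pixel additive offsets).
uniform_movie <- function(values, ny = 8L, nx = 8L, frame_rate = 2,
                          stim_frames = integer()) {
  arr <- array(rep(values, times = ny * nx), dim = c(length(values), ny, nx))
  movie_stack(arr, frame_rate, pixel_size = 1, stim_frames = stim_frames)
}

# Default small study config for striatal fixtures used in tests.
test_striatal_config <- function(seed = 1L, noise_sd = 20) {
  synthetic_config(n_frames = 90L, height = 64L, width = 64L,
                   frame_rate = 1.47, pixel_size = 0.75, f0_mean = 2000,
                   noise_sd = noise_sd, bleach = c(0, 60, 1, 1e9),
                   seed = seed)
}

# Striatal-style analysis of rendered trials: per-trial dFF -> grid ->
# k-SD ROI detection, mirroring the pipeline stages.
analyse_trials <- function(trials, stim_frame, window, square_px = 8L, k = 2) {
  dff <- lapply(trials, compute_dff, baseline_spec("prestim_mean"))
  grids <- lapply(dff, apply_grid, square_px = square_px)
  detect_active_rois(grids, stim_frame, k = k, response_window = window)
}
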