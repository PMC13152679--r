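#' Run the full analysis pipeline from a config
#'
#' Executes the configured stages in order and writes every stage output
#' (CSV tables, JSON results) plus a provenance record to `out_dir`.
#' Two pipeline modes exist:
#'
#' * `"striatal"` — evoked-release trials on two channels: per-trial
#'   dFF (pre-stimulus baseline), grid mask, k-SD ROI detection with
#'   trial averaging, whole-field integrated response, and rise-decay
#'   kinetics on the active squares of the nIR channel.
#' * `"retinal"` — one movie per channel: whole-field trace, dFF
#'   (trial-median baseline on the raw trace), double-exponential bleach
#'   correction of the dFF trace, zero-phase low-pass, wave detection on
#'   the calcium channel, calcium-triggered averaging of both channels,
#'   and response quantification.
#'
#' Inputs come either from TIFF + sidecar files (`inputs:`) or from the
#' packaged synthetic generators (`simulate:`). Any stage error halts
#' the run with the stage name. Re-running an identical config (same
#' seed) reproduces the outputs byte for byte.
#'
#' @param config a named list, or the path of a YAML/JSON config file.
#'   Top-level fields: `mode`, `out_dir`, `seed`, and one of `simulate`
#'   (generator parameters) or `inputs` (file paths: striatal
#'   `nir`/`vis` path vectors, retinal `ca`/`nir` single paths); optional
#'   `grid` (`square_px`, `k`, `response_s`), `kinetics` (`enabled`),
#'   `events` (`z`, `min_sep_s`, `window_s`, `cutoff_hz`, `order`,
#'   `peak_win_s`, `flank_win_s`).
#' @param out_dir overrides `config$out_dir`.
#' @return invisibly, a list of the in-memory stage results
#'   (`summary`, plus mode-specific objects).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("'config' must be a list or a YAML/JSON path")
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stopf("config must name an 'out_dir'")
  mode <- match.arg(config$mode, c("striatal", "retinal"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  res <- if (mode == "striatal") run_striatal(config, stage)
         else run_retinal(config, stage)

  prov <- list(config_md5 = config_md5(config),
               seed = if (is.null(config$seed)) NA else config$seed,
               mode = mode,
               stage_order = res$stage_order,
               package_version = as.character(utils::packageVersion("duofluor")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(res$summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

config_md5 <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

cfg_get <- function(config, path, default) {
  x <- config
  for (k in path) {
    if (is.null(x[[k]])) return(default)
    x <- x[[k]]
  }
  x
}

load_trials <- function(paths) lapply(paths, read_movie)

run_striatal <- function(config, stage) {
  stage_order <- c("acquire", "dff", "grid", "rois", "integrated", "kinetics")
  seed <- as.integer(cfg_get(config, "seed", 1L))

  mov <- stage("acquire", {
    if (!is.null(config$inputs)) {
      list(nir = load_trials(unlist(config$inputs$nir)),
           vis = load_trials(unlist(config$inputs$vis)))
    } else {
      sim <- config$simulate
      if (is.null(sim)) sim <- list()
      cfg <- synthetic_config(
        n_frames = cfg_get(sim, "n_frames", 90L),
        height = cfg_get(sim, "height", 64L),
        width = cfg_get(sim, "width", 64L),
        frame_rate = cfg_get(sim, "frame_rate", 1.47),
        pixel_size = cfg_get(sim, "pixel_size", 0.75),
        f0_mean = cfg_get(sim, "f0_mean", 2000),
        noise_sd = cfg_get(sim, "noise_sd", 20),
        bleach = cfg_get(sim, "bleach", c(0, 60, 1, 1e9)),
        seed = seed)
      fx <- generate_striatal_fixture(
        cfg, stim_frame = cfg_get(sim, "stim_frame", 20L),
        n_trials = cfg_get(sim, "n_trials", 3L),
        amplitude_scale = cfg_get(sim, "amplitude_scale", 1))
      list(nir = fx$nir, vis = fx$vis)
    }
  })

  square_px <- cfg_get(config, c("grid", "square_px"), 8L)
  k <- cfg_get(config, c("grid", "k"), 2)
  response_s <- cfg_get(config, c("grid", "response_s"), 30)

  analyse_channel <- function(trials, label) {
    dff <- stage("dff", lapply(trials, compute_dff, baseline_spec("prestim_mean")))
    grids <- stage("grid", lapply(dff, apply_grid, square_px = square_px))
    stim <- trials[[1L]]$stim_frames[1L]
    win <- cfg_get(config, c("grid", "window"), NULL)
    if (is.null(win))
      win <- default_response_window(stim, trials[[1L]]$frame_rate,
                                     dim(trials[[1L]])[1L], response_s)
    map <- stage("rois", detect_active_rois(grids, stim, k = k,
                                            response_window = win))
    intr <- stage("integrated", {
      m <- dff[[1L]]
      m$data <- Reduce(`+`, lapply(dff, `[[`, "data")) / length(dff)
      integrated_response(m, win)
    })
    write_grid_csv(map, file.path(config$out_dir, sprintf("rois_%s.csv", label)))
    write_trace_csv(intr$trace,
                    file.path(config$out_dir, sprintf("field_trace_%s.csv", label)))
    list(map = map, integrated = intr)
  }
  nir <- analyse_channel(mov$nir, "nir")
  vis <- analyse_channel(mov$vis, "vis")

  kin <- NULL
  if (isTRUE(cfg_get(config, c("kinetics", "enabled"), TRUE))) {
    kin <- stage("kinetics", fit_grid(nir$map))
    utils::write.csv(kin$fits, file.path(config$out_dir, "kinetics_nir.csv"),
                     row.names = FALSE)
  }

  summary <- list(
    mode = "striatal",
    n_trials = length(mov$nir),
    n_squares = nrow(nir$map),
    nir = list(n_active = sum(nir$map$active),
               active_pct = 100 * mean(nir$map$active),
               integrated_peak = nir$integrated$peak),
    vis = list(n_active = sum(vis$map$active),
               active_pct = 100 * mean(vis$map$active),
               integrated_peak = vis$integrated$peak),
    kinetics = if (!is.null(kin))
      list(n_fitted = sum(kin$fits$converged), n_failed = kin$n_failed,
           tau_on_median = if (any(kin$fits$converged))
             stats::median(kin$fits$tau_on[kin$fits$converged]) else NA,
           tau_off_median = if (any(kin$fits$converged))
             stats::median(kin$fits$tau_off[kin$fits$converged]) else NA))
  list(summary = summary, nir = nir, vis = vis, kinetics = kin,
       stage_order = stage_order)
}

run_retinal <- function(config, stage) {
  stage_order <- c("acquire", "trace", "dff", "bleach", "filter",
                   "waves", "triggered", "response")
  seed <- as.integer(cfg_get(config, "seed", 1L))
  ev <- function(key, default) cfg_get(config, c("events", key), default)

  mov <- stage("acquire", {
    if (!is.null(config$inputs)) {
      list(ca = read_movie(config$inputs$ca), nir = read_movie(config$inputs$nir))
    } else {
      sim <- config$simulate
      if (is.null(sim)) sim <- list()
      n_frames <- cfg_get(sim, "n_frames", 2205L)
      fr <- cfg_get(sim, "frame_rate", 1.47)
      wave_frames <- cfg_get(sim, "wave_frames", NULL)
      if (is.null(wave_frames)) {
        n_waves <- cfg_get(sim, "n_waves", 20L)
        wave_frames <- synth_wave_frames(n_frames, fr, n_waves, seed,
                                         min_sep_s = ev("min_sep_s", 10))
      }
      cfg <- synthetic_config(
        n_frames = n_frames,
        height = cfg_get(sim, "height", 16L),
        width = cfg_get(sim, "width", 16L),
        frame_rate = fr,
        f0_mean = cfg_get(sim, "f0_mean", 2000),
        noise_sd = cfg_get(sim, "noise_sd", 15),
        bleach = cfg_get(sim, "bleach", c(0.25, 45, 0.75, 8000)),
        seed = seed)
      fx <- generate_wave_fixture(cfg, wave_frames,
                                  nir_noise_sd = cfg_get(sim, "nir_noise_sd", 150))
      list(ca = fx$ca, nir = fx$nir)
    }
  })

  # dFF first (median of the raw trace is always a well-posed F0), then
  # bleach-correct the dFF trace, then filter; dFF and the unit-DC
  # zero-phase filter commute exactly, and downstream detection and
  # quantification are invariant to the corrected trace's offset
  traces <- stage("trace", lapply(mov, movie_trace))
  dff_raw <- stage("dff", lapply(traces, compute_dff, baseline_spec("trial_median")))
  bc <- stage("bleach", lapply(dff_raw, correct_bleach))
  dff <- stage("filter", lapply(bc, function(b)
    lowpass(b$trace, cutoff = ev("cutoff_hz", 0.68), order = ev("order", 3L))))
  waves <- stage("waves", detect_waves(dff$ca, z = ev("z", 3),
                                       min_sep = ev("min_sep_s", 10)))
  write_events_csv(waves, file.path(config$out_dir, "waves.csv"))
  if (!nrow(waves)) {
    summary <- list(mode = "retinal", n_waves = 0L,
                    bleach_converged = vapply(bc, `[[`, logical(1), "converged"))
    return(list(summary = summary, waves = waves, stage_order = stage_order))
  }
  ta <- stage("triggered",
              triggered_average(dff, waves, window = ev("window_s", 60)))
  for (ch in names(ta))
    write_triggered_csv(ta[[ch]],
                        file.path(config$out_dir, sprintf("triggered_%s.csv", ch)))
  resp <- stage("response", lapply(ta, quantify_response,
                                   peak_win = ev("peak_win_s", 3),
                                   flank_win = ev("flank_win_s", 10)))
  jsonlite::write_json(lapply(resp, `[`, c("response", "before", "after")),
                       file.path(config$out_dir, "responses.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary <- list(
    mode = "retinal",
    n_waves = nrow(waves),
    wave_frames = I(waves$frame),
    bleach_converged = vapply(bc, `[[`, logical(1), "converged"),
    response = lapply(resp, `[[`, "response"),
    n_events_used = ta[[1L]]$n_events_used,
    n_events_dropped = ta[[1L]]$n_events_dropped)
  list(summary = summary, waves = waves, triggered = ta, responses = resp,
       stage_order = stage_order)
}

# Evenly spaced wave times with seeded jitter, respecting the minimum
# separation; used when a retinal simulate block gives only a count.
synth_wave_frames <- function(n_frames, frame_rate, n_waves, seed, min_sep_s = 10) {
  margin <- round(35 * frame_rate)          # keep full 60 s windows inside
  lo <- margin + 1L
  hi <- n_frames - margin
  if (hi <= lo) stopf("movie too short for %d waves", n_waves)
  base <- seq(lo, hi, length.out = n_waves)
  gap <- if (n_waves > 1L) base[2L] - base[1L] else hi - lo
  jit_max <- max(0, floor((gap - min_sep_s * frame_rate) / 2) - 1)
  with_seed(seed + 17L, {
    f <- round(base + stats::runif(n_waves, -jit_max, jit_max))
    f <- pmin(pmax(f, lo), hi)     # jitter must not leave the margins
    as.integer(sort(f))
  })
}
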